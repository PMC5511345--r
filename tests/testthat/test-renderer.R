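test_that("an empty cell renders as the camera offset everywhere", {
  g <- cell_geometry("spheroplast", diameter_um = 2)
  sim <- simulate_sheaths(simulation_config(g, duration_s = 4, seed = 1))
  stack <- render_stack(sim, quiet_optics(cytosol_background = 0),
                        noiseless = TRUE)
  expect_true(all(vapply(stack$frames, function(f) all(f == 100),
                         logical(1))))
})

test_that("rendered intensity integrates to the photon budget", {
  # two rings (a 10 nm stub) at brightness 1, no background
  g <- cell_geometry("spheroplast", diameter_um = 3)
  cfg <- simulation_config(
    g, duration_s = 2, seed = 1,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0, initial_length_um = 0.01)))
  sim <- simulate_sheaths(cfg)
  n_rings <- length(sim$frames[[1]][[1]]$ring_brightness)
  stack <- render_stack(sim, quiet_optics(cytosol_background = 0,
                                          photons_per_ring = 20),
                        noiseless = TRUE)
  total <- sum(stack$frames[[1]] - 100)
  expect_equal(total, 20 * n_rings, tolerance = 0.01)
})

test_that("noiseless rendering conserves intensity across contraction", {
  g <- cell_geometry("spheroplast", diameter_um = 3)
  cfg <- simulation_config(
    g, v_a_mean_nm_per_s = 80, extension_dwell_s = 4,
    disassembly_delay_s = 100, duration_s = 60, seed = 6,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0)))
  sim <- simulate_sheaths(cfg)
  contr_t <- sim$events$time_s[sim$events$event == "contraction"]
  expect_length(contr_t, 1)
  fi <- which(sim$times_s == contr_t)
  stack <- render_stack(sim, quiet_optics(cytosol_background = 0),
                        noiseless = TRUE)
  before <- sum(stack$frames[[fi - 1]] - 100)
  after <- sum(stack$frames[[fi]] - 100)
  expect_equal(after, before, tolerance = 0.01)
})

test_that("rendering is linear in truth brightness", {
  sim <- grow_sim(seed = 2, v_a = 55, diameter = 3, duration = 20)
  s1 <- render_stack(sim, quiet_optics(cytosol_background = 0,
                                       photons_per_ring = 10),
                     noiseless = TRUE)
  s2 <- render_stack(sim, quiet_optics(cytosol_background = 0,
                                       photons_per_ring = 30),
                     noiseless = TRUE)
  f1 <- s1$frames[[10]] - 100
  f2 <- s2$frames[[10]] - 100
  expect_equal(f2, 3 * f1, tolerance = 1e-8)
})

test_that("stacks round-trip through TIFF with exact metadata", {
  sim <- grow_sim(seed = 3, v_a = 55, diameter = 2, duration = 10)
  stack <- render_stack(sim, optics_config())
  path <- file.path(tempdir(), "roundtrip.tif")
  write_stack(stack, path)
  back <- read_stack(path)
  expect_identical(back$frames,
                   lapply(stack$frames,
                          function(f) pmin(pmax(round(f), 0), 65535)))
  expect_equal(back$pixel_size_nm, stack$pixel_size_nm)
  expect_equal(back$frame_interval_s, stack$frame_interval_s)
  expect_equal(back$origin_um, stack$origin_um)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("reading a stack without pixel size metadata names the field", {
  frames <- replicate(3, matrix(100, 8, 8), simplify = FALSE)
  stack <- make_stack(frames)
  path <- file.path(tempdir(), "nometa.tif")
  write_stack(stack, path)
  file.remove(paste0(path, ".yaml"))
  expect_error(read_stack(path), "sidecar")
  expect_error(read_stack(path, metadata = list(frame_interval_s = 2)),
               "pixel_size_nm")
  unlink(path)
})

test_that("a 2500-frame 2 ms stack round-trips with its frame interval", {
  frames <- replicate(2500, matrix(50, 4, 4), simplify = FALSE)
  stack <- make_stack(frames, frame_interval_s = 0.002)
  path <- file.path(tempdir(), "fast.tif")
  write_stack(stack, path)
  back <- read_stack(path)
  expect_length(back$frames, 2500)
  expect_equal(back$frame_interval_s, 0.002)
  expect_identical(back$frames[[2500]], matrix(50, 4, 4))
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("background estimation recovers the cytosolic level", {
  sim <- grow_sim(seed = 4, v_a = 55, diameter = 3, duration = 20)
  stack <- render_stack(sim, quiet_optics(cytosol_background = 20),
                        noiseless = TRUE)
  bg <- estimate_background(stack)
  expect_equal(bg$mean, rep(120, nrow(bg)), tolerance = 1e-6)
  stack_n <- render_stack(sim, optics_config(cytosol_background = 20))
  bg_n <- estimate_background(stack_n)
  expect_equal(mean(bg_n$mean), 120, tolerance = 1)
  expect_equal(mean(bg_n$sd), sqrt(20 + 4), tolerance = 1.5)
})
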