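test_that("chase time points follow the measurement schedule", {
  tps <- chase_timepoints(30, 82, 2)
  expect_equal(tps$t1, 30)
  expect_equal(tps$t2, 32)
  expect_equal(tps$t3, 62)
  expect_equal(tps$t4, 82)
  expect_warning(tps2 <- chase_timepoints(30, 45, 2), "t3")
  expect_true(is.na(tps2$t3))
})

test_that("intensity normalization maps background to 0 and reference to 100", {
  expect_equal(normalize_intensity(120, 120, 150), 0)
  expect_equal(normalize_intensity(150, 120, 150), 100)
  expect_error(normalize_intensity(130, 120, 110), "exceed")
  # exactly invariant under affine rescaling of camera counts
  raw <- c(108, 120, 135, 150)
  p1 <- normalize_intensity(raw, 110, 150, 112)
  gain <- 3.7
  offset <- 55
  p2 <- normalize_intensity(gain * raw + offset, gain * 110 + offset,
                            gain * 150 + offset, gain * 112 + offset)
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("ineligible events are rejected with the right reasons", {
  # nucleates after the bleach: not polymerizing pre-bleach
  geom <- cell_geometry("spheroplast", diameter_um = 4.5)
  anchor <- membrane_point(geom, pi)
  bl <- bleach_event(30, anchor + c(0.9, 1.5), anchor + c(0.9, -1.5))
  cfg <- simulation_config(
    geom, v_a_mean_nm_per_s = 55, duration_s = 120, bleach = bl, seed = 31,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 40)))
  stack <- render_stack(simulate_sheaths(cfg), optics_config())
  rep <- suppressWarnings(run_bleach_chase(stack))
  expect_equal(rep$status, "rejected")
  expect_true(any(grepl("pre-bleach", rep$reasons)))
  # bleach footprint covering the whole sheath: not partial
  stack2 <- render_stack(
    simulate_sheaths(simulation_config(
      geom, v_a_mean_nm_per_s = 55, duration_s = 120, seed = 32,
      bleach = bleach_event(30, anchor + c(0.9, 1.5), anchor + c(0.9, -1.5),
                            footprint_fwhm_um = 12),
      sheaths = list(list(anchor_angle = pi, target_angle = 0,
                          t_nucleation_s = 2)))),
    optics_config())
  rep2 <- suppressWarnings(run_bleach_chase(stack2))
  expect_equal(rep2$status, "rejected")
  expect_true(any(grepl("not partial", rep2$reasons)))
  # a compliant event passes
  ev3 <- simulate_chase_event("distal", seed = 33)
  rep3 <- suppressWarnings(run_bleach_chase(ev3$stack))
  expect_equal(rep3$status, "ok")
})

test_that("a noiseless distal event shows bright, bleached, dim in order", {
  ev <- simulate_chase_event("distal", seed = 41, noiseless = TRUE)
  rep <- suppressWarnings(run_bleach_chase(ev$stack))
  expect_equal(rep$status, "ok")
  secs <- rep$sections
  expect_true(all(c("bright", "bleached", "dim") %in% secs$klass))
  b1 <- min(secs$d_lo_nm[secs$klass == "bright"])
  b2 <- min(secs$d_lo_nm[secs$klass == "bleached"])
  b3 <- max(secs$d_lo_nm[secs$klass == "dim"])
  expect_true(b1 < b2 && b2 < b3)
})

test_that("a no-op bleach leaves no bleached span to classify", {
  geom <- cell_geometry("spheroplast", diameter_um = 4.5)
  anchor <- membrane_point(geom, pi)
  cfg <- simulation_config(
    geom, v_a_mean_nm_per_s = 55, duration_s = 120, seed = 42,
    bleach = bleach_event(30, anchor + c(0.9, 1.5), anchor + c(0.9, -1.5),
                          polymer_survival = 1, pool_survival = 1),
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 2)))
  stack <- render_stack(simulate_sheaths(cfg), optics_config())
  bg <- estimate_background(stack)
  l <- stack$meta$lines[[1]]
  kym <- orient_kymogram(extract_kymogram(stack,
                                          line_profile(l$start_um, l$end_um)),
                         bg)
  tr <- trace_front(kym, bg)
  pre <- prebleach_level(kym, tr, 30)
  expect_error(
    classify_sections(kym, 30, 100, bg, pre, trace = tr),
    "no bleached span")
})

test_that("noiseless events recover their mechanism exactly", {
  for (mech in c("distal", "proximal", "intercalation")) {
    ev <- simulate_chase_event(mech, seed = 43, noiseless = TRUE)
    rep <- suppressWarnings(run_bleach_chase(ev$stack))
    expect_equal(rep$call$label, mech)
  }
})

test_that("distal bleached and bright marks stay put; dim extends distally", {
  ev <- simulate_chase_event("distal", seed = 44, noiseless = TRUE)
  rep <- suppressWarnings(run_bleach_chase(ev$stack))
  tk <- rep$track
  bl <- tk[tk$section == "bleached", ]
  expect_gte(nrow(bl), 3)
  expect_lte(diff(range(bl$centroid_nm)), 65)
  br <- tk[tk$section == "bright" & tk$timepoint != "t1", ]
  expect_lte(diff(range(br$centroid_nm)), 65)
  dm <- tk[tk$section == "dim", ]
  expect_gt(dm$centroid_nm[nrow(dm)], dm$centroid_nm[1])
  expect_true(all(abs(bl$intensity_pct) < 10))
  expect_true(all(dm$intensity_pct > 20 & dm$intensity_pct < 60))
})

test_that("the analysis is equivariant to reversing the line", {
  ev <- simulate_chase_event("distal", seed = 45, noiseless = TRUE)
  rep1 <- suppressWarnings(run_bleach_chase(ev$stack))
  l <- ev$stack$meta$lines[[1]]
  rev_line <- line_profile(l$end_um, l$start_um)
  rep2 <- suppressWarnings(run_bleach_chase(ev$stack, line = rev_line))
  expect_equal(rep2$call$label, rep1$call$label)
  b1 <- rep1$track[rep1$track$section == "bleached", ]
  b2 <- rep2$track[rep2$track$section == "bleached", ]
  expect_equal(b2$centroid_nm, b1$centroid_nm, tolerance = 65)
})

test_that("mechanism inference is a pure function of its evidence", {
  mk <- function(drift, width, int) {
    tk <- data.frame(
      section = "bleached", timepoint = c("t2", "t3", "t4"),
      time_s = c(32, 62, 82),
      centroid_nm = 900 + drift * c(0, 30, 50),
      width_nm = 450 * c(1, 1 + width / 2, 1 + width),
      mean_intensity = 110,
      intensity_pct = c(5, 5 + int / 2, 5 + int))
    infer_mechanism(tk, v_a_nm_per_s = 55)$label
  }
  expect_equal(mk(0, 0, 0), "distal")
  expect_equal(mk(55, 0, 0), "proximal")
  expect_equal(mk(30, 1.5, 30), "intercalation")
  expect_equal(mk(-40, 0, 0), "ambiguous")  # retrograde drift fits nothing
})
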