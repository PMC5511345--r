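test_that("speed regression is exact on collinear points", {
  tr <- make_trace(c(0, 2, 4), c(0, 76, 152))
  sp <- estimate_speed(tr)
  expect_equal(sp$v_a_nm_per_s, 38)
  expect_equal(sp$r_squared, 1)
  expect_equal(sp$n_points, 3L)
})

test_that("speed regression matches the closed-form OLS on a 4-point table", {
  # hand-computed: x = 1..4, y = (2, 3, 5, 6):
  # slope = 7/5 = 1.4, intercept = 0.5, R^2 = 1 - 0.2/10 = 0.98
  tr <- make_trace(1:4, c(2, 3, 5, 6))
  sp <- estimate_speed(tr)
  expect_equal(sp$v_a_nm_per_s, 1.4)
  expect_equal(sp$intercept_nm, 0.5)
  expect_equal(sp$r_squared, 0.98)
})

test_that("speed estimation is shift-invariant and time-scale equivariant", {
  set.seed(8)
  y <- 40 * (0:19) + rnorm(20, 0, 15)
  tr <- make_trace(seq(0, 38, by = 2), y)
  sp <- estimate_speed(tr)
  shifted <- make_trace(seq(0, 38, by = 2), y + 500)
  expect_equal(estimate_speed(shifted)$v_a_nm_per_s, sp$v_a_nm_per_s)
  expect_equal(estimate_speed(shifted)$r_squared, sp$r_squared)
  stretched <- make_trace(seq(0, 76, by = 4), y)
  expect_equal(estimate_speed(stretched)$v_a_nm_per_s, sp$v_a_nm_per_s / 2)
  expect_error(estimate_speed(make_trace(c(1, 2), c(0, 1))), "3 valid")
})

test_that("noiseless front tracking is accurate to half a distance bin", {
  ev <- simulate_speed_event(55, seed = 3, noiseless = TRUE)
  bg <- estimate_background(ev$stack)
  l <- ev$stack$meta$lines[[1]]
  kym <- orient_kymogram(extract_kymogram(ev$stack,
                                          line_profile(l$start_um, l$end_um)),
                         bg)
  tr <- trace_front(kym, bg)
  truth <- truth_lengths(ev$sim)
  # beyond the diffraction scale the edge is localizable; below it is not
  ok <- tr$valid & truth$length_um >= 0.5
  err <- tr$front_nm[ok] - truth$length_um[ok] * 1000
  expect_lt(max(abs(err)), 32.5)
})

test_that("assembly end is found where growth stops", {
  # chord 2.5 um at 55 nm/s: growth stops at ~45.5 s
  sim <- grow_sim(seed = 9, v_a = 55, diameter = 2.5, duration = 90)
  t_ext <- sim$events$time_s[sim$events$event == "extended"]
  stack <- render_stack(sim, quiet_optics(), noiseless = TRUE)
  bg <- estimate_background(stack)
  l <- stack$meta$lines[[1]]
  kym <- orient_kymogram(extract_kymogram(stack,
                                          line_profile(l$start_um, l$end_um)),
                         bg)
  end <- detect_assembly_end(trace_front(kym, bg))
  expect_lte(abs(end$t_end_s - t_ext), 2)
  expect_false(end$still_growing)
  # monotone growth to the end of the stack raises the flag
  ev <- simulate_speed_event(55, seed = 10, noiseless = TRUE)
  bg2 <- estimate_background(ev$stack)
  l2 <- ev$stack$meta$lines[[1]]
  kym2 <- orient_kymogram(extract_kymogram(ev$stack,
                                           line_profile(l2$start_um,
                                                        l2$end_um)), bg2)
  expect_warning(end2 <- detect_assembly_end(trace_front(kym2, bg2)),
                 "still advancing")
  expect_true(end2$still_growing)
})

test_that("plateau detection is stable under default noise", {
  ends <- sapply(1:10, function(s) {
    sim <- grow_sim(seed = 100 + s, v_a = 55, diameter = 2.5, duration = 90)
    stack <- render_stack(sim, optics_config())
    bg <- estimate_background(stack)
    l <- stack$meta$lines[[1]]
    kym <- orient_kymogram(
      extract_kymogram(stack, line_profile(l$start_um, l$end_um)), bg)
    detect_assembly_end(trace_front(kym, bg))$t_end_s
  })
  expect_true(all(abs(ends - 46) <= 4))  # plateau onset within ~2 frames
})

test_that("contraction fractions come from the two lengths and sum to one", {
  ce <- quantify_contraction(2, 1)
  expect_equal(ce$shortening_fraction, 0.5)
  expect_equal(ce$remaining_fraction, 0.5)
  ce <- quantify_contraction(3.29, 1.69)
  expect_equal(ce$shortening_fraction, 0.486, tolerance = 1e-3)
  expect_equal(ce$remaining_fraction, 0.514, tolerance = 1e-3)
  expect_equal(ce$shortening_fraction + ce$remaining_fraction, 1)
  expect_error(quantify_contraction(2, 2.5), "smaller")
  expect_error(quantify_contraction(0, 1), "positive")
})

test_that("contraction speed bound is length change over frame interval", {
  expect_equal(contraction_speed_lower_bound(1.6, 0.002), 800)
  expect_equal(contraction_speed_lower_bound(0, 0.5), 0)
  expect_equal(contraction_speed_lower_bound(1.6, 0.004), 400)
  expect_error(contraction_speed_lower_bound(1, 0), "positive")
})

test_that("growth-only stacks yield no contraction events", {
  ev <- simulate_speed_event(55, seed = 14, duration_s = 40)
  events <- detect_contraction_events(ev$stack)
  expect_equal(nrow(events), 0)
})

test_that("a growing-then-contracting sheath drops within one frame pair", {
  ev <- simulate_contraction_event(seed = 21)
  events <- detect_contraction_events(ev$stack)
  expect_equal(nrow(events), 1)
  expect_equal(events$t_after_s - events$t_before_s, 2)
  truth <- ev$sim$events
  t_contr <- truth$time_s[truth$event == "contraction"]
  expect_lte(abs(events$t_after_s - t_contr), 2)
  expect_equal(events$remaining_fraction,
               truth$length_um[truth$event == "contraction"] /
                 truth$length_um[truth$event == "extended"],
               tolerance = 0.05)
})
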