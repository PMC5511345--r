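test_that("category fractions reproduce known proportions", {
  rec <- data.frame(
    morphology = c(rep("spheroplast", 1007 + 80), rep("rod", 25),
                   rep("lysed", 10)),
    dynamic_t6ss = c(rep(TRUE, 1007), rep(FALSE, 80), rep(TRUE, 10),
                     rep(FALSE, 15), rep(FALSE, 10)))
  s <- summarize_dynamics(rec)
  expect_equal(s$percent[s$morphology == "spheroplast" &
                           s$dynamics == "dynamic"], 89.75)
  expect_equal(sum(s$percent), 100, tolerance = 0.02)
  one <- summarize_dynamics(data.frame(morphology = "rod",
                                       dynamic_t6ss = TRUE))
  expect_equal(one$percent[one$n == 1], 100)
  half <- summarize_dynamics(data.frame(morphology = c("rod", "rod"),
                                        dynamic_t6ss = c(TRUE, FALSE)))
  expect_equal(sort(half$percent[half$n > 0]), c(50, 50))
  expect_error(summarize_dynamics(data.frame()), "non-empty")
})

test_that("an exactly proportional population regresses with R^2 = 1", {
  rec <- data.frame(morphology = "spheroplast",
                    diameter_um = c(2, 3, 4, 5, 6),
                    longest_sheath_um = 0.9 * c(2, 3, 4, 5, 6))
  r <- regress_length_vs_diameter(rec)
  expect_equal(r$slope, 0.9)
  expect_equal(r$r_squared, 1)
  expect_error(regress_length_vs_diameter(
    data.frame(morphology = "spheroplast", diameter_um = c(3, 3, 3),
               longest_sheath_um = c(1, 2, 3))), "variance")
})

test_that("chord-limited simulated sheaths correlate with cell diameter", {
  pop <- simulate_cell_population(40, seed = 2)
  r <- regress_length_vs_diameter(pop$records)
  expect_gte(r$r_squared, 0.8)
  expect_true(all(pop$records$longest_sheath_um <=
                    pop$records$diameter_um + 0.2, na.rm = TRUE))
  # shuffling the pairing destroys the correlation
  rec <- pop$records[!is.na(pop$records$longest_sheath_um), ]
  set.seed(7)
  shuffled_r2 <- replicate(50, {
    rec$longest_sheath_um <- sample(rec$longest_sheath_um)
    regress_length_vs_diameter(rec)$r_squared
  })
  expect_true(all(shuffled_r2 < 0.2))
})

test_that("event counting respects the window and the nucleation rate", {
  ev <- data.frame(cell_id = c(1, 1, 1, 2),
                   time_s = c(10, 50, 130, 20), sheath_id = 1:4,
                   event = "nucleation", length_um = 0)
  cnt <- count_sheath_events(ev, window_s = 120, acquisition_s = 150)
  expect_equal(cnt$n_events, c(2L, 1L))
  expect_error(count_sheath_events(ev, window_s = 200, acquisition_s = 150),
               "exceeds")
  # zero rate: zero counts everywhere
  pop0 <- simulate_cell_population(5, seed = 3, nucleation_rate_per_min = 0,
                                   duration_s = 120)
  expect_true(all(pop0$records$n_sheath_events_2min == 0))
})

test_that("mean counts scale with the nucleation rate", {
  p1 <- simulate_cell_population(40, seed = 5, duration_s = 120,
                                 nucleation_rate_per_min = 1.265)
  p3 <- simulate_cell_population(40, seed = 6, duration_s = 120,
                                 nucleation_rate_per_min = 3 * 1.265)
  m1 <- mean(p1$records$n_sheath_events_2min)
  m3 <- mean(p3$records$n_sheath_events_2min)
  expect_equal(m3 / m1, 3, tolerance = 0.35)
  expect_equal(m1, 2.53, tolerance = 0.3)
})
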