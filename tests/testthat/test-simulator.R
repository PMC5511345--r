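test_that("no nucleation means no sheaths and an unchanged pool", {
  g <- cell_geometry("spheroplast", diameter_um = 3)
  cfg <- simulation_config(g, nucleation_rate_per_min = 0, duration_s = 20,
                           seed = 1)
  sim <- simulate_sheaths(cfg)
  expect_length(sim$frames[[length(sim$frames)]], 0)
  expect_true(all(sim$pool_series$soluble_brightness == 1))
  expect_equal(nrow(sim$events), 0)
})

test_that("60 s of distal growth at 38 nm/s yields a 2.28 um sheath", {
  sim <- grow_sim(seed = 1, v_a = 38, diameter = 4, duration = 60)
  sh <- final_sheath(sim)
  expect_equal(max(sh$ring_positions_um), 2.28, tolerance = 0.01)
})

test_that("sheath length never exceeds the available chord", {
  for (mech in c("distal", "proximal", "intercalation")) {
    sim <- grow_sim(seed = 3, v_a = 80, diameter = 2, duration = 60,
                    mechanism = mech)
    lens <- truth_lengths(sim)
    expect_lte(max(lens$length_um), 2 + 1e-6)
  }
  # unlimited growth time in a large spheroplast stays within its diameter
  sim <- grow_sim(seed = 4, v_a = 55, diameter = 8.5, duration = 200)
  expect_lte(max(truth_lengths(sim)$length_um), 8.5)
  expect_gt(max(truth_lengths(sim)$length_um), 8)
})

test_that("mechanisms place new rings where they claim to", {
  g <- cell_geometry("spheroplast", diameter_um = 4)
  pool <- fluorophore_pool(soluble_brightness = 0.4)
  base <- sheathtrack:::new_sheath(1, c(-2, 0), c(1, 0), 4, 50, 0, "distal")
  base$ring_brightness <- rep(1, 51)             # 0.5 um of bright polymer
  base$ring_positions_um <- (0:50) * 0.01
  # distal: pre-existing ring distances unchanged, new rings dim at the tip
  sh <- base
  res <- step_assembly(sh, pool, dt = 2)         # +100 nm
  expect_equal(res$sheath$ring_positions_um[51], 0.5)
  expect_equal(res$sheath$ring_brightness[1:51], rep(1, 51))
  expect_true(all(res$sheath$ring_brightness[52:61] == 0.4))
  expect_equal(max(res$sheath$ring_positions_um), 0.6)
  # proximal: every pre-existing ring pushed outward by the added length
  sh <- base
  sh$mechanism <- "proximal"
  res <- step_assembly(sh, pool, dt = 2)
  b <- res$sheath$ring_brightness
  expect_true(all(b[1:10] == 0.4))               # new material at the anchor
  expect_true(all(b[11:61] == 1))
  expect_equal(res$sheath$ring_positions_um[match(1, b)], 0.1)
})

test_that("intercalation stretches a tagged block in proportion to length", {
  # ring-bookkeeping oracle: tag a contiguous block by brightness, grow, and
  # compare the expected block span with the length ratio over replicates
  set.seed(99)
  ratios <- replicate(100, {
    sh <- sheathtrack:::new_sheath(1, c(-3, 0), c(1, 0), 6, 50, 0,
                                   "intercalation")
    sh$ring_brightness <- rep(1, 100)            # 1 um
    sh$ring_positions_um <- (0:99) * 0.01
    sh$ring_brightness[41:60] <- 0               # tagged (bleached) block
    pool <- fluorophore_pool()
    for (i in 1:20) {
      res <- step_assembly(sh, pool, dt = 2)     # 100 nm per step
      sh <- res$sheath
    }
    idx <- which(sh$ring_brightness == 0)
    span <- (max(idx) - min(idx) + 1) / 20       # block stretch factor
    L_ratio <- length(sh$ring_brightness) / 100
    span / L_ratio
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("photobleach respects footprint geometry and is irreversible", {
  sh <- sheathtrack:::new_sheath(1, c(0, 0), c(1, 0), 4, 50, 0, "distal")
  sh$ring_brightness <- rep(1, 301)
  sh$ring_positions_um <- (0:300) * 0.01         # rings along x in [0, 3]
  pool <- fluorophore_pool()
  ev <- bleach_event(10, line_start_um = c(1, -1), line_end_um = c(1, 1),
                     polymer_survival = 0, pool_survival = 0.4)
  res <- apply_photobleach(list(sh), pool, ev)
  b <- res$sheaths[[1]]$ring_brightness
  expect_equal(b[101], 0)                        # ring on the line centre
  expect_gt(b[1], 0.98)                          # ring 1 um away: ~untouched
  expect_gt(b[301], 0.9999)                      # ring 2 um away: untouched
  expect_equal(res$pool$soluble_brightness, 0.4)
  # total brightness decreased, never increased
  expect_lt(sum(b), sum(sh$ring_brightness))
  # a second identical bleach cannot brighten anything
  res2 <- apply_photobleach(res$sheaths, res$pool, ev)
  expect_true(all(res2$sheaths[[1]]$ring_brightness <= b + 1e-12))
  expect_lte(res2$pool$soluble_brightness, 0.4)
})

test_that("contraction halves positions, conserves brightness, keeps anchor", {
  sim <- grow_sim(seed = 5, v_a = 55, diameter = 2, duration = 60)
  sh <- final_sheath(sim)
  expect_equal(sh$phase, "extended")
  total_before <- sum(sh$ring_brightness)
  anchor_before <- sh$anchor_um
  contracted <- contract_sheath(sh, 0.5)
  expect_equal(max(contracted$ring_positions_um),
               max(sh$ring_positions_um) * 0.5)
  expect_equal(sum(contracted$ring_brightness), total_before)
  expect_equal(contracted$anchor_um, anchor_before)
  expect_error(contract_sheath(sh, 1.2), "fraction")
  expect_error(contract_sheath(sh, 0), "fraction")
})

test_that("simulation is deterministic given its seed and phases are ordered", {
  g <- cell_geometry("spheroplast", diameter_um = 4)
  mk <- function() simulate_sheaths(simulation_config(
    g, nucleation_rate_per_min = 3, extension_dwell_s = 10,
    disassembly_delay_s = 10, disassembly_tau_s = 8, duration_s = 120,
    seed = 77))
  s1 <- mk()
  s2 <- mk()
  expect_identical(s1$events, s2$events)
  expect_identical(truth_lengths(s1), truth_lengths(s2))
  # each sheath's events appear in life-cycle order
  phase_order <- c(nucleation = 1, extended = 2, contraction = 3,
                   disassembly = 4, gone = 5)
  for (id in unique(s1$events$sheath_id)) {
    if (is.na(id)) next
    ev <- s1$events$event[s1$events$sheath_id == id]
    expect_true(!is.unsorted(phase_order[ev]))
  }
})

test_that("a finite subunit pool halts polymerization when exhausted", {
  g <- cell_geometry("spheroplast", diameter_um = 6)
  cfg <- simulation_config(
    g, v_a_mean_nm_per_s = 55, duration_s = 80, seed = 2,
    pool = fluorophore_pool(pool_size = 100),    # 1 um worth of rings
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0)))
  sim <- simulate_sheaths(cfg)
  expect_lte(max(truth_lengths(sim)$length_um), 1.01)
})
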