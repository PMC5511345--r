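# Canned in-silico experiments reproducing the study designs: single-sheath
# photobleach-chase acquisitions, speed-recovery acquisitions, contraction
# series at 2 s/frame, and high-frame-rate (500 fps) contraction captures.
# These fix the acquisition geometry once; tests and the acceptance analysis
# run the same code paths.

#' Simulate one photobleach-chase acquisition
#'
#' One sheath nucleates 2 s into a 2-minute acquisition at 2 s per frame in a
#' spheroplast, polymerizing along the diameter. After 30 s a bleach line
#' crosses the sheath perpendicular to its axis 0.9 um from the origin,
#' fully bleaching the polymer in its footprint and reducing the soluble
#' pool to 40%. Growth then continues to the available chord, so the
#' post-bleach assembly lasts well over 20 s and all four chase time points
#' are defined.
#'
#' @param mechanism `"distal"`, `"proximal"` or `"intercalation"`.
#' @param seed Integer seed.
#' @param v_a_nm_per_s Polymerization speed (default 55, typical of cells
#'   assembling few sheaths).
#' @param diameter_um Spheroplast diameter (default 4.5).
#' @param noiseless Disable camera noise (default FALSE).
#' @param bleach_at_um Distance of the bleach-line crossing from the origin
#'   (default 0.9).
#' @param optics An [optics_config()].
#' @return `list(sim =, stack =)`.
#' @export
simulate_chase_event <- function(mechanism, seed, v_a_nm_per_s = 55,
                                 diameter_um = 4.5, noiseless = FALSE,
                                 bleach_at_um = 0.9,
                                 optics = optics_config()) {
  geom <- cell_geometry("spheroplast", diameter_um = diameter_um)
  anchor <- membrane_point(geom, pi)
  dir <- c(1, 0)
  cross <- anchor + dir * bleach_at_um
  bl <- bleach_event(t_bleach_s = 30,
                     line_start_um = cross + c(0, 1.5),
                     line_end_um = cross - c(0, 1.5))
  cfg <- simulation_config(
    geometry = geom, mechanism = mechanism,
    v_a_mean_nm_per_s = v_a_nm_per_s,
    frame_interval_s = 2, duration_s = 120, bleach = bl, seed = seed,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 2)))
  sim <- simulate_sheaths(cfg)
  stack <- render_stack(sim, optics, noiseless = noiseless)
  list(sim = sim, stack = stack)
}

#' Simulate a growth-only acquisition for speed recovery
#'
#' One sheath polymerizing along a spheroplast diameter at the given speed,
#' imaged at 2 s per frame; the acquisition ends while the sheath is still
#' growing, so the whole trace is a single linear growth phase.
#'
#' @param v_a_nm_per_s True polymerization speed.
#' @param seed Integer seed.
#' @param diameter_um Spheroplast diameter (default 5).
#' @param duration_s Acquisition length (default 80 s).
#' @param noiseless Disable camera noise (default FALSE).
#' @param optics An [optics_config()].
#' @return `list(sim =, stack =)`.
#' @export
simulate_speed_event <- function(v_a_nm_per_s, seed, diameter_um = 5,
                                 duration_s = 80, noiseless = FALSE,
                                 optics = optics_config()) {
  geom <- cell_geometry("spheroplast", diameter_um = diameter_um)
  cfg <- simulation_config(
    geometry = geom, mechanism = "distal",
    v_a_mean_nm_per_s = v_a_nm_per_s,
    frame_interval_s = 2, duration_s = duration_s, seed = seed,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0)))
  sim <- simulate_sheaths(cfg)
  stack <- render_stack(sim, optics, noiseless = noiseless)
  list(sim = sim, stack = stack)
}

#' Measure polymerization speed from a rendered acquisition
#'
#' Kymogram along the sheath's chord, orientation, front trace and OLS speed.
#'
#' @param stack An [image_stack()] with metadata lines and geometry.
#' @param window Optional time window for the regression.
#' @return A [estimate_speed()] result.
#' @export
measure_speed <- function(stack, window = NULL) {
  bg <- estimate_background(stack)
  l <- stack$meta$lines[[1]]
  kym <- orient_kymogram(extract_kymogram(stack, line_profile(l$start_um,
                                                              l$end_um)), bg)
  estimate_speed(trace_front(kym, bg), window = window)
}

#' Simulate a contraction acquisition at 2 s per frame
#'
#' One sheath grows to its full chord, dwells briefly in the extended state
#' and contracts (remaining fraction drawn from the configured contraction
#' model); the contracted sheath persists long enough to be measured.
#'
#' @param seed Integer seed.
#' @param v_a_nm_per_s Polymerization speed (default 55).
#' @param diameter_um Spheroplast diameter (default 4).
#' @param noiseless Disable camera noise (default FALSE).
#' @param optics An [optics_config()].
#' @return `list(sim =, stack =)`.
#' @export
simulate_contraction_event <- function(seed, v_a_nm_per_s = 55,
                                       diameter_um = 4, noiseless = FALSE,
                                       optics = optics_config()) {
  geom <- cell_geometry("spheroplast", diameter_um = diameter_um)
  duration <- ceiling(diameter_um * 1000 / v_a_nm_per_s) + 30
  cfg <- simulation_config(
    geometry = geom, mechanism = "distal",
    v_a_mean_nm_per_s = v_a_nm_per_s,
    extension_dwell_s = 6, disassembly_delay_s = 60,
    frame_interval_s = 2, duration_s = duration, seed = seed,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0)))
  sim <- simulate_sheaths(cfg)
  stack <- render_stack(sim, optics, noiseless = noiseless)
  list(sim = sim, stack = stack)
}

#' Simulate a high-frame-rate contraction capture
#'
#' A fully extended sheath imaged for 5 s at 500 frames per second; the
#' contraction fires at a random time inside the window and completes
#' between two consecutive 2 ms frames.
#'
#' @param seed Integer seed.
#' @param diameter_um Spheroplast diameter (default 3).
#' @param optics An [optics_config()].
#' @return `list(sim =, stack =)`.
#' @export
simulate_highspeed_contraction <- function(seed, diameter_um = 3,
                                           optics = optics_config()) {
  geom <- cell_geometry("spheroplast", diameter_um = diameter_um)
  set.seed(seed)
  dwell <- stats::runif(1, 0.5, 4)
  cfg <- simulation_config(
    geometry = geom, mechanism = "distal",
    extension_dwell_s = dwell, disassembly_delay_s = 60,
    frame_interval_s = 0.002, duration_s = 5, seed = seed + 1L,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0,
                        initial_length_um = diameter_um)))
  sim <- simulate_sheaths(cfg)
  stack <- render_stack(sim, optics)
  list(sim = sim, stack = stack)
}

#' Mechanism recovery over seeded replicates
#'
#' Simulates `n` photobleach-chase events under one mechanism and runs the
#' full analysis on each.
#'
#' @param mechanism `"distal"`, `"proximal"` or `"intercalation"`.
#' @param n Number of events.
#' @param seed Base seed; event `i` uses `seed + i`.
#' @param noiseless Disable camera noise.
#' @param ... Passed to [simulate_chase_event()].
#' @return Data frame with `seed`, `label`, `drift_nm_per_s`,
#'   `width_change`, `intensity_change_pct`, `v_a_pre`, `v_a_post`,
#'   `r_squared_pre`, `r_squared_post`.
#' @export
mechanism_recovery <- function(mechanism, n, seed = 0, noiseless = FALSE,
                               ...) {
  rows <- lapply(seq_len(n), function(i) {
    ev <- simulate_chase_event(mechanism, seed = seed + i,
                               noiseless = noiseless, ...)
    rep <- run_bleach_chase(ev$stack)
    data.frame(
      seed = seed + i,
      label = if (rep$status == "ok") rep$call$label else "rejected",
      drift_nm_per_s = if (rep$status == "ok")
        rep$call$bleached_drift_nm_per_s else NA_real_,
      width_change = if (rep$status == "ok")
        rep$call$bleached_width_change_fraction else NA_real_,
      intensity_change_pct = if (rep$status == "ok")
        rep$call$bleached_intensity_change_pct else NA_real_,
      v_a_pre = if (!is.null(rep$speed_pre)) rep$speed_pre$v_a_nm_per_s
        else NA_real_,
      v_a_post = if (!is.null(rep$speed_post)) rep$speed_post$v_a_nm_per_s
        else NA_real_,
      r_squared_pre = if (!is.null(rep$speed_pre)) rep$speed_pre$r_squared
        else NA_real_,
      r_squared_post = if (!is.null(rep$speed_post)) rep$speed_post$r_squared
        else NA_real_)
  })
  do.call(rbind, rows)
}

#' Speed recovery over seeded replicates
#'
#' @param v_a_nm_per_s True speed.
#' @param n Number of replicates.
#' @param seed Base seed.
#' @param ... Passed to [simulate_speed_event()].
#' @return Data frame with `seed`, `v_a_hat`, `r_squared`.
#' @export
speed_recovery <- function(v_a_nm_per_s, n, seed = 0, ...) {
  rows <- lapply(seq_len(n), function(i) {
    ev <- simulate_speed_event(v_a_nm_per_s, seed = seed + i, ...)
    sp <- measure_speed(ev$stack)
    data.frame(seed = seed + i, v_a_hat = sp$v_a_nm_per_s,
               r_squared = sp$r_squared)
  })
  do.call(rbind, rows)
}

#' Contraction recovery over seeded replicates
#'
#' Simulates contraction acquisitions at 2 s per frame and measures the
#' remaining length fraction of each detected event.
#'
#' @param n Number of replicates.
#' @param seed Base seed.
#' @param ... Passed to [simulate_contraction_event()].
#' @return Data frame with `seed`, `L_ext_um`, `L_contr_um`,
#'   `remaining_fraction`, `truth_fraction`.
#' @export
contraction_recovery <- function(n, seed = 0, ...) {
  rows <- list()
  for (i in seq_len(n)) {
    ev <- simulate_contraction_event(seed = seed + i, ...)
    events <- detect_contraction_events(ev$stack)
    contr <- ev$sim$events[ev$sim$events$event == "contraction", ]
    ext <- ev$sim$events[ev$sim$events$event == "extended", ]
    truth_frac <- if (nrow(contr) && nrow(ext))
      contr$length_um[1] / ext$length_um[1] else NA_real_
    if (nrow(events) >= 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed + i, L_ext_um = events$L_ext_um[1],
        L_contr_um = events$L_contr_um[1],
        remaining_fraction = events$remaining_fraction[1],
        truth_fraction = truth_frac)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(0), L_ext_um = numeric(0),
               L_contr_um = numeric(0), remaining_fraction = numeric(0),
               truth_fraction = numeric(0))
}
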