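# Shared fixtures, built in code at test time.

# A tiny noiseless optics setup for fast, exact rendering checks.
quiet_optics <- function(...) {
  optics_config(shot_noise = FALSE, read_noise_sd = 0, camera_offset = 100,
                ...)
}

# A bare front_trace for regression-level tests.
make_trace <- function(times_s, front_nm, spacing_nm = 65) {
  out <- data.frame(frame = seq_along(times_s), time_s = times_s,
                    front_nm = front_nm, valid = !is.na(front_nm))
  attr(out, "spacing_nm") <- spacing_nm
  class(out) <- c("front_trace", "data.frame")
  out
}

# A synthetic stack from a list of frame matrices.
make_stack <- function(frames, frame_interval_s = 2, pixel_size_nm = 65,
                       ...) {
  image_stack(frames, frame_interval_s = frame_interval_s,
              pixel_size_nm = pixel_size_nm, ...)
}

# One-sheath growth simulation along the x diameter of a spheroplast.
grow_sim <- function(seed, v_a = 55, diameter = 4, duration = 60,
                     mechanism = "distal", frame_interval = 2, ...) {
  geom <- cell_geometry("spheroplast", diameter_um = diameter)
  cfg <- simulation_config(
    geometry = geom, mechanism = mechanism, v_a_mean_nm_per_s = v_a,
    frame_interval_s = frame_interval, duration_s = duration, seed = seed,
    sheaths = list(list(anchor_angle = pi, target_angle = 0,
                        t_nucleation_s = 0)), ...)
  simulate_sheaths(cfg)
}

final_sheath <- function(sim, id = 1) {
  for (sh in sim$frames[[length(sim$frames)]]) if (sh$id == id) return(sh)
  NULL
}
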