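# Forward simulator of T6SS sheath life cycles: nucleation at a membrane
# anchor, polymerization along a straight chord under one of three candidate
# assembly mechanisms, instantaneous contraction toward the anchor, and
# disassembly. The polymer is modelled as a stack of rings at a fixed pitch;
# each ring carries the relative brightness of the soluble subunits it was
# built from, which is what a photobleach-chase experiment reads out.

# Ring pitch of the modelled sheath polymer, um. Far below the pixel size
# (65 nm), so the exact value does not affect rendered images.
RING_PITCH_UM <- 0.01

#' Soluble fluorophore pool
#'
#' State of the cytosolic pool of free sheath subunits. `soluble_brightness`
#' is the relative fluorescence of a subunit drawn from the pool (1 before any
#' photobleach); newly added rings inherit the pool brightness at the moment
#' they are added. Photobleaching is irreversible, so pool brightness only
#' ever decreases.
#'
#' @param soluble_brightness Relative fluorescence of free subunits, in
#'   `[0, 1]`.
#' @param pool_size Number of free subunits, in ring equivalents. `Inf`
#'   (default) models an unlimited pool; a finite pool halts polymerization
#'   when exhausted.
#' @return An object of class `fluorophore_pool`.
#' @export
fluorophore_pool <- function(soluble_brightness = 1, pool_size = Inf) {
  stopifnot(soluble_brightness >= 0, soluble_brightness <= 1, pool_size >= 0)
  structure(list(soluble_brightness = soluble_brightness,
                 pool_size = pool_size),
            class = "fluorophore_pool")
}

#' Photobleach event
#'
#' A laser swept along a line segment between `line_start_um` and
#' `line_end_um`. The bleached zone is modelled as a Gaussian line profile:
#' a ring at perpendicular distance `d` from the segment keeps the brightness
#' fraction `polymer_survival + (1 - polymer_survival) * (1 - exp(-d^2 /
#' (2 * sigma^2)))` with `sigma = footprint_fwhm_um / 2.3548`, i.e. full
#' bleaching at the line centre falling off to no effect far away. The
#' soluble pool, which diffuses through the illuminated region, is bleached
#' uniformly by the factor `pool_survival`, producing the "dim" subunits that
#' build the post-bleach sheath sections.
#'
#' @param t_bleach_s Bleach time, seconds from acquisition start.
#' @param line_start_um,line_end_um Numeric length-2 endpoints of the bleach
#'   line, um.
#' @param footprint_fwhm_um Full width at half maximum of the bleached zone
#'   (default 0.8 um).
#' @param polymer_survival Residual brightness factor for rings at the line
#'   centre (default 0: complete bleaching).
#' @param pool_survival Residual brightness factor for the soluble pool
#'   (default 0.4: partial bleaching).
#' @return An object of class `bleach_event`.
#' @export
bleach_event <- function(t_bleach_s, line_start_um, line_end_um,
                         footprint_fwhm_um = 0.8, polymer_survival = 0,
                         pool_survival = 0.4) {
  stopifnot(length(line_start_um) == 2, length(line_end_um) == 2)
  if (sum((line_end_um - line_start_um)^2) == 0)
    stop("degenerate bleach line: start and end coincide")
  stopifnot(footprint_fwhm_um > 0,
            polymer_survival >= 0, polymer_survival <= 1,
            pool_survival >= 0, pool_survival <= 1)
  structure(list(t_bleach_s = t_bleach_s,
                 line_start_um = as.numeric(line_start_um),
                 line_end_um = as.numeric(line_end_um),
                 footprint_fwhm_um = footprint_fwhm_um,
                 polymer_survival = polymer_survival,
                 pool_survival = pool_survival),
            class = "bleach_event")
}

#' Simulation configuration
#'
#' Conditions of one simulated acquisition. Sheaths either nucleate at random
#' (`nucleation_rate_per_min` > 0: Poisson events at uniformly random membrane
#' anchors, growing along the chord toward a second uniformly random membrane
#' point) or are specified explicitly through `sheaths`, a list of lists with
#' fields `anchor_angle` (polar angle of the baseplate on the membrane),
#' `target_angle` (polar angle of the membrane point the chord aims at;
#' defaults to the antipode), `t_nucleation_s`, optional `v_a_nm_per_s`, and
#' optional `initial_length_um` (polymer already present at simulation start,
#' built at brightness 1).
#'
#' @param geometry A [cell_geometry()].
#' @param mechanism Assembly mechanism: `"distal"` (new rings added at the end
#'   away from the anchor), `"proximal"` (new rings inserted at the anchor,
#'   pushing existing rings outward) or `"intercalation"` (new rings inserted
#'   at uniformly random positions along the polymer).
#' @param v_a_mean_nm_per_s,v_a_sd_nm_per_s Polymerization speed distribution,
#'   nm/s. Defaults 38 and 0.
#' @param contraction_fraction Remaining length fraction after contraction
#'   (default 0.5), jittered per event by a Gaussian of sd
#'   `contraction_fraction_sd` (default 0.03).
#' @param contraction_fraction_sd See above.
#' @param nucleation_rate_per_min Expected nucleation events per cell per
#'   minute (default 0).
#' @param extension_dwell_s Time a fully extended sheath persists before
#'   contracting. Default `Inf` (no contraction), so that assembly-phase
#'   analyses see the complete growth curve; set finite to study contraction.
#' @param disassembly_delay_s Time a contracted sheath persists before
#'   disassembly starts (default 30 s).
#' @param disassembly_tau_s Exponential time constant of contracted-sheath
#'   brightness decay during disassembly (default 15 s).
#' @param frame_interval_s Simulation step and frame interval, s (default 2).
#' @param duration_s Total simulated time, s (default 120).
#' @param bleach Optional [bleach_event()].
#' @param pool Initial [fluorophore_pool()].
#' @param sheaths Optional list of explicit sheath specifications (see above).
#' @param seed Integer random seed; required, so that every simulation is
#'   reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry,
                              mechanism = c("distal", "proximal",
                                            "intercalation"),
                              v_a_mean_nm_per_s = 38, v_a_sd_nm_per_s = 0,
                              contraction_fraction = 0.5,
                              contraction_fraction_sd = 0.03,
                              nucleation_rate_per_min = 0,
                              extension_dwell_s = Inf,
                              disassembly_delay_s = 30,
                              disassembly_tau_s = 15,
                              frame_interval_s = 2, duration_s = 120,
                              bleach = NULL, pool = fluorophore_pool(),
                              sheaths = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!inherits(geometry, "cell_geometry")) stop("`geometry` must be a cell_geometry")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be positive")
  if (contraction_fraction <= 0 || contraction_fraction >= 1)
    stop("`contraction_fraction` must be in (0, 1)")
  if (nucleation_rate_per_min < 0) stop("rates must be >= 0")
  if (is.null(seed)) stop("`seed` is required for a reproducible simulation")
  if (!is.null(bleach)) {
    stopifnot(inherits(bleach, "bleach_event"))
    if (bleach$t_bleach_s < 0 || bleach$t_bleach_s > duration_s)
      stop("bleach time outside the acquisition window")
  }
  structure(list(geometry = geometry, mechanism = mechanism,
                 v_a_mean_nm_per_s = v_a_mean_nm_per_s,
                 v_a_sd_nm_per_s = v_a_sd_nm_per_s,
                 contraction_fraction = contraction_fraction,
                 contraction_fraction_sd = contraction_fraction_sd,
                 nucleation_rate_per_min = nucleation_rate_per_min,
                 extension_dwell_s = extension_dwell_s,
                 disassembly_delay_s = disassembly_delay_s,
                 disassembly_tau_s = disassembly_tau_s,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, bleach = bleach, pool = pool,
                 sheaths = sheaths, seed = as.integer(seed)),
            class = "simulation_config")
}

# Construct an empty sheath truth object.
new_sheath <- function(id, anchor_um, direction, chord_um, v_a_nm_per_s,
                       t_nucleation_s, mechanism) {
  structure(list(id = id, anchor_um = anchor_um,
                 direction = direction / sqrt(sum(direction^2)),
                 chord_um = chord_um, v_a_nm_per_s = v_a_nm_per_s,
                 t_nucleation_s = t_nucleation_s, mechanism = mechanism,
                 ring_positions_um = numeric(0),
                 ring_brightness = numeric(0),
                 growth_debt_um = 0, phase = "assembling",
                 t_extended_s = NA_real_, t_contracted_s = NA_real_,
                 initial_total_brightness = NA_real_),
            class = "sheath_truth")
}

sheath_length_um <- function(sheath) {
  n <- length(sheath$ring_positions_um)
  if (n == 0) 0 else max(sheath$ring_positions_um)
}

#' Advance the assembly of one sheath by one time step
#'
#' Adds `v_a * dt` of polymer (in whole rings at the modelled ring pitch,
#' carrying fractional remainders between steps), capped at the chord length
#' available inside the cell. New rings carry the current pool brightness.
#' Where the new rings go depends on the mechanism: appended at the distal
#' end (`"distal"`), inserted at the anchor so that all pre-existing rings
#' move outward (`"proximal"`), or inserted at uniformly random positions
#' along the polymer (`"intercalation"`). Ring positions are always
#' `(0, pitch, 2*pitch, ...)` from the anchor; mechanisms differ only in the
#' ordering of ring identities (their brightness values).
#'
#' @param sheath A sheath truth object in phase `"assembling"`.
#' @param pool A [fluorophore_pool()].
#' @param dt Time step, s (> 0).
#' @return `list(sheath =, pool =)`, both updated.
#' @export
step_assembly <- function(sheath, pool, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  if (sheath$phase != "assembling") stop("sheath is not assembling")
  pitch <- RING_PITCH_UM
  debt <- sheath$growth_debt_um + sheath$v_a_nm_per_s * dt / 1000
  n_cur <- length(sheath$ring_brightness)
  n_max <- floor(sheath$chord_um / pitch) + 1
  n_new <- floor(debt / pitch)
  capped <- FALSE
  if (n_cur + n_new >= n_max) {
    n_new <- max(n_max - n_cur, 0)
    capped <- TRUE
  }
  if (is.finite(pool$pool_size) && n_new > pool$pool_size) {
    n_new <- floor(pool$pool_size)
  }
  if (n_new > 0) {
    b_new <- rep(pool$soluble_brightness, n_new)
    b <- sheath$ring_brightness
    if (sheath$mechanism == "distal") {
      b <- c(b, b_new)
    } else if (sheath$mechanism == "proximal") {
      b <- c(b_new, b)
    } else {  # intercalation: each new ring at a uniformly random index
      for (bi in b_new) {
        k <- length(b)
        at <- sample.int(k + 1, 1) - 1  # insert after position `at` in 0..k
        b <- append(b, bi, after = at)
      }
    }
    sheath$ring_brightness <- b
    sheath$ring_positions_um <- (seq_along(b) - 1) * pitch
    if (is.finite(pool$pool_size)) pool$pool_size <- pool$pool_size - n_new
  }
  sheath$growth_debt_um <- if (capped) 0 else debt - n_new * pitch
  if (capped && length(sheath$ring_brightness) >= n_max) {
    sheath$phase <- "extended"
  }
  if (is.finite(pool$pool_size) && pool$pool_size < 1 &&
      sheath$phase == "assembling") {
    sheath$phase <- "extended"  # pool exhausted: growth stops
  }
  list(sheath = sheath, pool = pool)
}

# 2D coordinates of a sheath's rings.
ring_xy <- function(sheath) {
  n <- length(sheath$ring_positions_um)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  cbind(sheath$anchor_um[1] + sheath$direction[1] * sheath$ring_positions_um,
        sheath$anchor_um[2] + sheath$direction[2] * sheath$ring_positions_um)
}

# Distance from points (x, y) to the segment a--b.
point_segment_distance <- function(x, y, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((x - px)^2 + (y - py)^2)
}

#' Apply a photobleach event to sheaths and pool
#'
#' Ring brightness is multiplied by the Gaussian-profile survival factor of
#' the bleach footprint (see [bleach_event()]); the soluble pool brightness is
#' multiplied by `pool_survival`. Both effects are irreversible.
#'
#' @param sheaths List of sheath truth objects.
#' @param pool A [fluorophore_pool()].
#' @param event A [bleach_event()].
#' @return `list(sheaths =, pool =)`, both updated.
#' @export
apply_photobleach <- function(sheaths, pool, event) {
  stopifnot(inherits(event, "bleach_event"))
  sigma <- event$footprint_fwhm_um / (2 * sqrt(2 * log(2)))
  sheaths <- lapply(sheaths, function(sh) {
    if (length(sh$ring_brightness) == 0) return(sh)
    xy <- ring_xy(sh)
    d <- point_segment_distance(xy[, 1], xy[, 2],
                                event$line_start_um, event$line_end_um)
    survival <- event$polymer_survival +
      (1 - event$polymer_survival) * (1 - exp(-d^2 / (2 * sigma^2)))
    sh$ring_brightness <- sh$ring_brightness * survival
    sh
  })
  pool$soluble_brightness <- pool$soluble_brightness * event$pool_survival
  list(sheaths = sheaths, pool = pool)
}

#' Contract a sheath toward its anchor
#'
#' Every ring position is scaled by `fraction` toward the (static) anchor;
#' ring brightness values are untouched, so the summed polymer brightness is
#' conserved and the fluorescence density per unit length increases.
#'
#' @param sheath A sheath truth object in phase `"assembling"` or
#'   `"extended"`.
#' @param fraction Remaining length fraction, in (0, 1).
#' @return The contracted sheath (phase `"contracted"`).
#' @export
contract_sheath <- function(sheath, fraction) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)")
  if (!sheath$phase %in% c("assembling", "extended"))
    stop("only assembling or extended sheaths can contract")
  sheath$ring_positions_um <- sheath$ring_positions_um * fraction
  sheath$phase <- "contracted"
  sheath
}

#' Simulate sheath life cycles in a cell
#'
#' Runs the forward model at the frame interval of the configuration:
#' nucleation (explicit or Poisson), per-step assembly under the configured
#' mechanism, an optional photobleach applied between the frames bracketing
#' the bleach time, instantaneous contraction after the extension dwell, and
#' exponential disassembly after the disassembly delay. Deterministic given
#' the seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `sheath_sim`: a list with `times_s`, `frames`
#'   (one snapshot per frame: a list of per-sheath states with `id`,
#'   `anchor_um`, `direction`, `ring_positions_um`, `ring_brightness`,
#'   `phase`), `pool_series` (data frame `time_s`, `soluble_brightness`),
#'   `events` (data frame `time_s`, `sheath_id`, `event`, `length_um`),
#'   `geometry` and `config`.
#' @export
simulate_sheaths <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  geom <- config$geometry
  dt <- config$frame_interval_s
  times <- seq(0, config$duration_s, by = dt)
  pool <- config$pool
  sheaths <- list()     # active + finished sheath states
  pending <- list()     # explicit sheaths not yet nucleated
  events <- list()
  next_id <- 1L
  add_event <- function(t, id, what, len) {
    events[[length(events) + 1L]] <<- data.frame(
      time_s = t, sheath_id = id, event = what, length_um = len)
  }

  make_explicit <- function(spec) {
    anchor <- membrane_point(geom, spec$anchor_angle)
    target_angle <- if (!is.null(spec$target_angle)) spec$target_angle else
      spec$anchor_angle + pi
    target <- membrane_point(geom, target_angle)
    dir <- target - anchor
    chord <- chord_length(geom, anchor, dir)
    if (chord <= 0) stop("explicit sheath has zero available chord")
    v <- if (!is.null(spec$v_a_nm_per_s)) spec$v_a_nm_per_s else
      config$v_a_mean_nm_per_s
    sh <- new_sheath(next_id, anchor, dir, chord, v,
                     spec$t_nucleation_s, config$mechanism)
    next_id <<- next_id + 1L
    if (!is.null(spec$initial_length_um) && spec$initial_length_um > 0) {
      n0 <- min(floor(spec$initial_length_um / RING_PITCH_UM) + 1,
                floor(chord / RING_PITCH_UM) + 1)
      sh$ring_brightness <- rep(1, n0)
      sh$ring_positions_um <- (seq_len(n0) - 1) * RING_PITCH_UM
    }
    sh
  }
  for (spec in (config$sheaths %||% list())) {
    sh <- make_explicit(spec)
    if (sh$t_nucleation_s <= 0) {
      sheaths[[length(sheaths) + 1L]] <- sh
      add_event(sh$t_nucleation_s, sh$id, "nucleation", sheath_length_um(sh))
    } else {
      pending[[length(pending) + 1L]] <- sh
    }
  }

  frames <- vector("list", length(times))
  pool_series <- data.frame(time_s = times,
                            soluble_brightness = NA_real_)
  bleached <- FALSE
  snapshot <- function() {
    lapply(sheaths, function(sh)
      list(id = sh$id, anchor_um = sh$anchor_um, direction = sh$direction,
           ring_positions_um = sh$ring_positions_um,
           ring_brightness = sh$ring_brightness, phase = sh$phase,
           chord_um = sh$chord_um, v_a_nm_per_s = sh$v_a_nm_per_s,
           t_nucleation_s = sh$t_nucleation_s))
  }

  for (fi in seq_along(times)) {
    t <- times[fi]
    if (fi > 1) {
      # 1. nucleation due in (t - dt, t]
      keep <- logical(length(pending))
      for (pk in seq_along(pending)) {
        if (pending[[pk]]$t_nucleation_s <= t) {
          sh <- pending[[pk]]
          sheaths[[length(sheaths) + 1L]] <- sh
          add_event(sh$t_nucleation_s, sh$id, "nucleation", 0)
        } else keep[pk] <- TRUE
      }
      pending <- pending[keep]
      if (config$nucleation_rate_per_min > 0) {
        n_nuc <- stats::rpois(1, config$nucleation_rate_per_min * dt / 60)
        for (k in seq_len(n_nuc)) {
          # anchors are uniform on the membrane; growth aims near the
          # antipodal membrane point (sheaths typically polymerize across
          # the whole cell), with angular jitter around it
          a_ang <- stats::runif(1, 0, 2 * pi)
          t_ang <- a_ang + pi + stats::rnorm(1, 0, 0.8)
          anchor <- membrane_point(geom, a_ang)
          dir <- membrane_point(geom, t_ang) - anchor
          if (sum(dir^2) < 1e-6) next  # degenerate chord; skip this attempt
          chord <- chord_length(geom, anchor, dir)
          if (chord < 10 * RING_PITCH_UM) next
          v <- max(stats::rnorm(1, config$v_a_mean_nm_per_s,
                                config$v_a_sd_nm_per_s), 1)
          sh <- new_sheath(next_id, anchor, dir, chord, v, t, config$mechanism)
          next_id <- next_id + 1L
          sheaths[[length(sheaths) + 1L]] <- sh
          add_event(t, sh$id, "nucleation", 0)
        }
      }
      # 2. assembly / contraction / disassembly
      for (si in seq_along(sheaths)) {
        sh <- sheaths[[si]]
        if (sh$phase == "assembling") {
          res <- step_assembly(sh, pool, dt)
          sh <- res$sheath
          pool <- res$pool
          if (sh$phase == "extended") {
            sh$t_extended_s <- t
            sh$initial_total_brightness <- sum(sh$ring_brightness)
            add_event(t, sh$id, "extended", sheath_length_um(sh))
          }
        } else if (sh$phase == "extended") {
          if (is.na(sh$t_extended_s)) sh$t_extended_s <- t
          if (is.finite(config$extension_dwell_s) &&
              t - sh$t_extended_s >= config$extension_dwell_s) {
            frac <- stats::rnorm(1, config$contraction_fraction,
                                 config$contraction_fraction_sd)
            frac <- min(max(frac, 0.05), 0.95)
            len_before <- sheath_length_um(sh)
            sh <- contract_sheath(sh, frac)
            sh$t_contracted_s <- t
            add_event(t, sh$id, "contraction", sheath_length_um(sh))
          }
        } else if (sh$phase == "contracted") {
          if (t - sh$t_contracted_s >= config$disassembly_delay_s) {
            sh$phase <- "disassembling"
            add_event(t, sh$id, "disassembly", sheath_length_um(sh))
          }
        } else if (sh$phase == "disassembling") {
          sh$ring_brightness <- sh$ring_brightness *
            exp(-dt / config$disassembly_tau_s)
          tot0 <- sh$initial_total_brightness
          if (!is.na(tot0) && sum(sh$ring_brightness) < 0.01 * tot0) {
            sh$phase <- "gone"
            sh$ring_brightness <- numeric(0)
            sh$ring_positions_um <- numeric(0)
            add_event(t, sh$id, "gone", 0)
          }
        }
        sheaths[[si]] <- sh
      }
    }
    # explicit sheaths pre-extended at start
    if (fi == 1) {
      for (si in seq_along(sheaths)) {
        sh <- sheaths[[si]]
        if (sh$phase == "assembling" &&
            length(sh$ring_brightness) >= floor(sh$chord_um / RING_PITCH_UM) + 1) {
          sh$phase <- "extended"
          sh$t_extended_s <- 0
          sh$initial_total_brightness <- sum(sh$ring_brightness)
          sheaths[[si]] <- sh
        }
      }
    }
    frames[[fi]] <- snapshot()
    pool_series$soluble_brightness[fi] <- pool$soluble_brightness
    # 3. photobleach fires after the frame at/just before its time is recorded
    if (!bleached && !is.null(config$bleach) && t >= config$bleach$t_bleach_s) {
      res <- apply_photobleach(sheaths, pool, config$bleach)
      sheaths <- res$sheaths
      pool <- res$pool
      bleached <- TRUE
      add_event(t, NA_integer_, "bleach", NA_real_)
    }
  }

  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), sheath_id = integer(0),
               event = character(0), length_um = numeric(0))
  structure(list(times_s = times, frames = frames, pool_series = pool_series,
                 events = events_df, geometry = geom, config = config),
            class = "sheath_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sheath_sim <- function(x, ...) {
  cat(sprintf("<sheath_sim> %d frames at %.4g s/frame, %d sheath(s), %d event(s)\n",
              length(x$times_s), x$config$frame_interval_s,
              length(x$frames[[length(x$frames)]]),
              nrow(x$events)))
  invisible(x)
}

#' Per-frame sheath lengths from a simulation
#'
#' @param sim A `sheath_sim`.
#' @return Data frame with `time_s`, `sheath_id`, `length_um`, `phase`,
#'   `total_brightness`.
#' @export
truth_lengths <- function(sim) {
  rows <- list()
  for (fi in seq_along(sim$frames)) {
    for (sh in sim$frames[[fi]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = sim$times_s[fi], sheath_id = sh$id,
        length_um = if (length(sh$ring_positions_um))
          max(sh$ring_positions_um) else 0,
        phase = sh$phase,
        total_brightness = sum(sh$ring_brightness))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), sheath_id = integer(0),
               length_um = numeric(0), phase = character(0),
               total_brightness = numeric(0))
}

#' Line along a simulated sheath's chord
#'
#' Convenience for analysing synthetic data: the kymograph line from the
#' sheath's anchor to the end of its available chord, known from simulation
#' ground truth (real data requires a manually drawn line).
#'
#' @param sim A `sheath_sim`.
#' @param sheath_id Sheath id (default 1).
#' @return `list(start_um =, end_um =)`.
#' @export
truth_line <- function(sim, sheath_id = 1) {
  for (sh in sim$frames[[length(sim$frames)]]) {
    if (sh$id == sheath_id) {
      return(list(start_um = sh$anchor_um,
                  end_um = sh$anchor_um + sh$direction * sh$chord_um))
    }
  }
  stop("sheath_id not found in simulation")
}
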