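# Photobleach-chase analysis: after partially bleaching a polymerizing
# sheath, the fate of the bleached mark distinguishes where new subunits are
# added. If the mark stays fixed in position, size and (near-zero) intensity,
# subunits add at the distal end; if it moves away from the assembly origin
# at the polymerization speed, subunits insert at the baseplate; if it
# stretches and its intensity rises toward the dim level, subunits
# intercalate along the polymer.

#' Analysis thresholds for the photobleach chase
#'
#' @param bright_floor A bin counts as "bright" when its intensity is at
#'   least this fraction of the pre-bleach on-polymer level (default 0.7).
#' @param bleach_k A bin counts as "bleached" when its intensity is at most
#'   `background mean + bleach_k * background sd` (default 2).
#' @param drift_frac Drift tolerance for a stationary bleached mark, as a
#'   fraction of the measured polymerization speed (default 0.2).
#' @param width_tol Relative width-change tolerance (default 0.3).
#' @param intensity_rise_min Minimum normalized-intensity rise (percentage
#'   points) counted as dilution of the bleached mark (default 5).
#' @param min_bins Minimum section length in distance bins (default 2).
#' @param min_speed_nm_per_s Minimum regression slope accepted as "still
#'   polymerizing" in the eligibility test (default 10).
#' @return A list of thresholds.
#' @export
chase_thresholds <- function(bright_floor = 0.7, bleach_k = 2,
                             drift_frac = 0.2, width_tol = 0.3,
                             intensity_rise_min = 5, min_bins = 2,
                             min_speed_nm_per_s = 10) {
  list(bright_floor = bright_floor, bleach_k = bleach_k,
       drift_frac = drift_frac, width_tol = width_tol,
       intensity_rise_min = intensity_rise_min, min_bins = min_bins,
       min_speed_nm_per_s = min_speed_nm_per_s)
}

#' Measurement time points of the chase
#'
#' The four canonical measurement times: directly before the bleach (`t1`),
#' directly after it (`t2`, one frame later), 20 s before the end of
#' assembly (`t3`) and the end of assembly itself (`t4`). `t3` is dropped
#' with a warning when post-bleach assembly lasts less than 20 s.
#'
#' @param t_bleach_s Bleach time, s.
#' @param t_end_s End of assembly, s.
#' @param frame_interval_s Frame interval, s.
#' @return List with `t1`, `t2`, `t3` (possibly NA), `t4`.
#' @export
chase_timepoints <- function(t_bleach_s, t_end_s, frame_interval_s) {
  t1 <- t_bleach_s
  t2 <- t_bleach_s + frame_interval_s
  t3 <- t_end_s - 20
  t4 <- t_end_s
  if (t3 <= t2) {
    warning("post-bleach assembly shorter than 20 s; dropping timepoint t3")
    t3 <- NA_real_
  }
  if (!(t1 < t2 && t2 < t4)) stop("invalid timepoint ordering")
  list(t1 = t1, t2 = t2, t3 = t3, t4 = t4)
}

#' Mean pre-bleach on-polymer intensity
#'
#' The 100% reference of the intensity normalization: the mean kymogram
#' intensity over bins well inside the polymer (at least `margin_bins` from
#' the front) in valid frames before the bleach.
#'
#' @param kym An oriented `kymogram`.
#' @param trace A [trace_front()] result for `kym`.
#' @param t_bleach_s Bleach time, s.
#' @param margin_bins Bins excluded next to the front (default 3).
#' @return Mean intensity (camera counts).
#' @export
prebleach_level <- function(kym, trace, t_bleach_s, margin_bins = 3) {
  vals <- c()
  for (t in which(trace$valid & trace$time_s <= t_bleach_s)) {
    fbin <- floor(trace$front_nm[t] / kym$spacing_nm) + 1
    if (fbin - margin_bins < 1) next
    vals <- c(vals, kym$values[1:(fbin - margin_bins), t])
  }
  if (length(vals) == 0) stop("no pre-bleach on-polymer pixels")
  mean(vals)
}

#' Test whether a bleach-chase event is analysable
#'
#' An event qualifies when the sheath (i) was polymerizing before the bleach,
#' (ii) was only partially bleached (a below-background span strictly inside
#' the above-background extent just after the bleach), and (iii) kept
#' polymerizing in the same direction afterwards.
#'
#' @param kym An oriented `kymogram`.
#' @param t_bleach_s Bleach time, s.
#' @param background Background spec (see [locate_origin()]).
#' @param thresholds A [chase_thresholds()].
#' @param trace Optional precomputed [trace_front()].
#' @param t_end_s Optional end of assembly; the post-bleach speed regression
#'   stops there rather than running over the plateau.
#' @return List with `eligible` (logical), `reasons` (character vector of
#'   failures, empty when eligible), `speed_pre`, `speed_post`
#'   ([estimate_speed()] results or NULL).
#' @export
eligible_for_chase <- function(kym, t_bleach_s, background,
                               thresholds = chase_thresholds(),
                               trace = NULL, t_end_s = Inf) {
  bg <- resolve_background(background, ncol(kym$values))
  if (is.null(trace)) {
    trace <- tryCatch(trace_front(kym, bg), error = function(e) NULL)
  }
  reasons <- character(0)
  speed_pre <- speed_post <- NULL
  if (is.null(trace)) {
    reasons <- c(reasons, "not polymerizing pre-bleach",
                 "not polymerizing post-bleach")
  } else {
    speed_pre <- tryCatch(
      estimate_speed(trace, window = c(-Inf, t_bleach_s)),
      error = function(e) NULL)
    if (is.null(speed_pre) ||
        speed_pre$v_a_nm_per_s < thresholds$min_speed_nm_per_s) {
      reasons <- c(reasons, "not polymerizing pre-bleach")
    }
    speed_post <- tryCatch(
      estimate_speed(trace, window = c(t_bleach_s + kym$frame_interval_s,
                                       t_end_s)),
      error = function(e) NULL)
    if (is.null(speed_post) ||
        speed_post$v_a_nm_per_s < thresholds$min_speed_nm_per_s) {
      reasons <- c(reasons, "not polymerizing post-bleach")
    }
  }
  # Partial bleach: in the averaged first post-bleach frames, an
  # origin-anchored above-background run must be followed, beyond a gap of
  # at least min_bins, by a second above-background run: polymer signal
  # survives on both sides of the bleached span. A fully bleached sheath
  # leaves either no origin-side remnant or no second run.
  post_cols <- which(kym$times_s > t_bleach_s)[1:2]
  post_cols <- post_cols[!is.na(post_cols)]
  if (length(post_cols) == 0) {
    reasons <- c(reasons, "no frames after bleach")
  } else {
    prof <- rowMeans(kym$values[, post_cols, drop = FALSE])
    bgm <- mean(bg$mean[post_cols])
    bgs <- mean(bg$sd[post_cols]) * kym_sd_scale(kym)
    # like the bleached cutoff, the run-detection threshold keeps a floor
    # proportional to the polymer signal so that near-noise-free data does
    # not count the faint PSF bleed inside the bleached span as polymer
    amp <- tryCatch(
      prebleach_level(kym, trace, t_bleach_s) -
        mean(bg$mean[kym$times_s <= t_bleach_s]),
      error = function(e) NA_real_)
    thr_run <- bgm + max(3 * bgs, if (is.na(amp)) 0 else 0.15 * amp)
    runs <- bridged_runs(prof > thr_run)
    runs <- runs[runs$length >= 2, , drop = FALSE]
    if (nrow(runs) == 0 || runs$start[1] > 5) {
      reasons <- c(reasons, "not partial: no origin-side polymer signal")
    } else if (nrow(runs) < 2 ||
               runs$start[2] - runs$end[1] - 1 < thresholds$min_bins) {
      reasons <- c(reasons, "not partial: no interior bleached span")
    }
  }
  list(eligible = length(reasons) == 0, reasons = reasons,
       speed_pre = speed_pre, speed_post = speed_post)
}

#' Classify sheath sections after a partial photobleach
#'
#' Each distance bin is averaged over the post-bleach frames in which it lies
#' inside the polymer (origin side of the front), then assigned a class:
#' `"bleached"` at or below the background plus `bleach_k` standard
#' deviations, `"bright"` at or above `bright_floor` of the pre-bleach
#' on-polymer level, `"dim"` in between. Adjacent same-class bins merge into
#' maximal spans; spans shorter than `min_bins` are discarded.
#'
#' @param kym An oriented `kymogram`.
#' @param t_bleach_s,t_end_s Bleach time and end of assembly, s.
#' @param background Background spec.
#' @param pre_level Pre-bleach on-polymer intensity ([prebleach_level()]).
#' @param thresholds A [chase_thresholds()].
#' @param trace Optional precomputed [trace_front()].
#' @return Data frame of sections: `klass`, `bin_lo`, `bin_hi`, `d_lo_nm`,
#'   `d_hi_nm`, `mean_intensity`.
#' @export
classify_sections <- function(kym, t_bleach_s, t_end_s, background, pre_level,
                              thresholds = chase_thresholds(), trace = NULL) {
  bg <- resolve_background(background, ncol(kym$values))
  if (is.null(trace)) trace <- trace_front(kym, bg)
  cols <- which(kym$times_s > t_bleach_s & kym$times_s <= t_end_s)
  if (length(cols) < 2) stop("too few post-bleach frames")
  D <- nrow(kym$values)
  mean_int <- rep(NA_real_, D)
  n_obs <- integer(D)
  for (b in seq_len(D)) {
    inside <- cols[trace$valid[cols] &
                     (b - 1) * kym$spacing_nm <= trace$front_nm[cols]]
    if (length(inside) >= 3) {
      mean_int[b] <- mean(kym$values[b, inside])
      n_obs[b] <- length(inside)
    }
  }
  bgm <- mean(bg$mean[cols])
  bgs <- mean(bg$sd[cols]) * kym_sd_scale(kym)
  # pre_level sits on the pre-bleach background, while post-bleach counts sit
  # on the dimmer post-bleach background: thresholds are set relative to the
  # polymer signal amplitude (pre_level - pre-bleach background) added to the
  # current background
  bg_pre <- mean(bg$mean[kym$times_s <= t_bleach_s])
  amp <- pre_level - bg_pre
  thr_bleached <- bgm + max(thresholds$bleach_k * bgs, 0.08 * amp)
  thr_bright <- bgm + thresholds$bright_floor * amp
  klass <- ifelse(is.na(mean_int), NA,
                  ifelse(mean_int <= thr_bleached, "bleached",
                         ifelse(mean_int >= thr_bright, "bright", "dim")))
  # merge runs
  out <- list()
  b <- 1
  while (b <= D) {
    if (is.na(klass[b])) { b <- b + 1; next }
    e <- b
    while (e < D && !is.na(klass[e + 1]) && klass[e + 1] == klass[b]) e <- e + 1
    if (e - b + 1 >= thresholds$min_bins) {
      out[[length(out) + 1L]] <- data.frame(
        klass = klass[b], bin_lo = b, bin_hi = e,
        d_lo_nm = (b - 1) * kym$spacing_nm, d_hi_nm = (e - 1) * kym$spacing_nm,
        mean_intensity = mean(mean_int[b:e]))
    }
    b <- e + 1
  }
  sections <- if (length(out)) do.call(rbind, out) else
    data.frame(klass = character(0), bin_lo = integer(0), bin_hi = integer(0),
               d_lo_nm = numeric(0), d_hi_nm = numeric(0),
               mean_intensity = numeric(0))
  if (!any(sections$klass == "bleached"))
    stop("no bleached span found; event should have failed eligibility")
  sections
}

# Profile at a timepoint: mean of kymogram columns within +/- 1 frame,
# restricted to (t_min, t_max] so that averaging never mixes frames across
# the bleach boundary.
timepoint_profile <- function(kym, t_s, t_min = -Inf, t_max = Inf,
                              halfwidth_frames = 2) {
  idx <- which(abs(kym$times_s - t_s) <=
                 halfwidth_frames * kym$frame_interval_s + 1e-9 &
                 kym$times_s > t_min & kym$times_s <= t_max + 1e-9)
  if (length(idx) == 0) stop("timepoint outside kymogram")
  rowMeans(kym$values[, idx, drop = FALSE])
}

# 3-bin running mean with reflected ends; damps single-bin shot noise before
# span edges are located.
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  (c(v[1], v[-n]) + v + c(v[-1], v[n])) / 3
}

# Contiguous span around the minimum of `v[1:extent]` whose values stay
# within `tol` of that minimum, with the span edges refined to sub-bin
# precision by linear interpolation of the threshold crossing. Tracks the
# bleached mark even when intercalated dim subunits raise its absolute
# intensity.
min_region_span <- function(v, extent, tol) {
  interior <- 2:max(extent - 1, 2)
  m_idx <- interior[which.min(v[interior])]
  thr <- v[m_idx] + tol
  lo <- m_idx
  while (lo > 1 && v[lo - 1] <= thr) lo <- lo - 1
  hi <- m_idx
  while (hi < extent && v[hi + 1] <= thr) hi <- hi + 1
  lo_f <- if (lo > 1 && v[lo - 1] > thr)
    lo - (thr - v[lo]) / (v[lo - 1] - v[lo]) else lo
  hi_f <- if (hi < extent && v[hi + 1] > thr)
    hi + (thr - v[hi]) / (v[hi + 1] - v[hi]) else hi
  c(lo_f, hi_f)
}

#' Track section positions over the chase time points
#'
#' For each time point, locates the bleached mark (the contiguous
#' minimum-intensity region inside the polymer) and the bright section (the
#' longest run at or above the bright floor), and reports the span centroid
#' distance from the origin, the span width and the mean raw and normalized
#' intensities. The bleached mark is undefined at `t1` (pre-bleach) and is
#' reported from `t2` on; the bright section is reported at every defined
#' time point.
#'
#' @param kym An oriented `kymogram`.
#' @param trace A [trace_front()] result.
#' @param tps A [chase_timepoints()] list.
#' @param background Background spec.
#' @param pre_level Pre-bleach on-polymer level.
#' @param thresholds A [chase_thresholds()].
#' @return Data frame with `section`, `timepoint`, `time_s`, `centroid_nm`,
#'   `width_nm`, `mean_intensity`, `intensity_pct`.
#' @export
track_sections <- function(kym, trace, tps, background, pre_level,
                           thresholds = chase_thresholds()) {
  bg <- resolve_background(background, ncol(kym$values))
  bg_pre <- mean(bg$mean[kym$times_s <= tps$t1])
  rows <- list()
  for (tp_name in c("t1", "t2", "t3", "t4")) {
    t_s <- tps[[tp_name]]
    if (is.na(t_s)) next
    ti <- which.min(abs(kym$times_s - t_s))
    if (!trace$valid[ti]) next
    prof <- if (tp_name == "t1") {
      timepoint_profile(kym, t_s, t_max = tps$t1)
    } else {
      timepoint_profile(kym, t_s, t_min = tps$t1)
    }
    extent <- floor(trace$front_nm[ti] / kym$spacing_nm) + 1
    extent <- min(extent, length(prof))
    if (extent < 3) next
    bg_tp <- bg$mean[ti]
    add_row <- function(section, lo, hi, intensity_bins = NULL) {
      i_bins <- intensity_bins %||% (ceiling(lo):floor(hi))
      mi <- mean(prof[i_bins])
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section, timepoint = tp_name, time_s = t_s,
        centroid_nm = ((lo + hi) / 2 - 1) * kym$spacing_nm,
        width_nm = (hi - lo + 1) * kym$spacing_nm,
        mean_intensity = mi,
        intensity_pct = normalize_intensity(mi, bg_tp, pre_level, bg_pre))
    }
    # Bleached mark (post-bleach only): edges located on a lightly smoothed
    # profile so single-bin shot noise does not jitter the span width. The
    # intensity is read from the span core (bins close to the minimum); the
    # outer span bins sit on the shoulders of the bleach footprint and carry
    # residual flanking fluorescence that is not part of the mark proper.
    if (tp_name != "t1") {
      tol <- 0.25 * (pre_level - bg_pre)
      span <- min_region_span(smooth3(prof), extent, tol)
      i_lo <- ceiling(span[1])
      i_hi <- max(floor(span[2]), i_lo)
      sv <- prof[i_lo:i_hi]
      core <- (i_lo:i_hi)[sv <= min(sv) + 0.4 * tol]
      add_row("bleached", span[1], span[2], intensity_bins = core)
    }
    # bright section: longest run at/above the bright floor, with edges
    # refined to the sub-bin threshold crossing
    thr_bright <- bg_tp + thresholds$bright_floor * (pre_level - bg_pre)
    sm <- smooth3(prof)
    runs <- bridged_runs(sm[seq_len(extent)] >= thr_bright)
    runs <- runs[runs$length >= thresholds$min_bins, , drop = FALSE]
    if (nrow(runs) > 0) {
      main <- runs[1, ]  # the origin-nearest fully bright segment
      lo <- main$start
      hi <- main$end
      lo_f <- if (lo > 1 && sm[lo - 1] < thr_bright)
        lo - (sm[lo] - thr_bright) / (sm[lo] - sm[lo - 1]) else lo
      hi_f <- if (hi < extent && sm[hi + 1] < thr_bright)
        hi + (sm[hi] - thr_bright) / (sm[hi] - sm[hi + 1]) else hi
      add_row("bright", lo_f, hi_f)
    }
    # dim section: longest run between the bleached and bright levels
    thr_bleached <- bg_tp + max(
      thresholds$bleach_k * bg$sd[ti] * kym_sd_scale(kym),
      0.08 * (pre_level - bg_pre))
    dim_mask <- prof[seq_len(extent)] > thr_bleached &
      prof[seq_len(extent)] < thr_bright
    runs <- bridged_runs(dim_mask)
    runs <- runs[runs$length >= thresholds$min_bins, , drop = FALSE]
    if (nrow(runs) > 0 && tp_name != "t1") {
      main <- runs[which.max(runs$length), ]
      add_row("dim", main$start, main$end)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(section = character(0), timepoint = character(0),
               time_s = numeric(0), centroid_nm = numeric(0),
               width_nm = numeric(0), mean_intensity = numeric(0),
               intensity_pct = numeric(0))
}

#' Normalize fluorescence intensity to a percent scale
#'
#' Maps the cytosolic background to 0% and the pre-bleach on-polymer level to
#' 100%. The numerator background may differ from the reference background
#' (the cytosol dims when the soluble pool is partially bleached), in which
#' case each is subtracted on its own side. Exactly invariant under affine
#' rescaling of the raw camera counts.
#'
#' @param raw Raw intensity (scalar or vector).
#' @param background Cytosolic background at the measurement time point.
#' @param reference_level Pre-bleach on-polymer intensity (the 100% point).
#' @param reference_background Background at the reference time (defaults to
#'   `background`).
#' @return Intensity in percent.
#' @export
normalize_intensity <- function(raw, background, reference_level,
                                reference_background = background) {
  if (reference_level <= reference_background)
    stop("reference level must exceed background")
  100 * (raw - background) / (reference_level - reference_background)
}

#' Call the assembly mechanism from tracked sections
#'
#' Pure decision function on three pieces of evidence about the bleached
#' mark: its centroid drift (nm/s, positive away from the origin), its
#' relative width change between `t2` and the last time point, and its
#' normalized intensity change over the same interval. A stationary,
#' constant-width mark means distal-end addition; a mark drifting at least
#' `drift_frac` of the measured polymerization speed with constant width
#' means insertion at the baseplate; a widening mark with rising intensity
#' means intercalation; anything else is ambiguous.
#'
#' @param track A [track_sections()] data frame.
#' @param v_a_nm_per_s Measured polymerization speed (sets the drift
#'   tolerance).
#' @param thresholds A [chase_thresholds()].
#' @return An object of class `mechanism_call`: list with `label`,
#'   `bleached_drift_nm_per_s`, `drift_tol_nm_per_s`,
#'   `bleached_width_change_fraction`, `bleached_intensity_change_pct`,
#'   `thresholds`.
#' @export
infer_mechanism <- function(track, v_a_nm_per_s,
                            thresholds = chase_thresholds()) {
  bl <- track[track$section == "bleached", ]
  if (nrow(bl) < 3) stop("insufficient post-bleach timepoints (need >= 3)")
  fit <- stats::lm(centroid_nm ~ time_s, data = bl)
  drift <- unname(stats::coef(fit)[2])
  w2 <- bl$width_nm[bl$timepoint == "t2"]
  wlast <- bl$width_nm[nrow(bl)]
  width_change <- (wlast - w2) / w2
  i2 <- bl$intensity_pct[bl$timepoint == "t2"]
  ilast <- bl$intensity_pct[nrow(bl)]
  intensity_change <- ilast - i2
  drift_tol <- thresholds$drift_frac * v_a_nm_per_s
  label <- if (abs(drift) < drift_tol && abs(width_change) < thresholds$width_tol) {
    "distal"
  } else if (drift >= drift_tol && abs(width_change) < thresholds$width_tol) {
    "proximal"
  } else if (width_change >= thresholds$width_tol &&
             intensity_change >= thresholds$intensity_rise_min) {
    "intercalation"
  } else {
    "ambiguous"
  }
  structure(list(label = label, bleached_drift_nm_per_s = drift,
                 drift_tol_nm_per_s = drift_tol,
                 bleached_width_change_fraction = width_change,
                 bleached_intensity_change_pct = intensity_change,
                 thresholds = thresholds),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf(paste0("<mechanism_call> %s (drift %.1f nm/s, width change ",
                     "%+.0f%%, intensity change %+.1f pts)\n"),
              x$label, x$bleached_drift_nm_per_s,
              100 * x$bleached_width_change_fraction,
              x$bleached_intensity_change_pct))
  invisible(x)
}

#' Run the complete photobleach-chase analysis on a stack
#'
#' Orchestrates the full measurement: background estimation, kymogram
#' extraction and orientation, front tracing, pre/post-bleach speed
#' regression, end-of-assembly detection, eligibility screening, section
#' classification, section tracking at the chase time points, and mechanism
#' inference. The bleach time and geometry come from the stack metadata (the
#' simulator writes them; for external data supply them explicitly).
#'
#' @param stack An [image_stack()].
#' @param line A [line_profile()] along the sheath; defaults to the first
#'   synthetic-truth line in the metadata.
#' @param t_bleach_s Bleach time; defaults to `stack$meta$bleach$t_bleach_s`.
#' @param geometry Cell geometry for background estimation; defaults to
#'   metadata.
#' @param thresholds A [chase_thresholds()].
#' @return An object of class `chase_report`: list with `status`
#'   (`"ok"`/`"rejected"`), `call` (a `mechanism_call` or NULL), `reasons`,
#'   `speed_pre`, `speed_post`, `t_end_s`, `timepoints`, `sections`, `track`,
#'   `trace`, `pre_level`, `background`.
#' @export
run_bleach_chase <- function(stack, line = NULL, t_bleach_s = NULL,
                             geometry = NULL,
                             thresholds = chase_thresholds()) {
  if (is.null(t_bleach_s)) {
    if (is.null(stack$meta$bleach))
      stop("bleach time required: none given and none in stack metadata")
    t_bleach_s <- stack$meta$bleach$t_bleach_s
  }
  if (is.null(line)) {
    l <- (stack$meta$lines %||% list())[[1]]
    if (is.null(l)) stop("analysis line required: none in stack metadata")
    line <- line_profile(l$start_um, l$end_um)
  }
  bg <- estimate_background(stack, geometry)
  kym <- extract_kymogram(stack, line)
  kym <- orient_kymogram(kym, bg)
  trace <- tryCatch(trace_front(kym, bg), error = function(e) NULL)
  end <- if (is.null(trace)) NULL else
    tryCatch(detect_assembly_end(trace), error = function(e) NULL)
  elig <- eligible_for_chase(kym, t_bleach_s, bg, thresholds, trace = trace,
                             t_end_s = if (is.null(end)) Inf else end$t_end_s)
  if (!elig$eligible || is.null(end)) {
    reasons <- elig$reasons
    if (is.null(end)) reasons <- c(reasons, "no detectable end of assembly")
    return(structure(list(status = "rejected", call = NULL,
                          reasons = reasons,
                          speed_pre = elig$speed_pre,
                          speed_post = elig$speed_post,
                          t_end_s = NA_real_, timepoints = NULL,
                          sections = NULL, track = NULL, trace = trace,
                          pre_level = NA_real_, background = bg),
                     class = "chase_report"))
  }
  tps <- chase_timepoints(t_bleach_s, end$t_end_s, kym$frame_interval_s)
  pre_level <- prebleach_level(kym, trace, t_bleach_s)
  # The static per-bin time average only resolves sections whose positions
  # are fixed; when the bleached mark moves or stretches (non-distal
  # mechanisms) it finds no bleached span, and the call rests on tracking.
  sections <- tryCatch(
    classify_sections(kym, t_bleach_s, end$t_end_s, bg, pre_level,
                      thresholds, trace = trace),
    error = function(e) NULL)
  track <- track_sections(kym, trace, tps, bg, pre_level, thresholds)
  call <- infer_mechanism(track, elig$speed_post$v_a_nm_per_s, thresholds)
  structure(list(status = "ok", call = call, reasons = character(0),
                 speed_pre = elig$speed_pre, speed_post = elig$speed_post,
                 t_end_s = end$t_end_s, timepoints = tps, sections = sections,
                 track = track, trace = trace, pre_level = pre_level,
                 background = bg),
            class = "chase_report")
}

#' @export
print.chase_report <- function(x, ...) {
  if (x$status == "rejected") {
    cat("<chase_report> rejected:", paste(x$reasons, collapse = "; "), "\n")
  } else {
    cat(sprintf("<chase_report> %s; v_a pre %.1f / post %.1f nm/s; t_end %.0f s\n",
                x$call$label, x$speed_pre$v_a_nm_per_s,
                x$speed_post$v_a_nm_per_s, x$t_end_s))
  }
  invisible(x)
}
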