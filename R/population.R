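# Population-level summaries: morphology/dynamics category fractions, the
# sheath-length versus cell-diameter regression, and per-cell counts of
# sheath assembly events.

#' Summarize cell morphology and T6SS dynamics categories
#'
#' @param records Data frame with columns `morphology` (e.g. `"rod"`,
#'   `"spheroplast"`, `"lysed"`) and `dynamic_t6ss` (logical).
#' @return Data frame with `morphology`, `dynamics`, `n` and `percent`
#'   (percent of all records, rounded to 2 decimals). Percentages sum to 100
#'   within rounding.
#' @export
summarize_dynamics <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a non-empty data frame")
  stopifnot(all(c("morphology", "dynamic_t6ss") %in% names(records)))
  dynamics <- ifelse(records$dynamic_t6ss, "dynamic", "static")
  tab <- as.data.frame(table(morphology = records$morphology,
                             dynamics = dynamics),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$percent <- round(100 * tab$n / nrow(records), 2)
  tab[order(-tab$n), ]
}

#' Regress longest sheath length on cell diameter
#'
#' Ordinary least squares of the longest sheath per cell on the cell
#' diameter over spheroplast records, quantifying how strongly the available
#' intracellular space limits sheath length.
#'
#' @param records Data frame with columns `morphology`, `diameter_um` and
#'   `longest_sheath_um`.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
regress_length_vs_diameter <- function(records) {
  d <- records[records$morphology == "spheroplast" &
                 !is.na(records$longest_sheath_um), ]
  if (nrow(d) < 3) stop("need at least 3 spheroplast records")
  if (stats::var(d$diameter_um) == 0) stop("zero variance in diameter")
  fit <- stats::lm(longest_sheath_um ~ diameter_um, data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$longest_sheath_um - mean(d$longest_sheath_um))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = nrow(d)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.3f, intercept %.3f, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Count sheath assembly events per cell
#'
#' Number of distinct nucleation events within the counting window, per cell.
#'
#' @param events Event log data frame (`time_s`, `sheath_id`, `event`) with
#'   an additional `cell_id` column, e.g. from stacking per-cell
#'   `sheath_sim$events` logs.
#' @param window_s Counting window from time 0 (default 120 s).
#' @param acquisition_s Total acquisition length; the window must not exceed
#'   it (default `window_s`).
#' @param cells Vector of all observed cell ids, including cells without any
#'   event (those count as zero). Defaults to the cells present in `events`,
#'   which silently omits event-free cells — pass the full census when it is
#'   known.
#' @return Data frame with `cell_id`, `n_events`.
#' @export
count_sheath_events <- function(events, window_s = 120,
                                acquisition_s = window_s,
                                cells = unique(events$cell_id)) {
  stopifnot(all(c("cell_id", "time_s", "event") %in% names(events)))
  if (window_s > acquisition_s)
    stop("counting window exceeds the acquisition")
  nuc <- events[events$event == "nucleation" & events$time_s <= window_s, ]
  counts <- table(factor(nuc$cell_id, levels = cells))
  data.frame(cell_id = names(counts), n_events = as.integer(counts),
             row.names = NULL)
}

#' Simulate a spheroplast population
#'
#' Ground-truth simulation of `n_cells` spheroplasts with diameters drawn
#' uniformly from `diameter_range_um`, each running the sheath life cycle for
#' `duration_s`. The longest sheath per cell is the maximum truth length over
#' the observation period plus one-pixel Gaussian measurement noise
#' (emulating a manual length measurement). Rendering is skipped: the
#' regression operates on measured-style tables, and cell diameter is taken
#' from the geometry truth.
#'
#' @param n_cells Number of cells.
#' @param seed Integer base seed.
#' @param diameter_range_um Diameter range, um (default `c(2, 6)`).
#' @param nucleation_rate_per_min Nucleation rate (default 1.265 events per
#'   minute, i.e. 2.53 per 2 minutes as in cells assembling few sheaths).
#' @param v_a_nm_per_s Polymerization speed (default 38).
#' @param duration_s Observation period (default 300 s).
#' @param measurement_sd_um Length measurement noise (default 0.065, one
#'   pixel).
#' @return List with `records` (one row per cell: `cell_id`, `morphology`,
#'   `dynamic_t6ss`, `diameter_um`, `surface_area_um2`, `longest_sheath_um`,
#'   `n_sheath_events_2min`) and `events` (stacked per-cell event logs with
#'   `cell_id`).
#' @export
simulate_cell_population <- function(n_cells, seed,
                                     diameter_range_um = c(2, 6),
                                     nucleation_rate_per_min = 1.265,
                                     v_a_nm_per_s = 38, duration_s = 300,
                                     measurement_sd_um = 0.065) {
  set.seed(seed)
  diameters <- stats::runif(n_cells, diameter_range_um[1],
                            diameter_range_um[2])
  cell_seeds <- sample.int(2^30, n_cells)
  records <- list()
  all_events <- list()
  for (ci in seq_len(n_cells)) {
    geom <- cell_geometry("spheroplast", diameter_um = diameters[ci])
    cfg <- simulation_config(
      geometry = geom, mechanism = "distal",
      v_a_mean_nm_per_s = v_a_nm_per_s,
      nucleation_rate_per_min = nucleation_rate_per_min,
      extension_dwell_s = 10, disassembly_delay_s = 10,
      disassembly_tau_s = 10,
      frame_interval_s = 2, duration_s = duration_s, seed = cell_seeds[ci])
    sim <- simulate_sheaths(cfg)
    # longest *fully extended* structure seen during the window; cells in
    # which no sheath completed assembly are unmeasurable (NA)
    ext <- sim$events[sim$events$event == "extended", ]
    longest <- if (nrow(ext)) max(ext$length_um) else NA_real_
    set.seed(cell_seeds[ci] + 1L)
    longest_meas <- if (is.na(longest)) NA_real_ else
      max(longest + stats::rnorm(1, 0, measurement_sd_um), 0)
    ev <- sim$events
    if (nrow(ev)) ev$cell_id <- ci
    all_events[[ci]] <- ev
    n2min <- sum(ev$event == "nucleation" & ev$time_s <= 120)
    records[[ci]] <- data.frame(
      cell_id = ci, morphology = "spheroplast",
      dynamic_t6ss = n2min > 0,
      diameter_um = diameters[ci],
      surface_area_um2 = pi * (diameters[ci] / 2)^2,
      longest_sheath_um = longest_meas,
      n_sheath_events_2min = n2min)
  }
  events <- do.call(rbind, Filter(function(e) nrow(e) > 0, all_events))
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), sheath_id = integer(0),
                         event = character(0), length_um = numeric(0),
                         cell_id = integer(0))
  list(records = do.call(rbind, records), events = events)
}
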