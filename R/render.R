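# Rendering ground-truth polymer states into fluorescence image stacks:
# pixel-integrated 2D Gaussian PSF per ring, cytosolic background confined to
# the cell mask and proportional to the soluble-pool brightness, Poisson shot
# noise, Gaussian read noise, and a camera offset.

#' Optics and camera configuration
#'
#' @param pixel_size_nm Camera pixel size in the sample plane (default 65).
#' @param psf_sigma_nm Standard deviation of the 2D Gaussian point spread
#'   function (default 110 nm, approximately diffraction-limited for GFP
#'   emission at NA 1.4).
#' @param photons_per_ring Integrated photon count contributed by one ring at
#'   brightness 1 (default 20).
#' @param cytosol_background Photons per pixel of cytosolic background at pool
#'   brightness 1, inside the cell mask only (default 20).
#' @param read_noise_sd Gaussian read noise standard deviation, counts
#'   (default 2).
#' @param camera_offset Constant camera offset, counts (default 100).
#' @param shot_noise Apply Poisson shot noise to photon counts (default TRUE).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_nm = 65, psf_sigma_nm = 110,
                          photons_per_ring = 20, cytosol_background = 20,
                          read_noise_sd = 2, camera_offset = 100,
                          shot_noise = TRUE) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm >= 0, photons_per_ring >= 0,
            cytosol_background >= 0, read_noise_sd >= 0, camera_offset >= 0)
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 photons_per_ring = photons_per_ring,
                 cytosol_background = cytosol_background,
                 read_noise_sd = read_noise_sd,
                 camera_offset = camera_offset, shot_noise = shot_noise),
            class = "optics_config")
}

#' Construct an image stack
#'
#' @param frames List of H x W nonnegative intensity matrices (rows are y,
#'   columns are x).
#' @param frame_interval_s Frame interval, s.
#' @param pixel_size_nm Pixel size, nm.
#' @param t0_s Acquisition start time (default 0).
#' @param origin_um Image-plane coordinate of the corner of pixel `[1, 1]`
#'   (default `c(0, 0)`); pixel `[i, j]` is centred at
#'   `origin_um + (j - 0.5, i - 0.5) * pixel_size`.
#' @param meta Optional list of acquisition metadata (bleach event, geometry,
#'   suggested analysis lines, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s, pixel_size_nm, t0_s = 0,
                        origin_um = c(0, 0), meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1,
            frame_interval_s > 0, pixel_size_nm > 0)
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("frame intensities must be nonnegative")
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_nm = pixel_size_nm, t0_s = t0_s,
                 origin_um = as.numeric(origin_um), meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g nm/px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size_nm,
              x$frame_interval_s))
  invisible(x)
}

#' Frame times of a stack
#' @param stack An [image_stack()].
#' @return Numeric vector of frame times, s.
#' @export
frame_times <- function(stack) {
  stack$t0_s + (seq_along(stack$frames) - 1) * stack$frame_interval_s
}

# Noiseless photon image of one simulation snapshot. Each ring contributes a
# pixel-integrated isotropic Gaussian of total intensity
# photons_per_ring * brightness.
render_snapshot <- function(snapshot, pool_brightness, mask, optics,
                            origin_um, nrow, ncol) {
  px_um <- optics$pixel_size_nm / 1000
  sigma_px <- optics$psf_sigma_nm / optics$pixel_size_nm
  img <- matrix(0, nrow, ncol)
  img[mask] <- optics$cytosol_background * pool_brightness
  w <- max(ceiling(4 * sigma_px), 2)
  for (sh in snapshot) {
    n <- length(sh$ring_positions_um)
    if (n == 0) next
    xs <- (sh$anchor_um[1] + sh$direction[1] * sh$ring_positions_um -
             origin_um[1]) / px_um         # in pixels from image corner
    ys <- (sh$anchor_um[2] + sh$direction[2] * sh$ring_positions_um -
             origin_um[2]) / px_um
    amp <- optics$photons_per_ring * sh$ring_brightness
    for (i in seq_len(n)) {
      if (amp[i] <= 0) next
      jlo <- max(floor(xs[i] - w), 0)
      jhi <- min(ceiling(xs[i] + w), ncol)
      ilo <- max(floor(ys[i] - w), 0)
      ihi <- min(ceiling(ys[i] + w), nrow)
      if (jhi <= jlo || ihi <= ilo) next
      # pixel-integrated 1D Gaussians over pixel edges (in px units)
      gx <- diff(stats::pnorm(jlo:jhi, mean = xs[i], sd = sigma_px))
      gy <- diff(stats::pnorm(ilo:ihi, mean = ys[i], sd = sigma_px))
      img[(ilo + 1):ihi, (jlo + 1):jhi] <-
        img[(ilo + 1):ihi, (jlo + 1):jhi] + amp[i] * outer(gy, gx)
    }
  }
  img
}

#' Render a simulation into a fluorescence image stack
#'
#' Produces one frame per simulation frame. The field of view covers the cell
#' plus a margin; pixel `[i, j]` is centred at
#' `origin_um + ((j - 0.5), (i - 0.5)) * pixel_size`. In noiseless mode the
#' returned intensities are expected photon counts plus the camera offset;
#' with noise enabled, Poisson shot noise is applied to the photon counts
#' followed by additive Gaussian read noise. Uses the current R random number
#' stream (a simulation followed by rendering under one `set.seed` is fully
#' reproducible). Frames whose truth state is unchanged reuse the cached
#' noiseless image, so only the noise is redrawn.
#'
#' @param sim A `sheath_sim` from [simulate_sheaths()].
#' @param optics An [optics_config()].
#' @param noiseless If TRUE, disable shot and read noise regardless of
#'   `optics` (default FALSE).
#' @param margin_um Field-of-view margin around the cell (default 0.6).
#' @return An [image_stack()] whose `meta` carries the simulation's geometry,
#'   bleach event and suggested per-sheath analysis lines.
#' @export
render_stack <- function(sim, optics = optics_config(), noiseless = FALSE,
                         margin_um = 0.6) {
  stopifnot(inherits(sim, "sheath_sim"), inherits(optics, "optics_config"))
  geom <- sim$geometry
  px_um <- optics$pixel_size_nm / 1000
  half_w <- geom$length_um / 2 + margin_um
  half_h <- geom$diameter_um / 2 + margin_um
  origin_um <- geom$center_um - c(half_w, half_h)
  ncol <- ceiling(2 * half_w / px_um)
  nrow <- ceiling(2 * half_h / px_um)
  mask <- cell_pixel_mask(geom, nrow, ncol, px_um, origin_um)
  shot <- optics$shot_noise && !noiseless
  read_sd <- if (noiseless) 0 else optics$read_noise_sd

  frames <- vector("list", length(sim$frames))
  prev_snapshot <- NULL
  base <- NULL
  for (fi in seq_along(sim$frames)) {
    snap <- sim$frames[[fi]]
    pool_b <- sim$pool_series$soluble_brightness[fi]
    key <- list(snap = lapply(snap, function(s)
      list(s$ring_positions_um, s$ring_brightness)), pool = pool_b)
    if (is.null(base) || !identical(key, prev_snapshot)) {
      base <- render_snapshot(snap, pool_b, mask, optics, origin_um,
                              nrow, ncol)
      prev_snapshot <- key
    }
    img <- base
    if (shot) {
      img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
    }
    img <- img + optics$camera_offset
    if (read_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, read_sd),
                          nrow(img), ncol(img))
    }
    frames[[fi]] <- pmax(img, 0)
  }
  meta <- list(geometry = geom, seed = sim$config$seed)
  if (!is.null(sim$config$bleach)) meta$bleach <- sim$config$bleach
  last <- sim$frames[[length(sim$frames)]]
  if (length(last)) {
    meta$lines <- lapply(last, function(sh)
      list(sheath_id = sh$id, start_um = sh$anchor_um,
           end_um = sh$anchor_um + sh$direction * sh$chord_um,
           synthetic_truth = TRUE))
  }
  image_stack(frames, sim$config$frame_interval_s, optics$pixel_size_nm,
              t0_s = sim$times_s[1], origin_um = origin_um, meta = meta)
}

#' Estimate per-frame cytosolic background
#'
#' For each frame, takes the pixels inside the cell mask, excludes bright
#' (sheath-attributed) pixels above `median + 3 * mad`, and returns the mean
#' and standard deviation of the rest. This is the 0% reference of the
#' photobleach-chase intensity normalization; it tracks the drop of cytosolic
#' fluorescence when the soluble pool is partially bleached.
#'
#' @param stack An [image_stack()].
#' @param geometry A [cell_geometry()]; defaults to `stack$meta$geometry`.
#' @return Data frame with `frame`, `time_s`, `mean`, `sd`.
#' @export
estimate_background <- function(stack, geometry = NULL) {
  geometry <- geometry %||% stack$meta$geometry
  if (is.null(geometry)) stop("`geometry` required: none in stack metadata")
  px_um <- stack$pixel_size_nm / 1000
  d <- dim(stack$frames[[1]])
  mask <- cell_pixel_mask(geometry, d[1], d[2], px_um, stack$origin_um)
  times <- frame_times(stack)
  out <- data.frame(frame = seq_along(stack$frames), time_s = times,
                    mean = NA_real_, sd = NA_real_)
  for (fi in seq_along(stack$frames)) {
    vals <- stack$frames[[fi]][mask]
    med <- stats::median(vals)
    madv <- stats::mad(vals)
    bg <- vals[vals <= med + 3 * max(madv, 1e-9)]
    out$mean[fi] <- mean(bg)
    out$sd[fi] <- stats::sd(bg)
  }
  out
}
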