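# Stack I/O: multi-frame 16-bit TIFF plus a YAML metadata sidecar. TIFF tags
# do not reliably carry pixel size or frame interval, so the sidecar is
# authoritative and required.

#' Write an image stack to a multi-frame TIFF with a YAML sidecar
#'
#' Intensities are rounded to integer counts and clamped to the 16-bit range
#' before writing, so `read_stack(write_stack(s))` reproduces the written
#' frames bit-exactly. Metadata (pixel size, frame interval, start time,
#' image origin, and any bleach event) is written to `<path>.yaml`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_s = stack$frame_interval_s,
               t0_s = stack$t0_s,
               origin_um = as.numeric(stack$origin_um))
  if (!is.null(stack$meta$bleach)) {
    b <- stack$meta$bleach
    meta$bleach <- list(t_bleach_s = b$t_bleach_s,
                        line_start_um = as.numeric(b$line_start_um),
                        line_end_um = as.numeric(b$line_end_um),
                        footprint_fwhm_um = b$footprint_fwhm_um,
                        polymer_survival = b$polymer_survival,
                        pool_survival = b$pool_survival)
  }
  if (!is.null(stack$meta$geometry)) {
    g <- stack$meta$geometry
    meta$geometry <- list(shape = g$shape, diameter_um = g$diameter_um,
                          length_um = g$length_um,
                          center_um = as.numeric(g$center_um))
  }
  if (!is.null(stack$meta$lines)) {
    meta$lines <- lapply(stack$meta$lines, function(l)
      list(sheath_id = l$sheath_id, start_um = as.numeric(l$start_um),
           end_um = as.numeric(l$end_um),
           synthetic_truth = isTRUE(l$synthetic_truth)))
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Frames are returned as integer photon/camera counts. Metadata is read from
#' the YAML sidecar `<path>.yaml` (or an explicit `metadata` list); missing
#' required fields raise an error naming the field rather than being filled
#' with silent defaults.
#'
#' @param path TIFF path.
#' @param metadata Optional metadata list overriding the sidecar.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(metadata)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("missing metadata sidecar: ", sidecar)
    metadata <- yaml::read_yaml(sidecar)
  }
  for (field in c("pixel_size_nm", "frame_interval_s")) {
    if (is.null(metadata[[field]]))
      stop("stack metadata is missing required field `", field, "`")
  }
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  frames <- lapply(raw, function(m) round(m * 65535))
  meta <- list()
  if (!is.null(metadata$bleach)) {
    b <- metadata$bleach
    meta$bleach <- bleach_event(b$t_bleach_s, unlist(b$line_start_um),
                                unlist(b$line_end_um),
                                footprint_fwhm_um = b$footprint_fwhm_um,
                                polymer_survival = b$polymer_survival,
                                pool_survival = b$pool_survival)
  }
  if (!is.null(metadata$geometry)) {
    g <- metadata$geometry
    meta$geometry <- cell_geometry(g$shape, g$diameter_um,
                                   length_um = g$length_um,
                                   center_um = unlist(g$center_um))
  }
  if (!is.null(metadata$lines)) {
    meta$lines <- lapply(metadata$lines, function(l)
      list(sheath_id = l$sheath_id, start_um = unlist(l$start_um),
           end_um = unlist(l$end_um),
           synthetic_truth = isTRUE(l$synthetic_truth)))
  }
  image_stack(frames,
              frame_interval_s = metadata$frame_interval_s,
              pixel_size_nm = metadata$pixel_size_nm,
              t0_s = metadata$t0_s %||% 0,
              origin_um = unlist(metadata$origin_um %||% c(0, 0)),
              meta = meta)
}
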