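#' Mean fluence by depth plane
#'
#' Averages the fluence rate over masked voxels within each voxel-aligned
#' plane perpendicular to `axis`. Planes are labeled by the depth of their
#' upper (beam-facing) face. Adjacent-plane differences and their mean
#' summarize how steeply fluence decays with depth.
#'
#' @param fluence a `fluence_volume`
#' @param mask logical array selecting the voxels to average (e.g. the
#'   tumor); must be non-empty
#' @param axis depth axis (default 3, the beam axis)
#' @return list with `profile` (`data.frame` of `depth_mm`, `mean_fluence`),
#'   `differences` (positive decrements between adjacent planes) and
#'   `mean_difference`
#' @export
depth_profile <- function(fluence, mask, axis = 3) {
  stopifnot(inherits(fluence, "fluence_volume"))
  if (!any(mask)) stop("empty mask")
  d <- dim(fluence$phi)
  planes <- which(apply(mask, axis, any))
  means <- vapply(planes, function(k) {
    idx <- switch(axis,
                  mask[k, , , drop = FALSE],
                  mask[, k, , drop = FALSE],
                  mask[, , k, drop = FALSE])
    sl <- switch(axis,
                 fluence$phi[k, , , drop = FALSE],
                 fluence$phi[, k, , drop = FALSE],
                 fluence$phi[, , k, drop = FALSE])
    mean(sl[idx])
  }, numeric(1))
  prof <- data.frame(depth_mm = (planes - 1) * fluence$pitch_mm,
                     mean_fluence = means)
  c(list(profile = prof), plane_difference_summary(means))
}

#' Adjacent-plane fluence differences and their mean
#'
#' Given per-plane mean fluences ordered by increasing depth, returns the
#' successive decrements and their average, the "fluence change per plane"
#' statistic used in depth-sensitivity reports (one-decimal values round
#' half up).
#'
#' @param means per-plane mean fluences, shallow to deep
#' @return list with `differences` and `mean_difference`
#' @export
plane_difference_summary <- function(means) {
  diffs <- -diff(means)
  list(differences = diffs,
       mean_difference = if (length(diffs)) mean(diffs) else NA_real_)
}

#' Tumor fluence summary
#'
#' @param fluence a `fluence_volume`
#' @param tumor_mask non-empty logical array
#' @return list with `mean`, `min`, `max` fluence (mW/cm^2) over the mask
#' @export
tumor_fluence_summary <- function(fluence, tumor_mask) {
  stopifnot(inherits(fluence, "fluence_volume"))
  if (!any(tumor_mask)) stop("empty tumor mask")
  v <- fluence$phi[tumor_mask]
  list(mean = mean(v), min = min(v), max = max(v))
}

#' Range of mean tumor fluences across phantoms
#'
#' @param means vector of per-phantom mean tumor fluences
#' @return `max - min` (0 for a single phantom)
#' @export
fluence_range <- function(means) {
  if (!length(means)) stop("no phantom means supplied")
  max(means) - min(means)
}

#' Render a cross-section map to PNG
#'
#' Deterministic rendering: a fixed perceptually uniform colormap, and the
#' normalization range recorded in a JSON sidecar so identical inputs give
#' byte-identical files.
#'
#' @param arr 3D numeric (or label/logical) array
#' @param slice slice index along `axis`
#' @param path output PNG path
#' @param axis slicing axis (default 3)
#' @param range normalization range; defaults to the slice data range
#' @param n_colors colormap resolution
#' @return `path`, invisibly
#' @export
render_map <- function(arr, slice, path, axis = 3, range = NULL,
                       n_colors = 256) {
  d <- dim(arr)
  if (slice < 1 || slice > d[axis]) stop("slice out of bounds")
  sl <- switch(axis, arr[slice, , ], arr[, slice, ], arr[, , slice])
  sl <- matrix(as.numeric(sl), nrow = nrow(sl))
  if (is.null(range)) range <- base::range(sl)
  span <- diff(range)
  norm <- if (span > 0) (sl - range[1]) / span else sl * 0
  norm <- pmin(pmax(norm, 0), 1)
  pal <- grDevices::hcl.colors(n_colors, "viridis")
  rgb <- grDevices::col2rgb(pal[1 + floor(norm * (n_colors - 1))]) / 255
  img <- array(0, c(nrow(sl), ncol(sl), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(sl)); img[, , 2] <- matrix(rgb[2, ], nrow(sl))
  img[, , 3] <- matrix(rgb[3, ], nrow(sl))
  png::writePNG(img, path)
  jsonlite::write_json(list(slice = slice, axis = axis, range = range,
                            palette = "viridis", n_colors = n_colors),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
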