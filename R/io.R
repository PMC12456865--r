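#' Write a labeled or scalar volume to a NIfTI file
#'
#' Labels are stored as 16-bit integers, scalar fields (fluence, dose) as
#' 32-bit floats; the voxel pitch goes into the NIfTI pixdim. A JSON legend
#' sidecar (`<file>.json`) records the label legend and pitch for labeled
#' volumes.
#'
#' @param vol a [labeled_volume()] or a list with elements `phi`/`pd` (3D
#'   array) and `pitch_mm`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "labeled_volume")) {
    img <- RNifti::asNifti(vol$labels)
    RNifti::pixdim(img) <- rep(vol$pitch_mm, 3)
    RNifti::writeNifti(img, path, datatype = "int16")
    legend <- list(pitch_mm = vol$pitch_mm, origin = vol$origin,
                   legend = as.list(tissue_codes()))
    jsonlite::write_json(legend, sidecar_path(path), auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    arr <- vol$phi %||% vol$pd
    if (is.null(arr)) stop("unsupported volume object")
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(vol$pitch_mm, 3)
    RNifti::writeNifti(img, path, datatype = "float")
  }
  invisible(path)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Load a labeled phantom volume
#'
#' Reads either a NIfTI file with integer labels (plus optional JSON legend
#' sidecar) or a directory holding an ordered stack of grayscale PNG slice
#' images with a mandatory `stack.json` sidecar carrying the pixel pitch and
#' label legend. Slice images encode the label code as `code/255` gray
#' levels, the format written by [write_label_stack()].
#'
#' @param path a `.nii`/`.nii.gz` file or a slice-stack directory
#' @param legend named integer vector mapping label names to codes; defaults
#'   to [tissue_codes()] (or the sidecar legend when present)
#' @return a [labeled_volume()]
#' @export
load_label_stack <- function(path, legend = NULL) {
  if (dir.exists(path)) {
    side_file <- file.path(path, "stack.json")
    if (!file.exists(side_file))
      stop("missing stack.json sidecar (pitch metadata) in ", path)
    side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
    if (is.null(side$pitch_mm))
      stop("sidecar does not declare pitch_mm")
    legend <- legend %||% unlist(side$legend) %||% tissue_codes()
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      round(m * 255)
    })
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent slice dimensions: slice ", which.max(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]),
           " differs from slice 1")
    arr <- array(0L, c(dims[1, 1], dims[2, 1], length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- as.integer(slices[[k]])
    check_legend(arr, legend)
    labeled_volume(arr, pitch_mm = side$pitch_mm,
                   origin = side$origin %||% c(0, 0, 0))
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    side_file <- sidecar_path(path)
    pitch <- pd[1]
    origin <- c(0, 0, 0)
    if (file.exists(side_file)) {
      side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
      pitch <- side$pitch_mm %||% pitch
      origin <- side$origin %||% origin
      legend <- legend %||% unlist(side$legend)
    }
    if (!isTRUE(pitch > 0)) stop("missing pitch metadata in ", path)
    arr <- array(as.integer(img), dim = dim(img))
    check_legend(arr, legend %||% tissue_codes())
    labeled_volume(arr, pitch_mm = pitch, origin = origin)
  }
}

check_legend <- function(arr, legend) {
  bad <- setdiff(unique(as.vector(arr)), as.integer(legend))
  if (length(bad))
    stop("label value(s) outside legend: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Write a phantom as an ordered PNG slice stack
#'
#' Inverse of the directory mode of [load_label_stack()]: one grayscale PNG
#' per slice along axis 3 plus a `stack.json` sidecar (pitch, legend,
#' dimensions). The write -> read round trip is bit-identical on labels.
#'
#' @param vol a [labeled_volume()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_label_stack <- function(vol, dir) {
  stopifnot(inherits(vol, "labeled_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$labels)
  for (k in seq_len(d[3])) {
    png::writePNG(vol$labels[, , k] / 255,
                  file.path(dir, sprintf("slice_%04d.png", k)))
  }
  side <- list(pitch_mm = vol$pitch_mm, origin = vol$origin,
               dim = d, legend = as.list(tissue_codes()))
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Nearest-neighbor isotropic resampling of a labeled volume
#'
#' Standardizes a phantom to a target voxel pitch (the pipeline works at
#' 0.33 mm). Nearest-neighbor interpolation guarantees that no new labels
#' are invented; the physical extent is preserved to within one voxel per
#' axis.
#'
#' @param vol a [labeled_volume()]
#' @param target_pitch_mm new isotropic pitch in mm
#' @return resampled [labeled_volume()]
#' @export
resample_iso <- function(vol, target_pitch_mm) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!is.numeric(target_pitch_mm) || length(target_pitch_mm) != 1 ||
      target_pitch_mm <= 0)
    stop("target pitch must be a single positive length")
  if (isTRUE(all.equal(target_pitch_mm, vol$pitch_mm))) return(vol)
  d <- dim(vol$labels)
  extent <- d * vol$pitch_mm
  nd <- pmax(1L, as.integer(round(extent / target_pitch_mm)))
  map_axis <- function(n_new, n_old) {
    centers <- (seq_len(n_new) - 0.5) * target_pitch_mm
    i <- floor(centers / vol$pitch_mm) + 1
    pmin(pmax(as.integer(i), 1L), n_old)
  }
  ix <- map_axis(nd[1], d[1]); iy <- map_axis(nd[2], d[2]); iz <- map_axis(nd[3], d[3])
  labeled_volume(vol$labels[ix, iy, iz, drop = FALSE],
                 pitch_mm = target_pitch_mm, origin = vol$origin)
}
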