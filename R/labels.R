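#' Tissue label codes
#'
#' The five voxel labels used throughout the package. Phantoms as loaded or
#' generated contain AIR, SKIN, FAT and DUCT; TUMOR appears only after
#' [embed_tumor()].
#'
#' @return named integer vector `c(AIR = 0, SKIN = 1, FAT = 2, DUCT = 3, TUMOR = 4)`
#' @export
tissue_codes <- function() {
  c(AIR = 0L, SKIN = 1L, FAT = 2L, DUCT = 3L, TUMOR = 4L)
}

#' Labeled voxel volume
#'
#' Container for a digital breast phantom: a 3D integer array of tissue
#' labels with an isotropic physical voxel pitch. Axis 3 of the array is the
#' slice-stacking/body axis; the irradiation beam travels along it in the
#' positive direction, entering at slice 1.
#'
#' @param labels 3D integer array of [tissue_codes()] values
#' @param pitch_mm isotropic voxel edge length in mm (default 0.33)
#' @param origin physical coordinate (mm) of the corner of voxel (1,1,1)
#' @return object of class `labeled_volume`
#' @export
labeled_volume <- function(labels, pitch_mm = 0.33, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3 || any(dim(labels) <= 0))
    stop("labels must be a 3D array with positive dimensions")
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1 || pitch_mm <= 0)
    stop("pitch_mm must be a single positive length")
  storage.mode(labels) <- "integer"
  known <- tissue_codes()
  bad <- setdiff(unique(as.vector(labels)), known)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, pitch_mm = pitch_mm,
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled_volume: %d x %d x %d voxels, pitch %.3g mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$pitch_mm,
              d[1] * x$pitch_mm, d[2] * x$pitch_mm, d[3] * x$pitch_mm))
  counts <- label_counts(x)
  for (nm in names(counts))
    if (counts[[nm]] > 0)
      cat(sprintf("  %-6s %10d voxels\n", nm, counts[[nm]]))
  invisible(x)
}

#' Per-label voxel counts
#'
#' @param vol a [labeled_volume()]
#' @return named integer vector of counts for each tissue label; counts sum
#'   to the voxel total (the labels partition the grid)
#' @export
label_counts <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  codes <- tissue_codes()
  tab <- tabulate(as.vector(vol$labels) + 1L, nbins = max(codes) + 1L)
  stats::setNames(tab[codes + 1L], names(codes))
}
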