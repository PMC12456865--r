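#' Voxelize a sphere on the phantom grid
#'
#' Membership is by voxel-center inclusion: a voxel belongs to the sphere if
#' its center lies strictly within `diameter_mm / 2` of the sphere center
#' (itself a voxel center). For a 7-mm sphere at 0.33 mm pitch this yields
#' the analytic volume `(pi/6) d^3 / pitch^3` (about 4997 voxels) to within
#' 2%.
#'
#' @param center voxel index `c(i, j, k)` of the sphere center
#' @param diameter_mm sphere diameter (mm), default 7
#' @param pitch_mm voxel pitch (mm)
#' @param dim grid dimensions (for the boundary check)
#' @return integer matrix of member voxel indices (one row per voxel)
#' @export
voxelize_sphere <- function(center, diameter_mm = 7, pitch_mm = 0.33,
                            dim = NULL) {
  r_vox <- (diameter_mm / 2) / pitch_mm
  m <- floor(r_vox - 1e-9)
  if (m < 0) m <- 0
  off <- -m:m
  if (!is.null(dim)) {
    if (any(center - m < 1) || any(center + m > dim))
      stop("sphere clipped by grid boundary")
  }
  g <- expand.grid(dx = off, dy = off, dz = off)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 < r_vox^2
  ids <- cbind(center[1] + g$dx[keep], center[2] + g$dy[keep],
               center[3] + g$dz[keep])
  colnames(ids) <- c("i", "j", "k")
  ids
}

#' Tumor depth below the irradiated skin surface
#'
#' Depth is measured along the beam axis through the tumor center column,
#' from the outer skin surface (the face of the first non-air voxel the beam
#' meets in that column) to the upper face of the shallowest tumor voxel.
#' The outer surface is used because the delivered dose and all reported
#' depths reference the illuminated surface.
#'
#' @param vol a [labeled_volume()]
#' @param voxel_ids integer matrix of tumor member voxels (rows `i, j, k`)
#' @return depth in mm
#' @export
tumor_depth <- function(vol, voxel_ids) {
  stopifnot(inherits(vol, "labeled_volume"), nrow(voxel_ids) > 0)
  ctr <- round(colMeans(voxel_ids))
  col <- vol$labels[ctr[1], ctr[2], ]
  k0 <- which(col != tissue_codes()[["AIR"]])[1]
  if (is.na(k0))
    stop("beam-axis column through the tumor center misses the breast")
  k_top <- min(voxel_ids[, 3])
  (k_top - k0) * vol$pitch_mm
}

#' Find admissible tumor embedding sites
#'
#' A site is admissible when the voxelized sphere centered there lies
#' entirely within milk-duct voxels and its depth falls inside
#' `depth_range`. The duct-interior test uses an exact Euclidean distance
#' transform of the non-duct mask (a sphere is all-duct iff the nearest
#' non-duct voxel center is at least one radius away).
#'
#' @param vol a [labeled_volume()]
#' @param diameter_mm tumor diameter (mm)
#' @param depth_range admissible `c(min, max)` depth in mm (default 15-25)
#' @param stride candidate-center stride in voxels (>1 trades completeness
#'   for speed on large grids)
#' @return `data.frame` with columns `i, j, k, depth_mm`, sorted by depth
#'   ascending (possibly empty)
#' @export
find_candidate_sites <- function(vol, diameter_mm = 7,
                                 depth_range = c(15, 25), stride = 1) {
  stopifnot(inherits(vol, "labeled_volume"))
  codes <- tissue_codes()
  d <- dim(vol$labels)
  r_vox <- (diameter_mm / 2) / vol$pitch_mm
  m <- floor(r_vox - 1e-9)
  d2 <- array(edt_sq_cpp(as.vector(vol$labels != codes[["DUCT"]]),
                         as.integer(d)), d)
  ok <- d2 >= r_vox^2 - 1e-9
  # keep the sphere fully inside the grid
  if (m > 0) {
    ok[c(seq_len(min(m, d[1])), max(d[1] - m + 1, 1):d[1]), , ] <- FALSE
    ok[, c(seq_len(min(m, d[2])), max(d[2] - m + 1, 1):d[2]), ] <- FALSE
    ok[, , c(seq_len(min(m, d[3])), max(d[3] - m + 1, 1):d[3])] <- FALSE
  }
  if (stride > 1) {
    keep1 <- (seq_len(d[1]) - 1) %% stride == 0
    keep2 <- (seq_len(d[2]) - 1) %% stride == 0
    keep3 <- (seq_len(d[3]) - 1) %% stride == 0
    ok <- ok & outer(outer(keep1, keep2, "&"), keep3, "&")
  }
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      depth_mm = numeric()))
  entry <- entry_map(vol$labels)
  k0 <- entry[cbind(cand[, 1], cand[, 2])]
  depth <- ((cand[, 3] - m) - k0) * vol$pitch_mm
  keep <- is.finite(depth) & depth >= depth_range[1] & depth <= depth_range[2]
  out <- data.frame(i = cand[keep, 1], j = cand[keep, 2], k = cand[keep, 3],
                    depth_mm = depth[keep])
  out[order(out$depth_mm, out$i, out$j, out$k), , drop = FALSE]
}

#' Embed a spherical tumor in the milk ducts
#'
#' Applies the four embedding criteria: the tumor is a sphere of
#' `diameter_mm`; its depth must lie within `depth_range`; it must sit
#' entirely within duct voxels; and among admissible sites the one closest
#' to the skin is chosen. Remaining ties are broken by smallest lateral
#' distance to the breast apex axis, then lexicographic voxel index.
#' Phantoms with no admissible site are returned unchanged and flagged
#' ineligible.
#'
#' @inheritParams find_candidate_sites
#' @return list with `volume` (tumor voxels relabeled DUCT -> TUMOR),
#'   `eligible` flag and `tumor` (a `tumor_spec` list: `center`,
#'   `diameter_mm`, `depth_mm`, `voxel_ids`, `n_voxels`; `NULL` when
#'   ineligible)
#' @export
embed_tumor <- function(vol, diameter_mm = 7, depth_range = c(15, 25),
                        stride = 1) {
  sites <- find_candidate_sites(vol, diameter_mm, depth_range, stride)
  if (nrow(sites) == 0)
    return(list(volume = vol, eligible = FALSE, tumor = NULL))
  best_depth <- sites$depth_mm[1]
  top <- sites[sites$depth_mm <= best_depth + 1e-9, , drop = FALSE]
  if (nrow(top) > 1) {
    apex <- apex_column(vol$labels)
    lat <- sqrt((top$i - apex[["i"]])^2 + (top$j - apex[["j"]])^2)
    top <- top[order(lat, top$i, top$j, top$k), , drop = FALSE]
  }
  center <- c(top$i[1], top$j[1], top$k[1])
  ids <- voxelize_sphere(center, diameter_mm, vol$pitch_mm, dim(vol$labels))
  codes <- tissue_codes()
  lin <- ids[, 1] + dim(vol$labels)[1] * ((ids[, 2] - 1) +
           dim(vol$labels)[2] * (ids[, 3] - 1))
  stopifnot(all(vol$labels[lin] == codes[["DUCT"]]))
  lab <- vol$labels
  lab[lin] <- codes[["TUMOR"]]
  out <- labeled_volume(lab, pitch_mm = vol$pitch_mm, origin = vol$origin)
  attr(out, "host") <- attr(vol, "host")
  attr(out, "provenance") <- attr(vol, "provenance")
  tumor <- structure(list(center = center, diameter_mm = diameter_mm,
                          depth_mm = tumor_depth(out, ids),
                          voxel_ids = ids, n_voxels = nrow(ids)),
                     class = "tumor_spec")
  list(volume = out, eligible = TRUE, tumor = tumor)
}

#' @export
print.tumor_spec <- function(x, ...) {
  cat(sprintf("tumor_spec: %g mm sphere, %d voxels, depth %.2f mm, center (%d, %d, %d)\n",
              x$diameter_mm, x$n_voxels, x$depth_mm,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Serialize a tumor spec to JSON
#'
#' @param tumor a `tumor_spec` from [embed_tumor()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_tumor_spec <- function(tumor, path) {
  jsonlite::write_json(list(center = tumor$center,
                            diameter_mm = tumor$diameter_mm,
                            depth_mm = tumor$depth_mm,
                            n_voxels = tumor$n_voxels),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
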