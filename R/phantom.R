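#' Breast (glandular) density of a labeled phantom
#'
#' Density is the ratio of milk-duct volume to the combined duct and fat
#' volume. Skin, air and tumor voxels are excluded from both numerator and
#' denominator, so the value is invariant to tumor embedding; the pipeline
#' nevertheless computes and freezes density *before* embedding.
#'
#' @param vol a [labeled_volume()]
#' @return fraction in `[0, 1]`: `n_duct / (n_duct + n_fat)`
#' @export
compute_breast_density <- function(vol) {
  counts <- label_counts(vol)
  denom <- counts[["DUCT"]] + counts[["FAT"]]
  if (denom == 0) stop("volume has no fat or duct voxels (zero denominator)")
  counts[["DUCT"]] / denom
}

birads_levels <- c("fatty", "scattered", "heterogeneous", "extremely_dense")

#' Adjusted-density BI-RADS-style classification
#'
#' The raw voxel-tally density of CT-derived phantoms underestimates the
#' mammographic density that BI-RADS bins were calibrated for, so it is
#' multiplied by 2.5 (capped at 100%) before binning: `[0,25)` fatty,
#' `[25,50)` scattered fibroglandular, `[50,75)` heterogeneously dense,
#' `[75,100]` extremely dense.
#'
#' @param raw_density fraction in `[0, 1]`
#' @return list with `raw_density`, `adjusted_density_pct` (percent) and
#'   `birads_class` (one of `"fatty"`, `"scattered"`, `"heterogeneous"`,
#'   `"extremely_dense"`)
#' @export
classify_breast <- function(raw_density) {
  if (!is.numeric(raw_density) || any(raw_density < 0) || any(raw_density > 1))
    stop("raw density must lie in [0, 1]")
  adjusted <- pmin(100, 250 * raw_density)
  cls <- ifelse(adjusted >= 75, "extremely_dense",
         ifelse(adjusted >= 50, "heterogeneous",
         ifelse(adjusted >= 25, "scattered", "fatty")))
  list(raw_density = raw_density,
       adjusted_density_pct = adjusted,
       birads_class = cls)
}

#' Build a phantom record row
#'
#' @param id phantom identifier
#' @param raw_density fraction in `[0, 1]` (pre-embedding voxel tally)
#' @param eligible could a tumor be embedded under the four criteria?
#' @param tumor_depth_mm depth of the embedded tumor, or `NA`
#' @return one-row `data.frame` with columns `id`, `raw_density`,
#'   `adjusted_density_pct`, `birads_class`, `eligible`, `tumor_depth_mm`
#' @export
phantom_record <- function(id, raw_density, eligible = NA, tumor_depth_mm = NA_real_) {
  cls <- classify_breast(raw_density)
  data.frame(id = as.character(id),
             raw_density = raw_density,
             adjusted_density_pct = cls$adjusted_density_pct,
             birads_class = cls$birads_class,
             eligible = eligible,
             tumor_depth_mm = tumor_depth_mm,
             stringsAsFactors = FALSE)
}

#' Select the representative phantom of a depth group
#'
#' Given records of phantoms sharing a tumor depth, returns the member whose
#' density is closest to the group mean (simulations are then run on that
#' phantom as the group surrogate). Ties go to the lowest id.
#'
#' @param records `data.frame` with at least `id` and `raw_density`
#' @return the selected record (one-row `data.frame`)
#' @export
select_representative <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("empty phantom group")
  dens <- records$raw_density
  delta <- abs(dens - mean(dens))
  best <- which(delta == min(delta))
  if (length(best) > 1) best <- best[order(records$id[best])][1]
  records[best, , drop = FALSE]
}
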