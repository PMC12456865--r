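#' Sessions needed to reach the cell-death threshold
#'
#' Sessions are identical (the optical field is static across sessions), so
#' dose accumulates linearly and a voxel dies after
#' `ceiling(threshold / pd_session)` irradiations. A voxel receiving zero
#' dose is unreachable and reported as `Inf` rather than a large integer.
#' Reaching the threshold exactly counts as death.
#'
#' @param pd_session per-session dose (photons/cm^3), vectorized
#' @param threshold cell-death threshold (photons/cm^3), default 8.6e17
#' @return numeric vector of session counts (`Inf` where unreachable)
#' @export
sessions_to_kill <- function(pd_session, threshold = 8.6e17) {
  if (any(pd_session < 0)) stop("dose must be non-negative")
  out <- ceiling(threshold / pd_session)
  out[pd_session == 0] <- Inf
  out
}

#' Voxel kill map after a number of sessions
#'
#' @param pd_vol a `pd_volume`
#' @param n_sessions number of completed irradiation sessions (>= 0)
#' @param threshold cell-death threshold (photons/cm^3); defaults to the
#'   threshold carried by the dose parameters
#' @return logical array: `TRUE` where `n x pd >= threshold` (all `FALSE`
#'   for `n = 0`); kill maps are nested across increasing `n`
#' @export
kill_map <- function(pd_vol, n_sessions,
                     threshold = pd_vol$params$threshold_photons_cm3) {
  stopifnot(inherits(pd_vol, "pd_volume"))
  if (n_sessions < 0) stop("session count must be non-negative")
  if (n_sessions == 0) return(array(FALSE, dim(pd_vol$pd)))
  pd_vol$pd > 0 & n_sessions * pd_vol$pd >= threshold
}

#' Plan the irradiation course for a tumor
#'
#' Computes per-voxel sessions-to-death, the number of sessions required to
#' treat the whole tumor (`n_complete`, the per-voxel maximum), and the
#' cumulative fraction of tumor voxels killed after each session.
#'
#' @param pd_vol a `pd_volume` with a non-empty tumor
#' @param threshold cell-death threshold (photons/cm^3)
#' @return object of class `session_plan`: `sessions_per_voxel` (array,
#'   `NA` outside the tumor), `n_complete`, `kill_fraction_by_session`
#' @export
plan_treatment <- function(pd_vol,
                           threshold = pd_vol$params$threshold_photons_cm3) {
  stopifnot(inherits(pd_vol, "pd_volume"))
  mask <- pd_vol$pd > 0
  if (!any(mask)) stop("empty tumor: no voxels carry dose")
  sv <- array(NA_real_, dim(pd_vol$pd))
  svm <- sessions_to_kill(pd_vol$pd[mask], threshold)
  sv[mask] <- svm
  n_complete <- max(svm)
  kf <- if (is.finite(n_complete)) {
    # cumulative fraction treated after each session, from the count table
    counts <- tabulate(svm, nbins = n_complete)
    cumsum(counts) / length(svm)
  } else numeric(0)
  structure(list(sessions_per_voxel = sv, n_complete = n_complete,
                 kill_fraction_by_session = kf,
                 n_tumor_voxels = sum(mask), threshold = threshold,
                 fluence_id = pd_vol$fluence_id,
                 ete = compute_ete(pd_vol$params)),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("session_plan: %d tumor voxels, ETE %.2f%%\n",
              x$n_tumor_voxels, 100 * x$ete))
  if (is.finite(x$n_complete)) {
    cat(sprintf("  complete treatment after %d session(s)\n", x$n_complete))
    kf <- x$kill_fraction_by_session
    show <- unique(round(seq(1, length(kf), length.out = min(6, length(kf)))))
    for (n in show)
      cat(sprintf("  after %3d: %5.1f%% of tumor voxels treated\n",
                  n, 100 * kf[n]))
  } else {
    cat("  tumor not fully treatable: some voxels receive zero dose\n")
  }
  invisible(x)
}

#' Write a session plan as JSON + CSV
#'
#' @param plan a `session_plan`
#' @param path_json JSON output path (summary)
#' @param path_csv optional CSV path for the voxel histogram of session
#'   counts
#' @return `path_json`, invisibly
#' @export
write_session_plan <- function(plan, path_json, path_csv = NULL) {
  sv <- plan$sessions_per_voxel
  sv <- sv[!is.na(sv)]
  jsonlite::write_json(list(n_complete = if (is.finite(plan$n_complete))
                              plan$n_complete else "unreachable",
                            n_tumor_voxels = plan$n_tumor_voxels,
                            threshold_photons_cm3 = plan$threshold,
                            ete = plan$ete,
                            fluence_id = plan$fluence_id,
                            kill_fraction_by_session =
                              plan$kill_fraction_by_session),
                       path_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (!is.null(path_csv)) {
    tab <- table(sv[is.finite(sv)])
    utils::write.csv(data.frame(sessions = as.integer(names(tab)),
                                n_voxels = as.integer(tab)),
                     path_csv, row.names = FALSE)
  }
  invisible(path_json)
}
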