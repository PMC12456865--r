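#' Tissue optical properties at 808 nm
#'
#' Default per-tissue absorption coefficient (`mu_a`, 1/cm), scattering
#' coefficient (`mu_s`, 1/cm), refractive index (`n`) and Henyey-Greenstein
#' anisotropy (`g`) at the 808-nm excitation wavelength. The tumor row
#' includes the photosensitizer construct: its absorption is the 0.10 1/cm
#' tissue baseline plus the 0.38 1/cm contributed by UCQRs at a 75 mg/kg
#' intratumoral concentration. Air is transparent (`mu_a = mu_s = 0`,
#' `n = 1`).
#'
#' @param tumor_baseline_mu_a tumor tissue absorption without UCQRs (1/cm)
#' @param mu_a_ucqr UCQR absorption added to tumor voxels (1/cm)
#' @return `data.frame` with columns `tissue`, `code`, `mu_a`, `mu_s`, `n`,
#'   `g`, one row per tissue label
#' @export
default_optics_table <- function(tumor_baseline_mu_a = 0.10, mu_a_ucqr = 0.38) {
  data.frame(
    tissue = c("air", "skin", "fat", "duct", "tumor"),
    code = c(0L, 1L, 2L, 3L, 4L),
    mu_a = c(0, 1.35, 0.09, 0.06, tumor_baseline_mu_a + mu_a_ucqr),
    mu_s = c(0, 196, 108, 114, 98),
    n = c(1, 1.37, 1.45, 1.42, 1.45),
    g = c(0, 0.9, 0.9, 0.9, 0.9),
    stringsAsFactors = FALSE
  )
}

validate_optics_table <- function(table) {
  need <- c("code", "mu_a", "mu_s", "n", "g")
  if (!all(need %in% names(table))) stop("optics table missing columns")
  if (any(table$mu_a < 0) || any(table$mu_s < 0))
    stop("optical coefficients must be non-negative")
  if (any(table$n < 1)) stop("refractive index must be >= 1")
  if (any(abs(table$g) > 1)) stop("anisotropy must lie in [-1, 1]")
  invisible(table)
}

#' Map optical properties onto a labeled volume
#'
#' @param vol a [labeled_volume()]
#' @param table an optics table as returned by [default_optics_table()]
#' @return object of class `optical_volume`: the tissue-code grid plus a
#'   per-code property matrix `(mu_a, mu_s, n, g)` and the voxel pitch
#' @export
assign_optics <- function(vol, table = default_optics_table()) {
  stopifnot(inherits(vol, "labeled_volume"))
  validate_optics_table(table)
  present <- unique(as.vector(vol$labels))
  missing <- setdiff(present, table$code)
  if (length(missing))
    stop("unmapped label(s) in optics table: ", paste(missing, collapse = ", "))
  ncode <- max(table$code) + 1L
  props <- matrix(0, nrow = ncode, ncol = 4,
                  dimnames = list(NULL, c("mu_a", "mu_s", "n", "g")))
  props[table$code + 1L, ] <- as.matrix(table[, c("mu_a", "mu_s", "n", "g")])
  structure(list(tissue = vol$labels, props = props,
                 pitch_mm = vol$pitch_mm, table = table),
            class = "optical_volume")
}

#' Irradiation beam specification
#'
#' The beam is a collimated field directed along the body (slice-stacking)
#' axis, entering the grid at slice 1. The default delivers 330 mW/cm^2 over
#' the full entry face; a disc footprint can be requested instead.
#'
#' @param irradiance_mW_cm2 power density on the entry face (default 330)
#' @param field `"full"` (whole entry face) or `"disc"`
#' @param center_mm disc center `c(x, y)` in mm (disc field only)
#' @param radius_mm disc radius in mm (disc field only)
#' @param wavelength_nm bookkeeping only (default 808)
#' @return object of class `beam_spec`
#' @export
beam_spec <- function(irradiance_mW_cm2 = 330, field = c("full", "disc"),
                      center_mm = NULL, radius_mm = NULL,
                      wavelength_nm = 808) {
  field <- match.arg(field)
  if (irradiance_mW_cm2 <= 0) stop("irradiance must be positive")
  if (field == "disc" && (is.null(center_mm) || is.null(radius_mm)))
    stop("disc field needs center_mm and radius_mm")
  structure(list(irradiance_mW_cm2 = irradiance_mW_cm2, field = field,
                 center_mm = center_mm, radius_mm = radius_mm,
                 wavelength_nm = wavelength_nm),
            class = "beam_spec")
}

#' Session radiant exposure
#'
#' Total energy per unit area delivered by one irradiation session,
#' `irradiance x duration`, in J/cm^2 (330 mW/cm^2 for 606 s gives about
#' 200 J/cm^2, a typical single-exposure PDT dose).
#'
#' @param beam a [beam_spec()]
#' @param t_session_s session duration in seconds
#' @return exposure in J/cm^2
#' @export
session_exposure_J_cm2 <- function(beam = beam_spec(), t_session_s = 606) {
  beam$irradiance_mW_cm2 / 1000 * t_session_s
}
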