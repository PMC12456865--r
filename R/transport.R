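#' Sample a free path length
#'
#' Inverse-CDF exponential sample `-log(u) / mu_t`; the mean over many draws
#' is the mean free path `1 / mu_t`.
#'
#' @param mu_t interaction coefficient (1/cm), must be positive
#' @param u uniform(0,1) deviates
#' @return path lengths in cm
#' @export
sample_free_path <- function(mu_t, u) {
  if (!is.numeric(mu_t) || any(mu_t <= 0)) stop("mu_t must be positive")
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sample of `cos(theta)` from the Henyey-Greenstein phase
#' function with anisotropy `g`; `E[cos theta] = g`. For `g = 0` the
#' scattering is isotropic (`2u - 1`).
#'
#' @param g anisotropy factor in `[-1, 1]`
#' @param u uniform(0,1) deviates
#' @return sampled cosines in `[-1, 1]`
#' @export
sample_hg_cosine <- function(g, u) {
  if (abs(g) > 1) stop("anisotropy must lie in [-1, 1]")
  if (abs(g) < 1e-8) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  (1 + g^2 - t^2) / (2 * g)
}

#' Henyey-Greenstein cumulative distribution of the scattering cosine
#'
#' @param x cosine values
#' @param g anisotropy factor
#' @return `P(cos theta <= x)`
#' @export
hg_cdf <- function(x, g) {
  if (abs(g) < 1e-8) return(pmin(1, pmax(0, (x + 1) / 2)))
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances; returns 1 beyond the
#' critical angle (total internal reflection).
#'
#' @param n1 refractive index of the incident medium
#' @param n2 refractive index of the transmitting medium
#' @param cos_incident cosine of the incidence angle, in `(0, 1]`
#' @return reflection probability
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (any(n1 < 1) || any(n2 < 1)) stop("refractive indices must be >= 1")
  ratio <- n1 / n2
  sin_t2 <- ratio^2 * (1 - cos_incident^2)
  cos_t <- sqrt(pmax(0, 1 - sin_t2))
  rs <- ((n1 * cos_incident - n2 * cos_t) / (n1 * cos_incident + n2 * cos_t))^2
  rp <- ((n1 * cos_t - n2 * cos_incident) / (n1 * cos_t + n2 * cos_incident))^2
  r <- (rs + rp) / 2
  r[n1 == n2] <- 0
  r[sin_t2 >= 1] <- 1
  r
}

#' Run Monte Carlo photon transport
#'
#' Launches weighted photon packets uniformly over the beam field along the
#' body axis and scores per-voxel fluence rate. Packets undergo specular
#' Fresnel reflection at the ambient-air entry, continuous absorption
#' deposition along each traversed segment, Henyey-Greenstein scattering at
#' interaction sites sampled from `mu_s`, Fresnel reflection/refraction at
#' voxel faces where the refractive index changes (disable with
#' `internal_fresnel = FALSE`, e.g. for Beer-Lambert validation), and
#' Russian roulette termination below the weight threshold. Fluence is
#' recovered from the absorption score as `phi = A / (mu_a V)` and scaled so
#' the source delivers `irradiance x field area`; air voxels score zero.
#'
#' Every run carries an energy-conservation ledger: launched weight equals
#' absorbed + reflected (escaped through the entry face) + transmitted
#' (escaped elsewhere) to within 1e-6.
#'
#' @param optvol an `optical_volume` from [assign_optics()]
#' @param beam a [beam_spec()]
#' @param n_photons number of packets (default 1e6)
#' @param seed integer seed; packet `p` uses an RNG substream keyed by
#'   `(seed, p)`, so results do not depend on execution order
#' @param internal_fresnel honor refractive-index mismatches at interior
#'   voxel faces? (default `TRUE`)
#' @param roulette_threshold weight below which Russian roulette triggers
#' @param roulette_survival survival probability (survivor weight is divided
#'   by this)
#' @return object of class `fluence_volume`: `phi` (mW/cm^2 array),
#'   `ledger`, `n_photons`, `seed`, `pitch_mm`, `beam`, and a provenance
#'   `id` reused by downstream dose volumes
#' @export
run_transport <- function(optvol, beam = beam_spec(), n_photons = 1e6,
                          seed = 1, internal_fresnel = TRUE,
                          roulette_threshold = 1e-4,
                          roulette_survival = 0.1) {
  stopifnot(inherits(optvol, "optical_volume"))
  if (n_photons < 1) stop("need at least one photon packet")
  d <- dim(optvol$tissue)
  pitch_cm <- optvol$pitch_mm / 10

  if (beam$field == "disc") {
    cx <- beam$center_mm[1] / optvol$pitch_mm
    cy <- beam$center_mm[2] / optvol$pitch_mm
    r <- beam$radius_mm / optvol$pitch_mm
    if (cx + r < 0 || cx - r > d[1] || cy + r < 0 || cy - r > d[2])
      stop("beam field outside grid")
    area_cm2 <- pi * (beam$radius_mm / 10)^2
    res <- mc_transport_cpp(as.vector(optvol$tissue), as.integer(d),
                            optvol$props, pitch_cm, 1L, 0, 0, 0, 0,
                            cx, cy, r, n_photons, as.integer(seed),
                            as.integer(internal_fresnel),
                            roulette_threshold, roulette_survival)
  } else {
    area_cm2 <- d[1] * d[2] * pitch_cm^2
    res <- mc_transport_cpp(as.vector(optvol$tissue), as.integer(d),
                            optvol$props, pitch_cm, 0L, 0, d[1], 0, d[2],
                            0, 0, 0, n_photons, as.integer(seed),
                            as.integer(internal_fresnel),
                            roulette_threshold, roulette_survival)
  }

  w_mW <- beam$irradiance_mW_cm2 * area_cm2 / n_photons
  mua <- array(optvol$props[as.vector(optvol$tissue) + 1L, "mu_a"], d)
  phi <- array(res$deposit, d) * w_mW
  nz <- mua > 0
  phi[nz] <- phi[nz] / (mua[nz] * pitch_cm^3)
  phi[!nz] <- 0

  ledger <- list(launched = res$launched, absorbed = res$absorbed,
                 reflected = res$reflected, transmitted = res$transmitted)
  structure(list(phi = phi, ledger = ledger, n_photons = n_photons,
                 seed = as.integer(seed), pitch_mm = optvol$pitch_mm,
                 beam = beam, internal_fresnel = internal_fresnel,
                 id = sprintf("mc-%d-%d-%s", as.integer(seed),
                              as.integer(n_photons),
                              paste(d, collapse = "x"))),
            class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("fluence_volume: %d x %d x %d voxels, %g packets, seed %d\n",
              d[1], d[2], d[3], x$n_photons, x$seed))
  cat(sprintf("  ledger: absorbed %.4f, reflected %.4f, transmitted %.4f (sum %.6f)\n",
              x$ledger$absorbed, x$ledger$reflected, x$ledger$transmitted,
              x$ledger$absorbed + x$ledger$reflected + x$ledger$transmitted))
  invisible(x)
}

#' Write a fluence volume and its conservation ledger
#'
#' @param fluence a `fluence_volume`
#' @param path output `.nii`/`.nii.gz` path (ledger goes to a JSON sidecar)
#' @return `path`, invisibly
#' @export
write_fluence <- function(fluence, path) {
  write_volume(fluence, path)
  jsonlite::write_json(c(fluence$ledger,
                         list(n_photons = fluence$n_photons,
                              seed = fluence$seed, id = fluence$id,
                              internal_fresnel = fluence$internal_fresnel)),
                       sidecar_path(path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
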