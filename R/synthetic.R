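#' Parameters of the synthetic prone-breast phantom generator
#'
#' The generator emulates the geometry of CT-derived labeled breast
#' phantoms: a pendant hemiellipsoidal breast with its apex facing the
#' irradiation (body) axis, a thin closed skin shell, and a binary fat/duct
#' interior whose glandular density is controlled exactly. A solid duct
#' "host" block can be guaranteed at a requested depth so that downstream
#' tumor embedding never depends on random-field luck.
#'
#' @param semi_axes_mm semi-axes (mm) of the hemiellipsoid, or `NULL` to
#'   auto-fit the grid at generation time
#' @param skin_thickness_mm skin shell thickness (mm); default 1.5
#' @param target_density requested duct/(duct+fat) fraction, in `[0, 0.45]`
#' @param duct_correlation_mm correlation length (Gaussian sigma, mm) of the
#'   duct texture field; default 4
#' @param host_depth_mm depth (mm, from the outer apex skin surface along
#'   the beam axis) at which the guaranteed host block places the top of a
#'   `host_for_diameter_mm` sphere; must lie in `[10, 30]`
#' @param host_size_mm edge (mm) of the guaranteed solid duct cube (>= 9)
#' @param host_block place the guaranteed host block? (default `TRUE`)
#' @param host_for_diameter_mm tumor diameter (mm) the host guarantee is
#'   sized for; default 7
#' @param seed integer seed controlling the duct texture
#' @return object of class `synthetic_params`
#' @export
synthetic_params <- function(semi_axes_mm = NULL, skin_thickness_mm = 1.5,
                             target_density = 0.2, duct_correlation_mm = 4,
                             host_depth_mm = 20, host_size_mm = 9,
                             host_block = TRUE, host_for_diameter_mm = 7,
                             seed = 1) {
  if (target_density < 0 || target_density > 0.45)
    stop("target_density must lie in [0, 0.45]")
  if (host_depth_mm < 10 || host_depth_mm > 30)
    stop("host_depth_mm must lie in [10, 30]")
  if (host_size_mm < host_for_diameter_mm)
    stop("host block must be at least as wide as the guaranteed sphere")
  structure(list(semi_axes_mm = semi_axes_mm,
                 skin_thickness_mm = skin_thickness_mm,
                 target_density = target_density,
                 duct_correlation_mm = duct_correlation_mm,
                 host_depth_mm = host_depth_mm,
                 host_size_mm = host_size_mm,
                 host_block = host_block,
                 host_for_diameter_mm = host_for_diameter_mm,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

auto_semi_axes <- function(dim, pitch_mm) {
  c(0.42 * min(dim[1], dim[2]) * pitch_mm,
    0.42 * min(dim[1], dim[2]) * pitch_mm,
    0.82 * dim[3] * pitch_mm)
}

#' Generate the breast contour (air / skin / fat)
#'
#' Builds a pendant hemiellipsoid with its flat base on the far (chest-wall)
#' face of the grid and its apex pointing toward slice 1, i.e. toward the
#' incoming beam. The skin shell is carved with an exact Euclidean distance
#' transform from the air interface, so its thickness is uniform to within
#' one voxel over the curved surface; the chest-wall base, which abuts the
#' grid boundary, carries no skin (it faces the body, not air).
#'
#' @param params a [synthetic_params()]
#' @param dim grid dimensions (default `c(120, 120, 120)`)
#' @param pitch_mm voxel pitch in mm (default 0.33)
#' @return a [labeled_volume()] containing AIR, SKIN and FAT only
#' @export
generate_breast_shape <- function(params, dim = c(120, 120, 120),
                                  pitch_mm = 0.33) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$skin_thickness_mm < pitch_mm)
    stop("skin thickness must be at least one voxel pitch")
  ax <- params$semi_axes_mm %||% auto_semi_axes(dim, pitch_mm)
  a <- ax[1]; b <- ax[2]; cc <- ax[3]
  if (2 * a > dim[1] * pitch_mm || 2 * b > dim[2] * pitch_mm ||
      cc > (dim[3] - 2) * pitch_mm)
    stop("breast shape too large for grid")
  cx <- dim[1] * pitch_mm / 2
  cy <- dim[2] * pitch_mm / 2
  zb <- dim[3] * pitch_mm  # flat base on the far face
  xs <- ((seq_len(dim[1]) - 0.5) * pitch_mm - cx) / a
  ys <- ((seq_len(dim[2]) - 0.5) * pitch_mm - cy) / b
  zs <- ((seq_len(dim[3]) - 0.5) * pitch_mm - zb) / cc
  qxy <- outer(xs^2, ys^2, "+")
  codes <- tissue_codes()
  lab <- array(codes[["AIR"]], dim)
  for (k in seq_len(dim[3])) {
    sl <- lab[, , k]
    sl[qxy + zs[k]^2 <= 1] <- codes[["FAT"]]
    lab[, , k] <- sl
  }
  d2 <- array(edt_sq_cpp(as.vector(lab == codes[["AIR"]]), as.integer(dim)), dim)
  skin <- lab == codes[["FAT"]] &
    sqrt(d2) <= params$skin_thickness_mm / pitch_mm
  lab[skin] <- codes[["SKIN"]]
  vol <- labeled_volume(lab, pitch_mm = pitch_mm)
  attr(vol, "provenance") <- list(params = unclass(params), dim = dim,
                                  semi_axes_mm = ax)
  vol
}

# smooth periodic Gaussian random field, separable FFT convolution
gaussian_random_field <- function(dims, sigma_vox) {
  w <- array(stats::rnorm(prod(dims)), dims)
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), if (n > 1) -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  fa <- Re(stats::fft(kern1(dims[1], sigma_vox)))
  fb <- Re(stats::fft(kern1(dims[2], sigma_vox)))
  fc <- Re(stats::fft(kern1(dims[3], sigma_vox)))
  f <- stats::fft(w) * outer(outer(fa, fb), fc)
  Re(stats::fft(f, inverse = TRUE)) / prod(dims)
}

# first non-air slice index per (x, y) column; Inf where the beam misses
entry_map <- function(labels) {
  d <- dim(labels)
  entry <- matrix(Inf, d[1], d[2])
  for (k in rev(seq_len(d[3]))) {
    m <- labels[, , k] != tissue_codes()[["AIR"]]
    entry[m] <- k
  }
  entry
}

# centroid of the columns the beam reaches first (the breast apex)
apex_column <- function(labels) {
  entry <- entry_map(labels)
  k0 <- min(entry)
  if (!is.finite(k0)) stop("volume contains no tissue")
  hit <- which(entry == k0, arr.ind = TRUE)
  c(i = round(mean(hit[, 1])), j = round(mean(hit[, 2])), k = k0)
}

#' Carve the glandular duct structure into a breast shape
#'
#' Converts interior fat voxels to milk duct until the voxel-tally density
#' matches `target_density`, using a thresholded Gaussian random field with
#' the stated correlation length (highest field values become duct, which
#' yields connected glandular blobs). When `host_block` is set, a solid duct
#' cube is first placed below the apex so that the shallowest admissible
#' `host_for_diameter_mm` sphere sits exactly at `host_depth_mm`; the block
#' counts toward the density budget.
#'
#' @param shape_vol output of [generate_breast_shape()]
#' @param params the same [synthetic_params()]
#' @return a [labeled_volume()] with DUCT carved into FAT; the `"host"`
#'   attribute records the guaranteed block (center, depth) and the
#'   `"provenance"` attribute echoes the generator parameters and the
#'   measured density
#' @export
generate_duct_field <- function(shape_vol, params) {
  stopifnot(inherits(shape_vol, "labeled_volume"),
            inherits(params, "synthetic_params"))
  codes <- tissue_codes()
  lab <- shape_vol$labels
  pitch <- shape_vol$pitch_mm
  d <- dim(lab)
  interior <- lab == codes[["FAT"]]
  n_interior <- sum(interior)
  if (n_interior == 0) stop("breast shape has no interior fat")

  host <- NULL
  block <- array(FALSE, d)
  if (isTRUE(params$host_block)) {
    apex <- apex_column(lab)
    r_vox <- (params$host_for_diameter_mm / 2) / pitch
    top_off <- floor(r_vox - 1e-9)
    nw <- ceiling(params$host_size_mm / pitch)
    if (nw %% 2 == 0) nw <- nw + 1
    h <- (nw - 1) / 2
    slack <- floor(h + 1 - r_vox + 1e-9)
    if (slack < 0) stop("host block too small for the guaranteed sphere")
    bc <- c(apex[["i"]], apex[["j"]],
            apex[["k"]] + round(params$host_depth_mm / pitch) + top_off + slack)
    rng <- lapply(1:3, function(a) (bc[a] - h):(bc[a] + h))
    if (any(rng[[1]] < 1 | rng[[1]] > d[1]) ||
        any(rng[[2]] < 1 | rng[[2]] > d[2]) ||
        any(rng[[3]] < 1 | rng[[3]] > d[3]))
      stop("host block does not fit inside the grid")
    if (!all(lab[rng[[1]], rng[[2]], rng[[3]]] == codes[["FAT"]]))
      stop("host block does not fit inside the breast interior")
    block[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    host <- list(center = bc, half_width_vox = h,
                 depth_mm = params$host_depth_mm, slack_vox = slack)
  }

  n_block <- sum(block)
  need_total <- round(params$target_density * n_interior)
  need_extra <- max(0L, need_total - n_block)
  avail <- interior & !block
  if (need_extra > sum(avail))
    stop("target density unreachable inside the breast contour")
  if (need_extra > 0) {
    field <- with_seed(params$seed, gaussian_random_field(
      d, params$duct_correlation_mm / pitch))
    idx <- which(avail)
    take <- idx[order(field[idx], decreasing = TRUE)[seq_len(need_extra)]]
    lab[take] <- codes[["DUCT"]]
  }
  lab[block] <- codes[["DUCT"]]

  vol <- labeled_volume(lab, pitch_mm = pitch, origin = shape_vol$origin)
  attr(vol, "host") <- host
  attr(vol, "provenance") <- c(attr(shape_vol, "provenance"),
                               list(measured_density = compute_breast_density(vol)))
  vol
}

#' Generate a full synthetic phantom (contour + ducts)
#'
#' Convenience wrapper chaining [generate_breast_shape()] and
#' [generate_duct_field()].
#'
#' @inheritParams generate_breast_shape
#' @return a [labeled_volume()]
#' @export
generate_phantom <- function(params, dim = c(120, 120, 120), pitch_mm = 0.33) {
  generate_duct_field(generate_breast_shape(params, dim, pitch_mm), params)
}

#' Cohort density distribution
#'
#' Mixture of uniform bins emulating the density histogram of the CT-derived
#' phantom cohorts the pipeline is modeled on: most mass below 0.30 raw
#' density (bin weights 84/46/17/3 out of 150 over
#' `[0,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.45)`).
#'
#' @param prob bin probabilities (normalized internally)
#' @param breaks list of `c(lo, hi)` bin supports, all within `[0, 0.45]`
#' @return object of class `density_mixture`
#' @export
density_mixture <- function(prob = c(84, 46, 17, 3) / 150,
                            breaks = list(c(0, 0.1), c(0.1, 0.2),
                                          c(0.2, 0.3), c(0.3, 0.45))) {
  if (length(prob) != length(breaks) || any(prob < 0) || sum(prob) <= 0)
    stop("invalid density distribution spec")
  for (b in breaks)
    if (length(b) != 2 || b[1] < 0 || b[2] > 0.45 || b[1] >= b[2])
      stop("invalid density distribution spec")
  structure(list(prob = prob / sum(prob), breaks = breaks),
            class = "density_mixture")
}

#' Probability mass of a density mixture below a cutoff
#'
#' @param mix a [density_mixture()]
#' @param x cutoff density
#' @return `P(density < x)` under the mixture
#' @export
mixture_mass_below <- function(mix, x) {
  stopifnot(inherits(mix, "density_mixture"))
  sum(vapply(seq_along(mix$prob), function(i) {
    b <- mix$breaks[[i]]
    mix$prob[i] * min(1, max(0, (x - b[1]) / (b[2] - b[1])))
  }, numeric(1)))
}

sample_mixture <- function(mix, n) {
  bin <- sample.int(length(mix$prob), n, replace = TRUE, prob = mix$prob)
  lo <- vapply(mix$breaks, `[`, numeric(1), 1)[bin]
  hi <- vapply(mix$breaks, `[`, numeric(1), 2)[bin]
  stats::runif(n, lo, hi)
}

#' Generate a cohort of synthetic phantoms
#'
#' Draws target densities from `distribution`, generates one phantom per
#' draw (each with its own derived seed) and assembles the phantom records
#' with the generator's ground truth. The host block is off by default here:
#' cohort phantoms serve density/classification statistics, and guaranteed
#' hosts would bias the density floor at small grids.
#'
#' @param n number of phantoms (>= 1)
#' @param dim per-phantom grid dimensions
#' @param pitch_mm voxel pitch (mm)
#' @param distribution a [density_mixture()]
#' @param seed cohort seed; phantom `i` uses a seed derived from `(seed, i)`
#' @param host_block place guaranteed host blocks? (default `FALSE`)
#' @return list with `volumes` (list of [labeled_volume()]), `records`
#'   (a `data.frame` of [phantom_record()] rows carrying measured densities)
#'   and `target_densities`
#' @export
generate_cohort <- function(n, dim = c(64, 64, 64), pitch_mm = 0.33,
                            distribution = density_mixture(), seed = 1,
                            host_block = FALSE) {
  if (!is.numeric(n) || n < 1) stop("cohort size must be at least 1")
  n <- as.integer(n)
  targets <- with_seed(seed, sample_mixture(distribution, n))
  volumes <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- synthetic_params(target_density = targets[i],
                          host_block = host_block,
                          seed = child_seed(seed, i))
    volumes[[i]] <- generate_phantom(p, dim = dim, pitch_mm = pitch_mm)
    records[[i]] <- phantom_record(sprintf("SYN-%03d", i),
                                   compute_breast_density(volumes[[i]]),
                                   eligible = host_block)
  }
  list(volumes = volumes, records = do.call(rbind, records),
       target_densities = targets)
}
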