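# shared fixture builders; everything is generated in code at test time

codes <- tissue_codes()

# layered slab phantom along the beam axis: air on top, optional skin,
# then fat, with an optional duct band given as slice range
make_slab <- function(dims = c(40, 40, 60), pitch = 0.5,
                      air_k = 1:5, skin_k = integer(0), duct_k = integer(0)) {
  lab <- array(codes[["FAT"]], dims)
  lab[, , air_k] <- codes[["AIR"]]
  if (length(skin_k)) lab[, , skin_k] <- codes[["SKIN"]]
  if (length(duct_k)) lab[, , duct_k] <- codes[["DUCT"]]
  labeled_volume(lab, pitch_mm = pitch)
}

# small hemiellipsoid phantom with a guaranteed host block, fast to build
host_phantom <- function(host_depth_mm = 15, target_density = 0,
                         seed = 3, dim = c(72, 72, 90),
                         semi_axes = c(10, 10, 26), host = TRUE) {
  p <- synthetic_params(semi_axes_mm = semi_axes,
                        target_density = target_density,
                        host_depth_mm = host_depth_mm,
                        host_block = host, seed = seed)
  generate_phantom(p, dim = dim, pitch_mm = 0.33)
}

# independent brute-force sphere voxelization (center-inclusion rule)
brute_sphere <- function(center, diameter_mm, pitch_mm) {
  r <- (diameter_mm / 2) / pitch_mm
  m <- ceiling(r) + 1
  ids <- NULL
  for (dx in -m:m) for (dy in -m:m) for (dz in -m:m)
    if (dx^2 + dy^2 + dz^2 < r^2)
      ids <- rbind(ids, center + c(dx, dy, dz))
  ids
}

# independent ray-march depth oracle along the beam axis
raymarch_depth <- function(vol, voxel_ids) {
  ctr <- round(colMeans(voxel_ids))
  k <- 1
  while (vol$labels[ctr[1], ctr[2], k] == codes[["AIR"]]) k <- k + 1
  (min(voxel_ids[, 3]) - k) * vol$pitch_mm
}

# fabricate a fluence_volume with a given phi array (for report arithmetic)
fake_fluence <- function(phi, pitch = 0.33) {
  structure(list(phi = phi, pitch_mm = pitch, id = "fake",
                 n_photons = 0, seed = 0,
                 ledger = list(launched = 1, absorbed = 1,
                               reflected = 0, transmitted = 0)),
            class = "fluence_volume")
}
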