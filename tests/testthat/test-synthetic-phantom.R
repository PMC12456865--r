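test_that("skin shell has the requested thickness against a brute-force oracle", {
  p <- synthetic_params(semi_axes_mm = c(5.5, 5.5, 7), skin_thickness_mm = 1.0,
                        host_block = FALSE, target_density = 0)
  vol <- generate_breast_shape(p, dim = c(40, 40, 30), pitch_mm = 0.33)
  lab <- vol$labels
  air <- which(lab == codes[["AIR"]], arr.ind = TRUE)
  t_vox <- 1.0 / 0.33

  skin <- which(lab == codes[["SKIN"]], arr.ind = TRUE)
  fat <- which(lab == codes[["FAT"]], arr.ind = TRUE)
  set.seed(1)
  dist_to_air <- function(v) sqrt(min((air[, 1] - v[1])^2 +
                                      (air[, 2] - v[2])^2 +
                                      (air[, 3] - v[3])^2))
  for (i in sample(nrow(skin), 100))
    expect_lte(dist_to_air(skin[i, ]), t_vox + 1e-9)
  for (i in sample(nrow(fat), 100))
    expect_gt(dist_to_air(fat[i, ]), t_vox)
})

test_that("one-pitch skin is exactly one voxel thick at the apex", {
  p <- synthetic_params(semi_axes_mm = c(5.5, 5.5, 7), skin_thickness_mm = 0.33,
                        host_block = FALSE, target_density = 0)
  vol <- generate_breast_shape(p, dim = c(40, 40, 30), pitch_mm = 0.33)
  apex_col <- vol$labels[20, 20, ]
  expect_equal(sum(apex_col == codes[["SKIN"]]), 1)
})

test_that("shape generation is deterministic and validates its inputs", {
  p <- synthetic_params(semi_axes_mm = c(5, 5, 6), target_density = 0.2,
                        host_block = FALSE, seed = 9)
  v1 <- generate_phantom(p, dim = c(36, 36, 28), pitch_mm = 0.33)
  v2 <- generate_phantom(p, dim = c(36, 36, 28), pitch_mm = 0.33)
  expect_identical(v1$labels, v2$labels)

  expect_error(generate_breast_shape(
    synthetic_params(semi_axes_mm = c(50, 50, 60), host_block = FALSE),
    dim = c(40, 40, 40), pitch_mm = 0.33), "too large")
  expect_error(synthetic_params(target_density = 0.6), "0.45")
  expect_error(synthetic_params(host_depth_mm = 40), "\\[10, 30\\]")
})

test_that("duct carving recovers the target density and differs across seeds", {
  mk <- function(seed) {
    p <- synthetic_params(semi_axes_mm = c(8, 8, 11), target_density = 0.30,
                          host_block = FALSE, seed = seed)
    generate_phantom(p, dim = c(56, 56, 42), pitch_mm = 0.33)
  }
  v7 <- mk(7); v8 <- mk(8)
  expect_lt(abs(compute_breast_density(v7) - 0.30), 0.02)
  expect_lt(abs(compute_breast_density(v8) - 0.30), 0.02)
  expect_false(identical(v7$labels, v8$labels))

  # target 0 without a host block means a pure-fat interior
  p0 <- synthetic_params(semi_axes_mm = c(8, 8, 11), target_density = 0,
                         host_block = FALSE)
  v0 <- generate_phantom(p0, dim = c(56, 56, 42), pitch_mm = 0.33)
  expect_equal(label_counts(v0)[["DUCT"]], 0L)
})

test_that("skin shell is topologically closed (no soft tissue touches air)", {
  vol <- host_phantom(host_depth_mm = 15, target_density = 0.25, seed = 5)
  lab <- vol$labels
  d <- dim(lab)
  air <- lab == codes[["AIR"]]
  soft <- lab == codes[["FAT"]] | lab == codes[["DUCT"]]
  adjacency <- 0
  for (ax in 1:3) for (s in c(1L, -1L)) {
    i1 <- lapply(d, seq_len); i2 <- i1
    if (s > 0) { i1[[ax]] <- 1:(d[ax] - 1); i2[[ax]] <- 2:d[ax] }
    else { i1[[ax]] <- 2:d[ax]; i2[[ax]] <- 1:(d[ax] - 1) }
    adjacency <- adjacency + sum(do.call(`[`, c(list(soft), i1)) &
                                 do.call(`[`, c(list(air), i2)))
  }
  expect_equal(adjacency, 0)
})

test_that("cohorts are reproducible and match the declared density mixture", {
  c1 <- generate_cohort(6, dim = c(40, 40, 32), seed = 2)
  c2 <- generate_cohort(6, dim = c(40, 40, 32), seed = 2)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$volumes[[3]]$labels, c2$volumes[[3]]$labels)
  expect_equal(nrow(c1$records), 6)

  expect_error(generate_cohort(0), "at least 1")
  expect_error(density_mixture(prob = c(1, 1), breaks = list(c(0, 0.1))),
               "invalid")
  expect_error(density_mixture(breaks = list(c(0, 0.6))), "invalid")

  # default mixture: targets below 0.30 occur with the mixture mass, within
  # 3-sigma binomial noise (closed form from the mixture itself)
  mix <- density_mixture()
  n <- 150
  targets <- with(new.env(), {
    c150 <- generate_cohort(n, dim = c(32, 32, 26), seed = 10)
    c150$target_densities
  })
  p <- mixture_mass_below(mix, 0.30)
  obs <- mean(targets < 0.30)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
})
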