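test_that("optics assignment carries the 808-nm table onto voxels", {
  tab <- default_optics_table()
  vol <- make_slab(c(8, 8, 12), pitch = 0.33, air_k = 1:2, skin_k = 3,
                   duct_k = 8:9)
  ov <- assign_optics(vol, tab)
  skin_row <- ov$props[codes[["SKIN"]] + 1, ]
  expect_equal(unname(skin_row), c(1.35, 196, 1.37, 0.9))
  # tumor absorption = 0.10 tissue baseline + 0.38 from UCQRs
  expect_equal(tab$mu_a[tab$tissue == "tumor"], 0.48)
  expect_equal(default_optics_table(0.10, 0.38)$mu_a[5], 0.10 + 0.38)

  # a label missing from the table is rejected
  lab <- vol$labels; lab[4, 4, 10] <- codes[["TUMOR"]]
  vol_t <- labeled_volume(lab, 0.33)
  expect_error(assign_optics(vol_t, tab[tab$tissue != "tumor", ]), "unmapped")
})

test_that("free-path sampling matches the exponential closed form", {
  expect_equal(sample_free_path(1, 0.5), log(2))
  mu_t <- 0.09 + 108  # fat mu_a + mu_s
  set.seed(21)
  u <- runif(1e5)
  s <- sample_free_path(mu_t, u)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / mu_t), 3 * se)
  expect_error(sample_free_path(0, 0.5), "positive")
})

test_that("Henyey-Greenstein sampling has mean g and the analytic CDF", {
  set.seed(22)
  u <- runif(2e5)
  iso <- sample_hg_cosine(0, u)
  expect_lt(abs(mean(iso)), 3 * sd(iso) / sqrt(length(iso)))

  x <- sample_hg_cosine(0.9, u)
  expect_lt(abs(mean(x) - 0.9), 3 * sd(x) / sqrt(length(x)))
  expect_true(all(x >= -1 & x <= 1))

  ks <- suppressWarnings(stats::ks.test(x[1:5000], function(q) hg_cdf(q, 0.9)))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_hg_cosine(1.2, 0.5), "\\[-1, 1\\]")
})

test_that("Fresnel reflectance reproduces the closed forms", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.7), 0)
  expect_equal(fresnel_reflectance(1.0, 1.37, 1.0), (0.37 / 2.37)^2)
  # beyond the critical angle: total internal reflection
  expect_equal(fresnel_reflectance(1.45, 1.0, 0.1), 1)
})

test_that("transport conserves energy and scales linearly with irradiance", {
  vol <- host_phantom(target_density = 0.2, seed = 6, dim = c(48, 48, 60),
                      semi_axes = c(6.5, 6.5, 17), host = FALSE)
  ov <- assign_optics(vol)
  fl <- run_transport(ov, beam_spec(), n_photons = 2e4, seed = 3)
  with(fl$ledger, expect_lt(abs(absorbed + reflected + transmitted - launched),
                            1e-6))
  expect_true(all(fl$phi >= 0))

  fl2 <- run_transport(ov, beam_spec(irradiance_mW_cm2 = 660),
                       n_photons = 2e4, seed = 3)
  expect_equal(fl2$phi, 2 * fl$phi)
})

test_that("an all-air phantom transmits essentially everything", {
  vol <- labeled_volume(array(codes[["AIR"]], c(10, 10, 10)), 0.33)
  fl <- run_transport(assign_optics(vol), beam_spec(), n_photons = 5e3,
                      seed = 1)
  expect_equal(fl$ledger$transmitted, 1)
  expect_equal(sum(fl$phi), 0)
})

test_that("scatter-free fluence follows Beer-Lambert attenuation", {
  tab <- default_optics_table()
  tab$mu_s[] <- 0
  lab <- array(codes[["FAT"]], c(16, 16, 40))
  vol <- labeled_volume(lab, pitch_mm = 0.33)
  fl <- run_transport(assign_optics(vol, tab), beam_spec(), n_photons = 1e5,
                      seed = 7, internal_fresnel = FALSE)
  prof <- apply(fl$phi, 3, mean)
  # voxel 31 sits 30 voxel-lengths (0.99 cm) below the entry voxel
  expect_lt(abs(prof[31] / prof[1] - exp(-0.09 * 30 * 0.033)), 0.01)
})

test_that("the fluence field respects the phantom's mirror symmetry", {
  # duct block offset in +x; mirrored phantom must give the mirrored field
  mk <- function(flip) {
    lab <- array(codes[["FAT"]], c(40, 40, 40))
    lab[, , 1:3] <- codes[["AIR"]]
    xs <- if (flip) 5:14 else 27:36
    lab[xs, 16:25, 15:24] <- codes[["DUCT"]]
    labeled_volume(lab, pitch_mm = 0.33)
  }
  f1 <- run_transport(assign_optics(mk(FALSE)), beam_spec(),
                      n_photons = 1e5, seed = 9)
  f2 <- run_transport(assign_optics(mk(TRUE)), beam_spec(),
                      n_photons = 1e5, seed = 9)
  m2 <- f2$phi[40:1, , ]  # mirror back
  half <- function(phi) c(mean(phi[1:20, , 10:30]), mean(phi[21:40, , 10:30]))
  expect_lt(max(abs(half(f1$phi) - half(m2)) / half(f1$phi)), 0.05)
})

test_that("plane-mean fluence decays monotonically past the backscatter peak", {
  lab <- array(codes[["FAT"]], c(30, 30, 50))
  lab[, , 1:2] <- codes[["AIR"]]
  vol <- labeled_volume(lab, pitch_mm = 0.33)
  fl <- run_transport(assign_optics(vol), beam_spec(), n_photons = 5e4,
                      seed = 4)
  prof <- apply(fl$phi, 3, mean)[3:50]
  peak <- which.max(prof)
  after <- prof[peak:length(prof)]
  # allow 2% Monte Carlo jitter per plane
  expect_true(all(diff(after) <= 0.02 * after[-length(after)]))
})

test_that("doubling the packet count shrinks the standard error about sqrt(2)", {
  vol <- make_slab(c(20, 20, 24), pitch = 0.33, air_k = 1:2, skin_k = 3,
                   duct_k = 12:16)
  ov <- assign_optics(vol)
  mask <- vol$labels == codes[["DUCT"]]
  mt <- function(n, seed) tumor_fluence_summary(
    run_transport(ov, beam_spec(), n_photons = n, seed = seed), mask)$mean
  lo <- vapply(1:8, function(s) mt(2e3, s), numeric(1))
  hi <- vapply(1:8, function(s) mt(8e3, 100 + s), numeric(1))
  ratio <- sd(lo) / sd(hi)  # expect about 2 for a 4x packet count
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})
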