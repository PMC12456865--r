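test_that("one-decimal report rounding is half-up", {
  expect_equal(round_half_up(9.95, 1), 10.0)
  expect_equal(round_half_up(10.85, 1), 10.9)
  expect_equal(round_half_up(10.25, 1), 10.3)
  expect_equal(round_half_up(1.24, 1), 1.2)
  expect_equal(round_half_up(c(3.665, 4.887) , 1), c(3.7, 4.9))
})

test_that("depth profiles report plane means and adjacent differences", {
  phi <- array(0, c(6, 6, 10))
  mask <- array(FALSE, c(6, 6, 10))
  mask[2:5, 2:5, 4:6] <- TRUE
  phi[, , 4] <- 29.9; phi[, , 5] <- 18.3; phi[, , 6] <- 10.0
  fl <- fake_fluence(phi)
  dp <- depth_profile(fl, mask)
  expect_equal(dp$profile$mean_fluence, c(29.9, 18.3, 10.0))
  expect_equal(dp$profile$depth_mm, (3:5) * 0.33)
  expect_equal(dp$differences, c(11.6, 8.3))
  expect_equal(round_half_up(dp$mean_difference, 1), 10.0)
  expect_error(depth_profile(fl, array(FALSE, c(6, 6, 10))), "empty mask")

  # uniform field: all differences vanish
  fl2 <- fake_fluence(array(7, c(6, 6, 10)))
  expect_true(all(depth_profile(fl2, mask)$differences == 0))

  expect_equal(round_half_up(
    plane_difference_summary(c(29.9, 17.5, 8.2))$mean_difference, 1), 10.9)
  expect_equal(round_half_up(
    plane_difference_summary(c(29.9, 17.3, 9.4))$mean_difference, 1), 10.3)
})

test_that("tumor fluence summaries and cross-phantom range are exact", {
  phi <- array(5.5, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  s <- tumor_fluence_summary(fake_fluence(phi), mask)
  expect_equal(s$mean, 5.5)
  expect_equal(fluence_range(c(18.3, 19.5, 23.2)), 4.9)
  expect_equal(fluence_range(20), 0)
  expect_error(tumor_fluence_summary(fake_fluence(phi),
                                     array(FALSE, c(4, 4, 4))), "empty")
})

test_that("map rendering is deterministic and records its normalization", {
  arr <- array(seq_len(20^3) %% 97, c(20, 20, 20))
  f1 <- file.path(tempdir(), "map1.png")
  f2 <- file.path(tempdir(), "map2.png")
  render_map(arr, 10, f1)
  render_map(arr, 10, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  side <- jsonlite::read_json(sub("\\.png$", ".json", f1),
                              simplifyVector = TRUE)
  expect_equal(side$range, range(arr[, , 10]))
  expect_error(render_map(arr, 25, f1), "out of bounds")
})

pipeline_config <- function(outdir, n_photons = 2e4, host = TRUE) {
  list(phantom = list(source = "synthetic",
                      dim = c(72, 72, 96), pitch_mm = 0.33,
                      params = list(semi_axes_mm = c(10, 10, 28),
                                    target_density = 0.1,
                                    host_depth_mm = 15,
                                    host_block = host, seed = 12)),
       transport = list(n_photons = n_photons, seed = 2),
       dose = list(p_multi = c(0.2, 1.0)),
       output_dir = outdir)
}

test_that("the pipeline produces a reproducible report bundle", {
  out1 <- tempfile("run1-"); out2 <- tempfile("run2-")
  b1 <- run_pipeline(pipeline_config(out1))
  b2 <- run_pipeline(pipeline_config(out2))

  expect_true(b1$eligible)
  for (f in c("classification.csv", "tumor.json", "fluence.nii.gz",
              "depth_profile.csv", "sessions_by_ete.csv",
              "fluence_xsection.png", "report.json"))
    expect_true(file.exists(file.path(out1, f)))

  # reproducible under the same config + seed
  expect_equal(b1$fluence$phi, b2$fluence$phi)
  expect_identical(readLines(file.path(out1, "sessions_by_ete.csv")),
                   readLines(file.path(out2, "sessions_by_ete.csv")))

  # the ETE sweep reuses the single transport run
  ids <- vapply(b1$plans, `[[`, character(1), "fluence_id")
  expect_true(all(ids == b1$fluence$id))
  expect_true(all(diff(b1$sessions_by_ete$n_complete) <= 0))
})

test_that("ineligible phantoms report eligibility and skip transport", {
  out <- tempfile("run0-")
  cfg <- pipeline_config(out, host = FALSE)
  cfg$phantom$params$target_density <- 0  # pure fat: no duct anywhere
  b <- run_pipeline(cfg)
  expect_false(b$eligible)
  expect_true(file.exists(file.path(out, "eligibility.json")))
  expect_false(file.exists(file.path(out, "fluence.nii.gz")))
})

test_that("malformed configurations fail with a named stage", {
  expect_error(read_run_config(list(beam = list())), "phantom")
  expect_error(read_run_config(list(phantom = list(source = "dicom"))),
               "synthetic")
  expect_error(read_run_config(list(phantom = list(source = "file"))),
               "path")
})
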