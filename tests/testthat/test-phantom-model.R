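test_that("breast density is the duct fraction of soft tissue", {
  lab <- array(codes[["AIR"]], c(10, 10, 10))
  lab[1:8, 1:10, 1:10] <- codes[["FAT"]]
  lab[1:2, 1:10, 1:10] <- codes[["DUCT"]]
  vol <- labeled_volume(lab, 0.33)
  expect_equal(compute_breast_density(vol), 200 / 800)

  # skin and tumor voxels stay out of both numerator and denominator
  lab[3, 1:10, 1:10] <- codes[["SKIN"]]
  lab[4, 1, 1] <- codes[["TUMOR"]]
  vol2 <- labeled_volume(lab, 0.33)
  expect_equal(compute_breast_density(vol2), 200 / (200 + 499))

  all_fat <- labeled_volume(array(codes[["FAT"]], c(5, 5, 5)), 0.33)
  expect_equal(compute_breast_density(all_fat), 0)

  air_only <- labeled_volume(array(codes[["AIR"]], c(5, 5, 5)), 0.33)
  expect_error(compute_breast_density(air_only), "denominator")
})

test_that("label counts partition the voxel grid", {
  set.seed(11)
  lab <- array(sample(codes, 4000, replace = TRUE), c(20, 20, 10))
  vol <- labeled_volume(lab, 0.5)
  expect_equal(sum(label_counts(vol)), 4000L)
  expect_error(labeled_volume(array(9L, c(3, 3, 3))), "unknown label")
})

test_that("classification applies the 2.5x adjustment, cap and bin edges", {
  r <- classify_breast(0.16)
  expect_equal(r$adjusted_density_pct, 40)
  expect_equal(r$birads_class, "scattered")

  expect_equal(classify_breast(0.09)$adjusted_density_pct, 22.5)
  expect_equal(classify_breast(0.09)$birads_class, "fatty")

  r <- classify_breast(0.40)  # adjusted would be 100; capped top bin
  expect_equal(r$adjusted_density_pct, 100)
  expect_equal(r$birads_class, "extremely_dense")

  # half-open bins, top bin closed: every adjusted density gets one class
  edges <- classify_breast(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(edges$birads_class,
               c("scattered", "heterogeneous", "extremely_dense",
                 "extremely_dense"))
  dens <- seq(0, 1, by = 0.01)
  cls <- classify_breast(dens)$birads_class
  expect_true(all(cls %in% c("fatty", "scattered", "heterogeneous",
                             "extremely_dense")))
  expect_error(classify_breast(1.2), "\\[0, 1\\]")
})

test_that("representative selection is nearest-to-mean with id tie-break", {
  grp <- do.call(rbind, Map(phantom_record,
                            c("a", "b", "c"), c(0.30, 0.40, 0.50)))
  expect_equal(select_representative(grp)$id, "b")
  expect_equal(select_representative(grp[1, ])$id, "a")
  tie <- do.call(rbind, Map(phantom_record, c("b2", "a1"), c(0.30, 0.50)))
  expect_equal(select_representative(tie)$id, "a1")
  expect_error(select_representative(grp[0, ]), "empty")
})

test_that("NIfTI and slice-stack IO round-trip labels bit-identically", {
  set.seed(4)
  lab <- array(sample(codes, 20^3, replace = TRUE), c(20, 20, 20))
  vol <- labeled_volume(lab, pitch_mm = 0.33)

  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- load_label_stack(f)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$pitch_mm, 0.33)

  d <- tempfile("stack-")
  write_label_stack(vol, d)
  back2 <- load_label_stack(d)
  expect_identical(back2$labels, vol$labels)
  expect_equal(back2$pitch_mm, 0.33)
})

test_that("stack loading rejects malformed inputs", {
  vol <- make_slab(c(12, 12, 6), pitch = 0.33, air_k = 1)
  d <- tempfile("stack-")
  write_label_stack(vol, d)

  # one slice with mismatched dimensions
  png::writePNG(matrix(0, 12, 11), file.path(d, "slice_0003.png"))
  expect_error(load_label_stack(d), "inconsistent slice dimensions")

  # missing pitch sidecar
  d2 <- tempfile("stack-")
  write_label_stack(vol, d2)
  file.remove(file.path(d2, "stack.json"))
  expect_error(load_label_stack(d2), "sidecar")

  # pixel value outside the legend
  d3 <- tempfile("stack-")
  write_label_stack(vol, d3)
  png::writePNG(matrix(200 / 255, 12, 12), file.path(d3, "slice_0002.png"))
  expect_error(load_label_stack(d3), "outside legend")
})

test_that("a CT-style labeled slice stack reassembles to the declared grid", {
  # scaled-down stack with the same structure: n equal slices + pitch sidecar
  vol <- make_slab(c(40, 40, 40), pitch = 0.33, air_k = 1:4, skin_k = 5:6)
  d <- tempfile("stack-")
  write_label_stack(vol, d)
  back <- load_label_stack(d)
  expect_equal(dim(back$labels), c(40, 40, 40))
  expect_equal(back$pitch_mm, 0.33)
})

test_that("nearest-neighbor resampling preserves labels and volume", {
  vol <- make_slab(c(30, 30, 30), pitch = 0.25, air_k = 1:3, duct_k = 10:14)
  expect_identical(resample_iso(vol, 0.25), vol)

  out <- resample_iso(vol, 0.33)
  expect_true(all(unique(as.vector(out$labels)) %in%
                  unique(as.vector(vol$labels))))
  # physical extent preserved within one voxel per axis
  expect_true(all(abs(dim(out$labels) * 0.33 - dim(vol$labels) * 0.25) <= 0.33))
  expect_error(resample_iso(vol, -1), "positive")

  # fat sphere: physical volume conserved within 5% across pitches
  dims <- c(50, 50, 50)
  lab <- array(codes[["AIR"]], dims)
  ctr <- c(25, 25, 25)
  for (k in 1:dims[3]) {
    dz2 <- (k - ctr[3])^2
    sl <- outer((1:dims[1] - ctr[1])^2, (1:dims[2] - ctr[2])^2, "+") + dz2
    lab[, , k][sl < 20^2] <- codes[["FAT"]]
  }
  sph <- labeled_volume(lab, pitch_mm = 0.2)
  res <- resample_iso(sph, 0.33)
  v_in <- sum(sph$labels == codes[["FAT"]]) * 0.2^3
  v_out <- sum(res$labels == codes[["FAT"]]) * 0.33^3
  expect_lt(abs(v_out - v_in) / v_in, 0.05)
})
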