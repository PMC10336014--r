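test_that("rmse matches hand evaluation and is symmetric", {
  expect_identical(rmse(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(rmse(matrix(c(0, 0), 1), matrix(c(3, 4), 1)),
               sqrt((9 + 16) / 2))
  set.seed(1)
  a <- matrix(rnorm(20), 4); b <- matrix(rnorm(20), 4)
  expect_identical(rmse(a, b), rmse(b, a))
  expect_gt(rmse(a, b), 0)
  expect_error(rmse(a, matrix(0, 2, 2)), "shape")
})

test_that("registration of identical images returns a (near) zero field", {
  sl <- fx_liver_slice()
  fld <- register_bspline(sl$img, sl$img, spacing = 1.8)
  expect_lt(max(sqrt(fld$u1^2 + fld$u2^2)), 0.1)
  expect_lt(mdisp(fld, sl$mask), 0.1)
  expect_error(register_bspline(sl$img, matrix(NaN, 64, 64)), "finite")
})

test_that("registration recovers known rigid shifts within 15 percent", {
  sl <- fx_liver_slice()
  rec <- vapply(c(1, 2, 4), function(vox) {
    lab <- shift_img(sl$img, vox, 0)
    mdisp(register_bspline(sl$img, lab, spacing = 1.8), sl$mask)
  }, 0)
  truth <- c(1, 2, 4) * 1.8
  expect_true(all(abs(rec - truth) / truth < 0.15))
  # approximate linearity: the 1-voxel recovery is about half the 2-voxel one
  expect_lt(abs(rec[1] - rec[2] / 2) / (rec[2] / 2), 0.15)
})

test_that("mdisp samples the field on an in-liver lattice in mm", {
  sl <- fx_liver_slice()
  zero <- structure(list(u1 = matrix(0, 64, 64), u2 = matrix(0, 64, 64),
                         spacing = c(1.8, 1.8)), class = "mri4d_field")
  expect_identical(mdisp(zero, sl$mask), 0)

  unif <- structure(list(u1 = matrix(0, 64, 64), u2 = matrix(3.6, 64, 64),
                         spacing = c(1.8, 1.8)), class = "mri4d_field")
  full <- matrix(TRUE, 64, 64)
  expect_equal(mdisp(unif, full), 3.6)

  # the mask restricts sampling: 2 mm in the kept half, junk elsewhere
  half_mask <- full; half_mask[, 33:64] <- FALSE
  fld <- structure(list(u1 = matrix(0, 64, 64),
                        u2 = cbind(matrix(2, 64, 32), matrix(50, 64, 32)),
                        spacing = c(1.8, 1.8)), class = "mri4d_field")
  expect_equal(mdisp(fld, half_mask), 2)

  expect_error(mdisp(zero, matrix(FALSE, 64, 64)), "mask too small")
  tiny <- matrix(FALSE, 64, 64); tiny[2, 2] <- TRUE
  expect_equal(mdisp(zero, tiny, spacing_vox = 8L), 0)
})

test_that("dn_rmse explains away deformation but not intensity bias", {
  sl <- fx_liver_slice()
  sub <- sl$subject
  # moderate phantom warp: dn_rmse far below rmse
  d <- mri4d:::slice_displacement(sub, sl$lr, 0.7)
  lab <- mri4d:::.warp_field(sl$img, d$u_ap, d$u_si)
  r <- rmse(sl$img, lab)
  dn <- dn_rmse(sl$img, lab, spacing = 1.8)
  expect_lt(dn / r, 0.5)

  # identical images: both measures at zero
  expect_lt(dn_rmse(sl$img, sl$img, spacing = 1.8), 1e-6)

  # a pure intensity offset cannot be removed by registration
  off <- sl$img + 0.1
  expect_equal(dn_rmse(sl$img, off, spacing = 1.8), rmse(sl$img, off),
               tolerance = 0.05)

  # the documented mdisp pathology: an empty prediction registers nowhere
  empty <- matrix(0, 64, 64)
  fld <- register_bspline(empty, sl$img, spacing = 1.8)
  expect_lt(mdisp(fld, sl$mask), 0.1)
  expect_gt(rmse(empty, sl$img), 0.1)
})

test_that("evaluate_set reports per-pair measures with mean and 95th percentile", {
  sl <- fx_liver_slice()
  pairs <- list(list(pred = sl$img, label = sl$img, family = "pre"),
                list(pred = sl$img, label = shift_img(sl$img, 1, 0),
                     family = "pre"))
  rep <- evaluate_set(pairs, mask = sl$mask, grouping = "family")
  expect_identical(nrow(rep$samples), 2L)
  expect_true(all(c("rmse", "mdisp", "dn_rmse") %in% names(rep$samples)))
  expect_true(all(c("rmse_mean", "rmse_p95", "mdisp_mean", "mdisp_p95",
                    "dn_rmse_mean", "dn_rmse_p95") %in% names(rep$summary)))
  expect_lt(rep$samples$rmse[1], 1e-12)
  expect_lt(rep$samples$mdisp[1], 0.1)

  # documented percentile convention: linear interpolation
  expect_equal(unname(quantile(1:100, 0.95, type = 7)), 95.05)

  f <- tempfile(fileext = ".csv")
  write_report(rep, f)
  expect_true(file.exists(f))
  expect_error(evaluate_set(list()), "empty")
})
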