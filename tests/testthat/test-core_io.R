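test_that("z-score normalization whitens pooled intensities and is invertible", {
  # hand-evaluated example: mean 2, population sd 1
  z <- zscore_normalize(matrix(c(1, 1, 3, 3), 2), "s")
  expect_equal(unclass(z$images), matrix(c(-1, -1, 1, 1), 2))
  expect_equal(z$params$mean, 2)
  expect_equal(z$params$std, 1)

  set.seed(1)
  imgs <- lapply(1:4, function(i) matrix(rnorm(64, 100, 20), 8))
  out <- zscore_normalize(imgs, "s")
  pool <- unlist(out$images)
  expect_lt(abs(mean(pool)), 1e-9)
  expect_lt(abs(sqrt(mean((pool - mean(pool))^2)) - 1), 1e-6)
  back <- denormalize(out$images, out$params)
  expect_equal(back, imgs, tolerance = 1e-9)

  expect_error(zscore_normalize(matrix(5, 1, 2)), "degenerate")
  expect_equal(denormalize(matrix(c(-1, 1), 1),
                           structure(list(mean = 2, std = 1, subject_id = "s"),
                                     class = "mri4d_norm")),
               matrix(c(1, 3), 1))
  expect_error(denormalize(matrix(0, 1, 1),
                           structure(list(mean = 0, std = 0, subject_id = "s"),
                                     class = "mri4d_norm")), "std")
  expect_error(denormalize(matrix(0, 1, 1)), "missing")
})

test_that("acquisition budget conversion is linear at 180 pairs per minute", {
  expect_identical(minutes_to_pairs(2), 360L)
  expect_identical(minutes_to_pairs(1), 180L)
  expect_identical(minutes_to_pairs(24), 4320L)
  for (m in c(0.25, 0.5, 3, 7, 12)) {
    p <- minutes_to_pairs(m)
    expect_true(p == as.integer(p))
    expect_identical(minutes_to_pairs(2 * m), 2L * p)
  }
  expect_error(minutes_to_pairs(0), "minutes")
  expect_error(minutes_to_pairs(-1), "minutes")
})

test_that("NIfTI volume round-trip preserves voxels, spacing and axis order", {
  set.seed(3)
  v <- as_volume(array(rnorm(16^3), c(16, 16, 16)), 1.8)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(max(abs(v2$voxels - v$voxels)), 0)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_identical(v2$axes, c("LR", "AP", "SI"))

  # asymmetric dims expose axis-order bugs
  va <- as_volume(array(seq_len(4 * 6 * 8), c(4, 6, 8)), c(1, 2, 3))
  fa <- tempfile(fileext = ".nii.gz")
  write_volume(va, fa)
  expect_equal(read_volume(fa)$voxels, va$voxels)

  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), f2)
  expect_error(read_volume(f2), "rank 3")
  expect_error(as_volume(matrix(0, 2, 2)), "rank 3")
  expect_error(as_volume(array(0, c(2, 2, 2)), -1), "positive")
})

test_that("slice sequences enforce interleaving and survive I/O", {
  sub <- fx_subject32()
  sq <- make_training_sequences(sub, 2, 5, seed = 1)[[1]]
  expect_identical(n_pairs(sq), 5L)
  expect_true(all(sq$slice_positions[sq$roles == "navigator"] ==
                    sq$navigator_position))
  f <- tempfile(fileext = ".nii.gz")
  write_sequence(sq, f)
  sq2 <- read_sequence(f)
  expect_equal(sq2$frames, sq$frames, tolerance = 1e-6)
  expect_identical(sq2$roles, sq$roles)
  expect_identical(sq2$navigator_position, sq$navigator_position)

  fr <- sq$frames
  expect_error(slice_sequence(fr, rev(sq$timestamps_s), sq$roles,
                              sq$slice_positions, sq$navigator_position),
               "increasing")
  expect_error(slice_sequence(fr, sq$timestamps_s, rev(sq$roles),
                              sq$slice_positions, sq$navigator_position),
               "alternate")
})
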