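test_that("breathing signal is seeded, cycle-annotated and bounded", {
  sig <- breathing_signal(85, seed = 3)
  expect_true(nrow(sig$cycles) >= 15 && nrow(sig$cycles) <= 26)
  expect_true(all(sig$amplitude >= 0 & sig$amplitude <= 1))
  # cycles tile the trace contiguously
  expect_equal(sig$cycles$start_s[-1],
               head(sig$cycles$start_s + sig$cycles$period_s, -1))
  sig2 <- breathing_signal(85, seed = 3)
  expect_identical(sig$amplitude, sig2$amplitude)
  expect_false(identical(sig$amplitude, breathing_signal(85, seed = 4)$amplitude))

  flat <- breathing_signal(20, pattern_config = list(
    list(type = "abdominal", period_s = c(4, 4), depth = c(0, 0))),
    seed = 1, drift = 0)
  expect_equal(max(flat$amplitude) - min(flat$amplitude), 0)
  expect_error(breathing_signal(10, pattern_config = list()), "empty")
  expect_error(breathing_signal(0), "duration")
})

test_that("synthetic subjects have plausible liver masks and seeded vessels", {
  sub <- fx_subject()
  frac <- mean(sub$mask)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.5)
  expect_true(sub$navigator_position >= sub$liver_lr_range[1])

  sub2 <- make_subject(seed = 3)
  expect_identical(sub$mask, sub2$mask)            # same ellipsoid
  expect_false(identical(sub$static$voxels, sub2$static$voxels))  # vessels moved

  expect_error(anatomy_params(vessel_count = 0), "vessel_count")
  expect_error(anatomy_params(noise_sigma = -1), "noise_sigma")
  expect_error(make_subject(anatomy_params(liver_extent_mm =
                                             c(SI = 500, AP = 60, LR = 60))),
               "extent")
})

test_that("ground-truth deformation is zero at rest, linear in amplitude", {
  sub <- fx_subject32()
  d0 <- deform_volume(sub, 0)
  expect_equal(d0$volume$voxels, sub$static$voxels)
  expect_equal(max(abs(d0$field$u_si)), 0)

  d5 <- deform_volume(sub, 0.5)
  d1 <- deform_volume(sub, 1.0)
  msk <- sub$mask
  m5 <- mean(sqrt(d5$field$u_ap[msk]^2 + d5$field$u_si[msk]^2))
  m1 <- mean(sqrt(d1$field$u_ap[msk]^2 + d1$field$u_si[msk]^2))
  expect_equal(m5, m1 / 2, tolerance = 1e-6)
  # zero outside the body
  expect_equal(max(abs(d1$field$u_si[!sub$body])), 0)
  # dominant component is SI (20% AP coupling)
  expect_equal(max(abs(d1$field$u_ap - 0.2 * d1$field$u_si)), 0)

  dc <- deform_volume(sub, 1, weight_mode = "constant")
  expect_equal(max(abs(dc$field$u_si[sub$mask] -
                         sub$params$max_si_mm)), 0)
  expect_error(deform_volume(sub, 1.2), "amplitude")
})

test_that("acquisition reproduces static slices without motion and noise", {
  p0 <- anatomy_params(noise_sigma = 0)
  sub <- make_subject(p0, seed = 2)
  sig <- breathing_signal(10, seed = 1)
  sig$amplitude[] <- 0
  pos <- sub$navigator_position + 4L
  pr <- acquire_pair(sub, sig, 1, pos)
  expect_equal(pr$navigator,
               mri4d:::dynamic_contrast(
                 sub$static$voxels[sub$navigator_position, , ], p0))
  expect_equal(pr$label,
               mri4d:::dynamic_contrast(sub$static$voxels[pos, , ], p0))
  expect_error(acquire_pair(sub, sig, 1, 1000), "position")
})

test_that("training sequences span 166 ms per slice with a fixed navigator", {
  sub <- fx_subject32()
  sqs <- make_training_sequences(sub, 3, 10, seed = 5)
  expect_length(sqs, 3)
  for (sq in sqs) {
    expect_equal(diff(sq$timestamps_s), rep(0.166, 19), tolerance = 1e-9)
    expect_identical(unique(sq$slice_positions[sq$roles == "navigator"]),
                     sub$navigator_position)
  }
  # a full-length sequence covers 175 pairs x 2 slices x 166 ms = 58.1 s
  dt <- acquisition_rate$ms_per_slice / 1000
  expect_equal(2 * 175 * dt, 58.1, tolerance = 1e-9)
  # data positions differ between sequences (right-to-left sampling)
  pos <- vapply(sqs, function(s) s$slice_positions[2], 1L)
  expect_identical(pos, sort(pos))
  expect_gt(length(unique(pos)), 1)
})

test_that("cohort generation is seeded and the shift knob is monotone", {
  co <- make_cohort(3, 2, shift_config = 1, seed = 5, grid = 32L)
  expect_length(co$source, 3)
  expect_length(co$target, 2)
  co2 <- make_cohort(3, 2, shift_config = 1, seed = 5, grid = 32L)
  expect_identical(co$target[[1]]$static$voxels, co2$target[[1]]$static$voxels)

  mean_noise <- function(subs)
    mean(vapply(subs, function(s) s$params$noise_sigma, 0))
  noise_at <- vapply(c(0, 1, 2), function(sh)
    mean_noise(make_cohort(2, 4, sh, seed = 5, grid = 32L)$target), 0)
  expect_true(all(diff(noise_at) > 0))
  src_noise <- mean_noise(make_cohort(2, 4, 1, seed = 5, grid = 32L)$source)
  expect_gt(noise_at[2], src_noise)
  expect_error(make_cohort(0, 1), "cohort")
})
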