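# Helpers to build a miniature source/target setting quickly.
mini_setting <- function() {
  memo("mini_setting", function() {
    cfg <- experiment_config("ci", n_source = 2L, n_target = 1L,
                             n_sequences = 3L, epochs = 3L)
    co <- mri4d:::exp_cohort(cfg, seed = 4)
    list(cfg = cfg, co = co, tc = mri4d:::exp_train_config(cfg, 4),
         arch = mri4d:::exp_arch(cfg))
  })
}

test_that("pre-training pools the per-subject budget and tags provenance", {
  ms <- mini_setting()
  mods <- pretrain(ms$co$source, j_minutes = 0.1, N = 2L, seeds = c(1, 2),
                   cfg = ms$tc, arch = ms$arch)
  expect_length(mods, 2)
  expect_identical(mods[[1]]$provenance$family, "pre")
  expect_identical(mods[[1]]$provenance$source_minutes, 0.1)
  expect_false(identical(mods[[1]]$weights, mods[[2]]$weights))
  # budget accounting: 0.1 min = 18 pairs per subject
  expect_identical(minutes_to_pairs(0.1), 18L)
  expect_error(pretrain(ms$co$source, j_minutes = 100, N = 1L, seeds = 1,
                        cfg = ms$tc, arch = ms$arch), "insufficient")
})

test_that("fine-tuning continues from base weights; zero epochs is identity", {
  ms <- mini_setting()
  base <- pretrain(ms$co$source, 0.1, N = 1L, seeds = 1, cfg = ms$tc,
                   arch = ms$arch)[[1]]
  cfg0 <- ms$tc; cfg0$epochs <- 0L
  same <- finetune(base, ms$co$target[[1]], 0.1, cfg0)
  expect_identical(same$weights, base$weights)
  expect_identical(same$provenance$family, "pre+TL")
  expect_identical(same$provenance$target_minutes, 0.1)

  ft <- finetune(base, ms$co$target[[1]], 0.1, ms$tc)
  expect_false(identical(ft$weights, base$weights))
  # fine-tuned validation loss on the target is no worse than the
  # base model evaluated there
  tsets <- mri4d:::target_sets(ms$co$target[[1]], 0.1)
  va <- mri4d:::samples_to_stacks(tsets$val, tsets$norms)
  base_loss <- mri4d:::mse_of(
    mri4d:::unet_forward(base$weights, va$x, base$arch)$out, va$y)
  expect_lte(ft$val_loss, base_loss)

  dr <- train_direct(ms$co$target[[1]], 0.1, ms$tc, ms$arch, seed = 3)
  expect_identical(dr$provenance$family, "direct")
  dr2 <- train_direct(ms$co$target[[1]], 0.1, ms$tc, ms$arch, seed = 3)
  expect_identical(dr$weights, dr2$weights)
})

test_that("ensemble mean averages de-normalized member predictions", {
  ms <- mini_setting()
  sub <- ms$co$target[[1]]$subject
  nrm <- mri4d:::subject_norm(sub, ms$co$target[[1]]$sequences)
  m1 <- build_unet(ms$arch, 1); m1$norms[[sub$subject_id]] <- nrm
  m2 <- build_unet(ms$arch, 2); m2$norms[[sub$subject_id]] <- nrm
  smp <- mri4d:::sequence_samples(sub, ms$co$target[[1]]$sequences, "first")[[1]]
  x <- assemble_input(smp, nrm)

  same <- ensemble_predict(ensemble(list(m1, m1)), x, sub$subject_id)
  expect_equal(same$mean, same$members[[1]])

  single <- ensemble_predict(ensemble(list(m1)), x, sub$subject_id)
  expect_equal(single$mean, single$members[[1]])

  both <- ensemble_predict(ensemble(list(m1, m2)), x, sub$subject_id)
  expect_equal(both$mean, (both$members[[1]] + both$members[[2]]) / 2)
  # permutation invariance
  swap <- ensemble_predict(ensemble(list(m2, m1)), x, sub$subject_id)
  expect_equal(both$mean, swap$mean)
  expect_error(ensemble(list()), "at least one")
})

test_that("checkpoints round-trip weights, provenance and history", {
  fit <- fx_tiny_fit()$model
  fit$provenance$family <- "direct"
  d <- file.path(tempdir(), "ckpt")
  save_model(fit, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(file.exists(file.path(d, "history.csv")))
  back <- load_model(d)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_identical(back$provenance$family, "direct")
  expect_equal(back$history$val_loss, fit$history$val_loss, tolerance = 1e-9)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  expect_equal(predict(back, x), predict(fit, x), tolerance = 1e-12)

  ed <- file.path(tempdir(), "ens_ckpt")
  save_ensemble(ensemble(list(fit, fit)), ed)
  eb <- load_ensemble(ed)
  expect_identical(eb$N, 2L)
  expect_equal(eb$members[[1]]$weights, fit$weights, tolerance = 1e-12)
})

test_that("series reconstruction maps one volume per navigator", {
  sub <- fx_subject32()
  arch <- arch_config(c(32, 32, 3), base_filters = 2)
  m <- build_unet(arch, 5)
  nrm <- zscore_normalize(sub$static$voxels, sub$subject_id)$params
  nav <- sub$static$voxels[sub$navigator_position, , ]
  vols <- reconstruct_series(m, list(nav, nav + 0.01), sub$static, nrm,
                             sub$navigator_position,
                             positions = c(10L, 11L, 12L))
  expect_length(vols, 2)
  expect_identical(dim(vols[[1]]$voxels), c(3L, 32L, 32L))
  expect_false(identical(vols[[1]]$voxels, vols[[2]]$voxels))
})

test_that("uncertainty map is the voxelwise coefficient of variation", {
  expect_equal(uncertainty_map(list(array(1, c(2, 2)),
                                    array(3, c(2, 2))))$values,
               array(0.5, c(2, 2)))  # sd 1 (population) / mean 2
  um0 <- uncertainty_map(list(array(2, c(3, 3)), array(2, c(3, 3))))
  expect_true(all(um0$values == 0))
  gg <- uncertainty_map(list(array(-1, c(1, 1)), array(1, c(1, 1))))
  expect_true(gg$flagged[1, 1])
  expect_identical(gg$values[1, 1], 0)
  expect_error(uncertainty_map(list(array(1, c(1, 1)))), "single member")

  # scale-free: uniform rescaling of all members leaves the map unchanged
  set.seed(8)
  mem <- lapply(1:4, function(i) array(runif(16, 1, 2), c(4, 4)))
  u1 <- uncertainty_map(mem)
  u2 <- uncertainty_map(lapply(mem, function(m) 7 * m))
  expect_equal(u1$values, u2$values, tolerance = 1e-12)
  expect_true(all(u1$values >= 0))
  # sample-sd variant
  us <- uncertainty_map(list(array(1, c(1, 1)), array(3, c(1, 1))),
                        sample_sd = TRUE)
  expect_equal(us$values[1, 1], sqrt(2) / 2)
})
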