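test_that("reference architecture counts 6.8 million trainable parameters", {
  a <- arch_config()
  expect_identical(count_parameters(a), 6776513)
  expect_equal(round(count_parameters(a) / 1e6, 1), 6.8)
  # count is independent of input spatial size (batch/shape invariance)
  expect_identical(count_parameters(arch_config(c(64, 64, 3))), 6776513)
  expect_error(arch_config(c(100, 100, 3)), "divisible")
  expect_error(arch_config(leaky_slope = 1.5), "leaky_slope")
})

test_that("the network maps (H, W, 3) to (H, W, 1) and is seed-reproducible", {
  a <- arch_config(c(16, 16, 3), base_filters = 2, dropout_rate = 0)
  m1 <- build_unet(a, seed = 11)
  m2 <- build_unet(a, seed = 11)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_unet(a, seed = 12)
  expect_false(identical(m1$weights, m3$weights))

  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- mri4d:::unet_forward(m1$weights, x, a)$out
  expect_identical(dim(out), c(16L, 16L, 1L, 2L))
})

test_that("analytic gradients match finite differences", {
  a <- arch_config(c(16, 16, 3), base_filters = 2, dropout_rate = 0)
  m <- build_unet(a, seed = 3)
  set.seed(4)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  fw <- mri4d:::unet_forward(m$weights, x, a, training = TRUE)
  dout <- 2 * (fw$out - y) / length(y)
  g <- mri4d:::unet_backward(m$weights, fw$cache, dout, a)
  eps <- 1e-5
  for (nm in c("e1a", "e3b", "u2", "v1", "out")) {
    for (t in c(1L, 3L)) {
      w1 <- m$weights; w1[[nm]]$w[t] <- w1[[nm]]$w[t] + eps
      w2 <- m$weights; w2[[nm]]$w[t] <- w2[[nm]]$w[t] - eps
      l1 <- mean((mri4d:::unet_forward(w1, x, a)$out - y)^2)
      l2 <- mean((mri4d:::unet_forward(w2, x, a)$out - y)^2)
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(num - g[[nm]]$w[t]) / max(abs(num), 1e-6), 5e-3)
    }
  }
})

test_that("input assembly keeps the semantic channel order", {
  sub <- fx_subject32()
  sq <- make_training_sequences(sub, 2, 4, seed = 1)
  smp <- mri4d:::sequence_samples(sub, sq, "first")[[1]]
  nrm <- zscore_normalize(list(sub$static$voxels, smp$navigator, smp$label),
                          sub$subject_id)$params
  st <- assemble_input(smp, nrm)
  expect_identical(dim(st), c(32L, 32L, 3L))
  expect_equal(st[, , 1], (smp$navigator - nrm$mean) / nrm$std)
  expect_equal(st[, , 2], (smp$static_at_nav - nrm$mean) / nrm$std)
  expect_equal(st[, , 3], (smp$static_at_target - nrm$mean) / nrm$std)
  # order is semantic: swapping channels 2/3 changes the stack
  expect_false(isTRUE(all.equal(st[, , 2], st[, , 3])))
  # stack statistics are near (0, 1) after whitening
  expect_lt(abs(mean(st)), 0.5)
  expect_lt(abs(sd(st) - 1), 0.5)
  bad <- smp; bad$static_at_nav <- matrix(0, 8, 8)
  expect_error(training_sample(bad$navigator, bad$static_at_nav,
                               bad$static_at_target, bad$label, 1L, "s"),
               "shape")
})

test_that("augmentation applies one joint transform to all four images", {
  sub <- fx_subject32()
  sq <- make_training_sequences(sub, 2, 4, seed = 1)
  smp <- mri4d:::sequence_samples(sub, sq, "first")[[1]]
  set.seed(7); a1 <- augment(smp)
  set.seed(7); a2 <- augment(smp)
  expect_identical(a1, a2)
  expect_identical(dim(a1$navigator), dim(smp$navigator))

  a0 <- augment(smp, list(translate_vox = 0, rotate_deg = 0, intensity = 0))
  expect_equal(a0$navigator, smp$navigator)
  expect_equal(a0$label, smp$label)

  # pure translation by (2, 0) voxels shifts navigator and label equally
  nav_s <- mri4d:::.warp_rigid(smp$navigator, 0, 2, 0)
  lab_s <- mri4d:::.warp_rigid(smp$label, 0, 2, 0)
  expect_equal(nav_s[12, 10], smp$navigator[10, 10], tolerance = 1e-9)
  expect_equal(lab_s[12, 10], smp$label[10, 10], tolerance = 1e-9)
})

test_that("training minimizes validation loss and checkpoints the best epoch", {
  fit <- fx_tiny_fit()$model
  h <- fit$history
  expect_identical(nrow(h), 15L)
  expect_lt(fit$val_loss, h$val_loss[1])
  expect_equal(fit$val_loss, min(h$val_loss))
  expect_error(train(build_unet(fx_tiny_fit()$arch, 1), list(), list(),
                     fx_tiny_fit()$cfg, list()), "nonempty")
})

test_that("training is bit-for-bit reproducible from config and seed", {
  fx <- fx_tiny_fit()
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 21,
                      learning_rate = 1e-3)
  f1 <- train(build_unet(fx$arch, 2), fx$samples[1:8], fx$samples[9:10],
              cfg, list(sub = fx$norm))
  f2 <- train(build_unet(fx$arch, 2), fx$samples[1:8], fx$samples[9:10],
              cfg, list(sub = fx$norm))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("volume reconstruction is equivalent batched and slice-by-slice", {
  sub <- fx_subject32()
  arch <- arch_config(c(32, 32, 3), base_filters = 2)
  m <- build_unet(arch, 5)
  nrm <- zscore_normalize(sub$static$voxels, sub$subject_id)$params
  nav <- sub$static$voxels[sub$navigator_position, , ]
  v1 <- reconstruct_volume(m, nav, sub$static, nrm, sub$navigator_position)
  v2 <- reconstruct_volume(m, nav, sub$static, nrm, sub$navigator_position,
                           batch_size = 1L)
  expect_identical(dim(v1$voxels)[1], dim(sub$static$voxels)[1])
  expect_lt(max(abs(v1$voxels - v2$voxels)), 1e-5)
  expect_error(reconstruct_volume(m, matrix(0, 8, 8), sub$static, nrm, 1L),
               "shape")
})
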