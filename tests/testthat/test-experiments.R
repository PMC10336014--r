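test_that("Cohen's d uses the (n-1)-weighted pooled standard deviation", {
  # means 4 and 3, per-group variance 4, pooled sd 2 -> d = 1/2
  expect_equal(cohens_d(c(2, 4, 6), c(1, 3, 5)), 0.5)
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "pooled variance")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
  # brute-force cross-check on random 10-element groups
  set.seed(2)
  for (r in 1:5) {
    a <- rnorm(10); b <- rnorm(7, 1)
    sp <- sqrt((9 * var(a) + 6 * var(b)) / 15)
    expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  }
})

test_that("distribution comparison reports rank-sum, normality and effect size", {
  set.seed(3)
  x <- rnorm(100)
  same <- compare_distributions(x, x)
  expect_gt(same$p_value, 0.9)
  shifted <- compare_distributions(rnorm(100), rnorm(100, 3))
  expect_lt(shifted$p_value, 1e-3)
  expect_lt(shifted$effect_size_d, -1)  # x below y
  expect_false(is.null(shifted$normality_x$shapiro_p))
  expect_false(is.null(shifted$normality_y$ks_p))
  tiny <- compare_distributions(c(1, 2), c(3, 4))
  expect_true(tiny$normality_x$skipped)
  expect_error(compare_distributions(numeric(), 1:3), "nonempty")
})

test_that("experiment harness runs are reproducible bit-for-bit", {
  cfg <- fx_micro_cfg()
  a <- run_domain_shift(cfg, seed = 7)
  b <- run_domain_shift(cfg, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$stats$mdisp$p_value, b$stats$mdisp$p_value)
  expect_identical(a$stats$dn_rmse$effect_size_d, b$stats$dn_rmse$effect_size_d)
  # different seed gives different draws
  c_ <- run_domain_shift(cfg, seed = 8)
  expect_false(identical(a$samples$mdisp, c_$samples$mdisp))
  # selection rule: test samples drawn from the first 10 s of the second half
  dt <- 2 * acquisition_rate$ms_per_slice / 1000
  expect_identical(floor(cfg$test_window_s / dt), 30)
})

test_that("tl-vs-direct table is keyed by budget and model family", {
  cfg <- experiment_config("ci", n_source = 2L, n_target = 1L,
                           n_sequences = 3L, epochs = 2L,
                           i_minutes = c(0.1, 0.2), j_minutes = 0.1,
                           val_max = 12L)
  res <- run_tl_vs_direct(cfg, seed = 5)
  expect_setequal(unique(res$samples$family), c("pre+TL", "direct"))
  expect_setequal(unique(res$samples$minutes), c(0.1, 0.2))
  expect_identical(nrow(res$table), 4L)
  expect_true(all(c("rmse_mean", "rmse_p95") %in% names(res$table)))
})

test_that("ensemble-size experiment reports ANOVA, Tukey and pairwise d", {
  cfg <- experiment_config("ci", n_source = 2L, n_target = 1L,
                           n_sequences = 3L, epochs = 2L,
                           ensemble_sizes = c(1L, 2L),
                           ensemble_j_minutes = 0.1,
                           ensemble_i_minutes = 0.1, val_max = 12L)
  res <- run_ensemble_sizes(cfg, seed = 5)
  expect_identical(sort(unique(res$samples$N)), c(1L, 2L))
  expect_false(is.null(res$tukey))
  expect_identical(dim(res$pairwise_d), c(2L, 2L))
  expect_identical(res$pairwise_d[1, 1], 0)
  # N = 1 row equals the TL-only evaluation of the first member
  m1 <- res$members[[1]]
  one <- res$samples[res$samples$N == 1, ]
  expect_identical(nrow(one), 12L)
  # permutation of members leaves the reported N = max mean unchanged
  pm <- res$member_preds
  full_fwd <- Reduce(`+`, pm) / length(pm)
  full_rev <- Reduce(`+`, rev(pm)) / length(pm)
  expect_equal(full_fwd, full_rev, tolerance = 1e-12)
})
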