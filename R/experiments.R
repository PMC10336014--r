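# Seeded experiment harness: domain shift, transfer learning versus
# direct training, ensemble sizes -- plus the statistical machinery
# (Cohen's d, rank-sum comparisons with normality checks, ANOVA/Tukey).

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' weighted by `n - 1` per group.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return signed effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs >= 2 values")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled variance: effect size undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Compare two metric distributions
#'
#' Runs a Shapiro-Wilk and a Kolmogorov-Smirnov normality check on
#' each group (skipped and flagged for n < 3), then a two-sided
#' Wilcoxon rank-sum test, and reports Cohen's d.
#'
#' @param x,y numeric vectors (nonempty).
#' @param label optional comparison label.
#' @return object of class `mri4d_stat`: test name, statistic,
#'   p-value, effect size, sample sizes and normality outcomes.
#' @export
compare_distributions <- function(x, y, label = "x vs y") {
  if (!length(x) || !length(y)) stop("groups must be nonempty")
  norm_check <- function(v) {
    if (length(v) < 3)
      return(list(shapiro_p = NA_real_, ks_p = NA_real_, skipped = TRUE))
    sv <- if (length(v) > 5000) v[round(seq(1, length(v), length.out = 5000))] else v
    sh <- tryCatch(shapiro.test(sv)$p.value, error = function(e) NA_real_)
    ks <- suppressWarnings(
      tryCatch(ks.test(v, "pnorm", mean(v), sd(v))$p.value,
               error = function(e) NA_real_))
    list(shapiro_p = sh, ks_p = ks, skipped = FALSE)
  }
  nx <- norm_check(x); ny <- norm_check(y)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
  structure(list(label = label, test = "Wilcoxon rank sum",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 effect_size_d = d, n = c(length(x), length(y)),
                 normality_x = nx, normality_y = ny,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "mri4d_stat")
}

#' @export
print.mri4d_stat <- function(x, ...) {
  cat(sprintf("<mri4d_stat> %s: W = %.1f, p = %.3g, d = %.3f (n = %d, m = %d)\n",
              x$label, x$statistic, x$p_value, x$effect_size_d, x$n[1], x$n[2]))
  cat(sprintf("  means %.4f vs %.4f; Shapiro p: %.3g / %.3g\n", x$mean_x,
              x$mean_y, x$normality_x$shapiro_p, x$normality_y$shapiro_p))
  invisible(x)
}

#' Experiment configuration presets
#'
#' `ci` is the desk-scale preset every automated run uses: 32^3 phantom
#' subjects (32 x 32 slices), a 4 + 2 cohort, a narrow network
#' (base_filters 2), 10 epochs, and data budgets that are scaled-down
#' "minute equivalents" (0.25 and 0.5 min, i.e. 45 / 90 pairs).
#' `paper` mirrors the full-scale study design (128 x 128 slices,
#' 16 + 4 cohort, reference architecture and recipe, budgets in real
#' minutes); it is provided for completeness and is GPU-scale.
#'
#' @param preset `"ci"` or `"paper"`.
#' @param ... named overrides of individual fields.
#' @return list of class `mri4d_exp_config`.
#' @export
experiment_config <- function(preset = c("ci", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "ci") {
    list(grid = 32L, spacing = 1.8, n_source = 4L, n_target = 2L,
         n_sequences = 8L, pairs_per_sequence = 60L,
         base_filters = 2L, epochs = 10L, batch_size = 32L,
         learning_rate = 4e-4, dropout_rate = 0.1,
         j_minutes = 0.5, i_minutes = c(0.25, 0.5),
         ensemble_sizes = c(1L, 2L, 5L), ensemble_j_minutes = 0.25,
         ensemble_i_minutes = 0.25,
         shift = 1, eval_pairs_per_seq = 6L, val_max = 64L,
         mdisp_spacing_vox = 2L,
         test_window_s = 10, test_fraction = 0.5)
  } else {
    list(grid = 128L, spacing = 1.8, n_source = 16L, n_target = 4L,
         n_sequences = 38L, pairs_per_sequence = 175L,
         base_filters = 32L, epochs = 200L, batch_size = 64L,
         learning_rate = 4e-4, dropout_rate = 0.5,
         j_minutes = 2, i_minutes = c(1, 2, 5, 12, 24, 47),
         ensemble_sizes = c(1L, 2L, 5L, 10L), ensemble_j_minutes = 2,
         ensemble_i_minutes = 2,
         shift = 1, eval_pairs_per_seq = Inf, val_max = Inf,
         mdisp_spacing_vox = 8L,
         test_window_s = 10, test_fraction = 0.5)
  }
  cfg$preset <- preset
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "mri4d_exp_config")
}

exp_arch <- function(cfg)
  arch_config(c(cfg$grid, cfg$grid, 3L), base_filters = cfg$base_filters,
              dropout_rate = cfg$dropout_rate)

exp_train_config <- function(cfg, seed)
  train_config(learning_rate = cfg$learning_rate, epochs = cfg$epochs,
               batch_size = cfg$batch_size,
               augment_ranges = list(translate_vox = 2, rotate_deg = 3,
                                     intensity = 0.1),
               seed = seed)

# Materialize a cohort with per-subject sequences.
exp_cohort <- function(cfg, seed, shift = cfg$shift) {
  ch <- make_cohort(cfg$n_source, cfg$n_target, shift_config = shift,
                    seed = seed, grid = cfg$grid, spacing = cfg$spacing)
  wrap <- function(sub, k)
    list(subject = sub,
         sequences = make_training_sequences(sub, cfg$n_sequences,
                                             cfg$pairs_per_sequence,
                                             seed = seed + 131L * k))
  list(source = lapply(seq_along(ch$source), function(k) wrap(ch$source[[k]], k)),
       target = lapply(seq_along(ch$target), function(k)
         wrap(ch$target[[k]], 1000L + k)))
}

cap_val <- function(samples, val_max) {
  if (length(samples) <= val_max) return(samples)
  samples[round(seq(1, length(samples), length.out = val_max))]
}

# Test samples per the study's selection rule: a seeded random 50% of
# the pairs in the first `window_s` seconds of the second half of each
# training sequence, optionally capped.
test_samples <- function(el, cfg, seed) {
  sub <- el$subject
  out <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dt <- acquisition_rate$ms_per_slice / 1000
  win_pairs <- floor(cfg$test_window_s / (2 * dt))
  for (sq in el$sequences) {
    smp <- sequence_samples(sub, list(sq), "second", win_pairs)
    take <- sort(sample.int(length(smp), round(cfg$test_fraction * length(smp))))
    take <- head(take, cfg$eval_pairs_per_seq)
    out <- c(out, smp[take])
  }
  out
}

# Predict one sample and return (pred, label) on the original scale.
predict_sample <- function(model, sample) {
  nm <- model$norms[[sample$subject_id]]
  if (is.null(nm)) stop("model lacks normalization for ", sample$subject_id)
  p <- predict(model, assemble_input(sample, nm))
  list(pred = denormalize(p[, , 1, 1], nm), label = sample$label)
}

# Per-sample metric rows for a model on a set of samples.
eval_samples <- function(model, el, samples, measures = c("rmse"),
                         params = reg_params(), spacing = NULL,
                         mdisp_spacing_vox = 8L) {
  sub <- el$subject
  if (is.null(spacing)) spacing <- sub$static$spacing[2:3]
  rows <- lapply(samples, function(sm) {
    pl <- predict_sample(model, sm)
    row <- data.frame(subject = sub$subject_id,
                      position = sm$target_position,
                      rmse = rmse(pl$pred, pl$label))
    if (any(c("mdisp", "dn_rmse") %in% measures)) {
      fld <- register_bspline(pl$pred, pl$label, params, spacing)
      msk <- sub$mask[sm$target_position, , ]
      row$mdisp <- mdisp(fld, msk, spacing_vox = mdisp_spacing_vox)
      row$dn_rmse <- dn_rmse(pl$pred, pl$label, params, spacing, field = fld)
    }
    row
  })
  do.call(rbind, rows)
}

#' Domain-shift experiment
#'
#' Pre-trains one pooled-source model, evaluates MDISP and DN_RMSE on
#' source validation samples versus target-domain test samples (both
#' drawn by the seeded selection rule), and tests the distribution
#' shift with the rank-sum machinery.
#'
#' @param cfg an [experiment_config()].
#' @param seed integer master seed.
#' @return object of class `mri4d_domain_shift`: per-sample metric
#'   table (`samples` with a `domain` column, the violin-plot data),
#'   `stats` (one `mri4d_stat` per measure), and the trained model.
#' @export
run_domain_shift <- function(cfg = experiment_config(), seed = 1L) {
  co <- exp_cohort(cfg, seed)
  tc <- exp_train_config(cfg, seed)
  model <- pretrain(co$source, cfg$j_minutes, N = 1L, seeds = seed,
                    cfg = tc, arch = exp_arch(cfg))[[1]]
  # target subjects are unseen: attach their normalization for inference
  for (el in co$target)
    model$norms[[el$subject$subject_id]] <- subject_norm(el$subject,
                                                         el$sequences)
  meas <- c("rmse", "mdisp", "dn_rmse")
  rows <- list()
  for (k in seq_along(co$source)) {
    sm <- test_samples(co$source[[k]], cfg, seed + 17L * k)
    df <- eval_samples(model, co$source[[k]], sm, meas,
                       mdisp_spacing_vox = cfg$mdisp_spacing_vox)
    df$domain <- "S"
    rows[[length(rows) + 1L]] <- df
  }
  for (k in seq_along(co$target)) {
    sm <- test_samples(co$target[[k]], cfg, seed + 1700L + 17L * k)
    df <- eval_samples(model, co$target[[k]], sm, meas,
                       mdisp_spacing_vox = cfg$mdisp_spacing_vox)
    df$domain <- "T"
    rows[[length(rows) + 1L]] <- df
  }
  samples <- do.call(rbind, rows)
  stats_out <- lapply(c("mdisp", "dn_rmse"), function(m) {
    compare_distributions(samples[[m]][samples$domain == "T"],
                          samples[[m]][samples$domain == "S"],
                          label = sprintf("%s: T vs S", m))
  })
  names(stats_out) <- c("mdisp", "dn_rmse")
  structure(list(samples = samples, stats = stats_out, model = model,
                 cfg = cfg, seed = seed),
            class = "mri4d_domain_shift")
}

#' @export
print.mri4d_domain_shift <- function(x, ...) {
  cat("<domain shift experiment>\n")
  for (m in names(x$stats)) print(x$stats[[m]])
  invisible(x)
}

#' Transfer learning versus direct training
#'
#' For each target-data budget `i` and each target subject, trains one
#' model directly from scratch and fine-tunes one from the shared
#' pooled-source base model, then evaluates both on the subject's
#' validation samples.
#'
#' @param cfg an [experiment_config()].
#' @param seed integer master seed.
#' @param measures metrics per sample (`"rmse"` is cheap; adding
#'   `"mdisp"`/`"dn_rmse"` runs a registration per sample).
#' @return object of class `mri4d_tl_direct`: `samples` (per-sample
#'   metrics keyed by budget and family), `table` (mean and 95th
#'   percentile per budget x family), base model provenance.
#' @export
run_tl_vs_direct <- function(cfg = experiment_config(), seed = 1L,
                             measures = "rmse") {
  co <- exp_cohort(cfg, seed)
  tc <- exp_train_config(cfg, seed)
  base <- pretrain(co$source, cfg$j_minutes, N = 1L, seeds = seed,
                   cfg = tc, arch = exp_arch(cfg))[[1]]
  rows <- list()
  for (i_min in cfg$i_minutes) {
    for (t in seq_along(co$target)) {
      el <- co$target[[t]]
      val <- cap_val(sequence_samples(el$subject, el$sequences, "second"),
                     cfg$val_max)
      tc_t <- exp_train_config(cfg, seed + 29L * t + round(1e4 * i_min))
      ft <- finetune(base, el, i_min, tc_t)
      dr <- train_direct(el, i_min, tc_t, exp_arch(cfg),
                         seed = seed + 7L * t + round(1e5 * i_min))
      for (fit in list(ft, dr)) {
        df <- eval_samples(fit, el, val, measures,
                           mdisp_spacing_vox = cfg$mdisp_spacing_vox)
        df$minutes <- i_min
        df$family <- fit$provenance$family
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  samples <- do.call(rbind, rows)
  tab <- summarize_metrics_cols(samples, c("minutes", "family"), measures)
  structure(list(samples = samples, table = tab, cfg = cfg, seed = seed,
                 base_minutes = cfg$j_minutes),
            class = "mri4d_tl_direct")
}

summarize_metrics_cols <- function(samples, keys, measures) {
  key <- interaction(samples[keys], drop = TRUE)
  out <- lapply(levels(key), function(lv) {
    sub <- samples[key == lv, , drop = FALSE]
    row <- sub[1, keys, drop = FALSE]
    row$n <- nrow(sub)
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_p95")]] <- unname(quantile(sub[[m]], 0.95, type = 7))
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.mri4d_tl_direct <- function(x, ...) {
  cat("<TL vs direct experiment>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Ensemble-size experiment
#'
#' Pre-trains `max(sizes)` members from distinct random
#' initializations, fine-tunes each to the first target subject, and
#' evaluates the ensemble-mean prediction at each size `N` (the first
#' `N` members; `N = 1` is the transfer-learning-only case).  Reports
#' the per-size table, a one-factor ANOVA over `N`, pairwise Tukey
#' HSD, and pairwise Cohen's d.
#'
#' @param cfg an [experiment_config()].
#' @param seed integer master seed.
#' @return object of class `mri4d_ensemble_sizes`.
#' @export
run_ensemble_sizes <- function(cfg = experiment_config(), seed = 1L) {
  co <- exp_cohort(cfg, seed)
  tc <- exp_train_config(cfg, seed)
  n_max <- max(cfg$ensemble_sizes)
  members <- pretrain(co$source, cfg$ensemble_j_minutes, N = n_max,
                      seeds = seed * 100L + seq_len(n_max),
                      cfg = tc, arch = exp_arch(cfg))
  el <- co$target[[1]]
  tuned <- lapply(members, function(m)
    finetune(m, el, cfg$ensemble_i_minutes, tc))
  val <- cap_val(sequence_samples(el$subject, el$sequences, "second"),
                 cfg$val_max)
  sid <- el$subject$subject_id
  # member predictions once; ensemble means are running averages
  stacks <- samples_to_stacks(val, stats::setNames(
    list(subject_norm(el$subject, el$sequences)), sid))
  member_preds <- lapply(tuned, function(m)
    denormalize(predict(m, stacks$x), m$norms[[sid]]))
  labels <- lapply(val, `[[`, "label")
  rows <- list()
  for (N in cfg$ensemble_sizes) {
    mp <- Reduce(`+`, member_preds[seq_len(N)]) / N
    for (v in seq_along(val))
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, sample = v, rmse = rmse(mp[, , 1, v], labels[[v]]))
  }
  samples <- do.call(rbind, rows)
  tab <- summarize_metrics_cols(samples, "N", "rmse")
  an <- aov(rmse ~ factor(N), data = samples)
  tukey <- TukeyHSD(an)
  sizes <- cfg$ensemble_sizes
  dmat <- outer(seq_along(sizes), seq_along(sizes), Vectorize(function(a, b) {
    if (a == b) return(0)
    cohens_d(samples$rmse[samples$N == sizes[a]],
             samples$rmse[samples$N == sizes[b]])
  }))
  dimnames(dmat) <- list(paste0("N", sizes), paste0("N", sizes))
  structure(list(samples = samples, table = tab, anova = summary(an),
                 tukey = tukey, pairwise_d = dmat, members = tuned,
                 member_preds = member_preds,
                 cfg = cfg, seed = seed),
            class = "mri4d_ensemble_sizes")
}

#' @export
print.mri4d_ensemble_sizes <- function(x, ...) {
  cat("<ensemble size experiment>\n")
  print(x$table, row.names = FALSE)
  cat("ANOVA main effect of N:\n")
  print(x$anova)
  invisible(x)
}
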