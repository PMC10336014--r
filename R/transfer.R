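# Pre-training on source cohorts, fine-tuning to target subjects,
# direct-training baselines, ensemble averaging and
# coefficient-of-variation uncertainty maps.

# Pooled per-subject normalization: static volume plus all dynamic
# frames of the supplied sequences.
subject_norm <- function(subject, sequences) {
  pool <- c(list(subject$static$voxels), unlist(lapply(sequences, `[[`, "frames"),
                                                recursive = FALSE))
  zscore_normalize(pool, subject$subject_id)$params
}

#' Pre-train an ensemble of models on the source cohort
#'
#' Trains `N` independently initialized models on the pooled source
#' samples: `minutes_to_pairs(j_minutes)` pairs per subject, drawn
#' contiguously from the starts of the training halves of each
#' subject's sequences.
#'
#' @param source_subjects list of phantom subjects with attached
#'   `sequences` (see [make_training_sequences()]); each element is a
#'   list with `subject` and `sequences`.
#' @param j_minutes per-subject source data budget in minutes.
#' @param N ensemble size (number of random initializations).
#' @param seeds integer vector of length `N`.
#' @param cfg a [train_config()].
#' @param arch an [arch_config()] matching the phantom slice shape.
#' @return list of `N` trained models, provenance family `"pre"`.
#' @export
pretrain <- function(source_subjects, j_minutes, N = 1L, seeds = seq_len(N),
                     cfg = train_config(), arch = arch_config()) {
  stopifnot(length(seeds) == N)
  pairs <- minutes_to_pairs(j_minutes)
  train_s <- list(); val_s <- list(); norms <- list()
  for (el in source_subjects) {
    sub <- el$subject; sqs <- el$sequences
    train_s <- c(train_s, budget_samples(sub, sqs, pairs))
    val_s <- c(val_s, sequence_samples(sub, sqs, "second"))
    norms[[sub$subject_id]] <- subject_norm(sub, sqs)
  }
  lapply(seq_len(N), function(m) {
    model <- build_unet(arch, seed = seeds[m])
    cfg_m <- cfg; cfg_m$seed <- as.integer(cfg$seed + 1000L * seeds[m])
    fit <- train(model, train_s, val_s, cfg_m, norms)
    fit$provenance$family <- "pre"
    fit$provenance$source_minutes <- j_minutes
    fit$provenance$seed <- as.integer(seeds[m])
    fit
  })
}

target_sets <- function(target, i_minutes) {
  pairs <- minutes_to_pairs(i_minutes)
  sub <- target$subject; sqs <- target$sequences
  list(train = budget_samples(sub, sqs, pairs),
       val = sequence_samples(sub, sqs, "second"),
       norms = stats::setNames(list(subject_norm(sub, sqs)), sub$subject_id))
}

#' Fine-tune a pre-trained model to a target subject
#'
#' Continues optimization from the base model's weights on target
#' samples only, with the same training recipe that produced the base
#' model (epochs, loss, batch size, augmentation).  The target
#' subject's own normalization parameters are computed and used.
#'
#' @param base a trained model (family `"pre"`).
#' @param target a list with `subject` and `sequences`.
#' @param i_minutes target data budget in minutes.
#' @param cfg a [train_config()]; defaults to the base model's.
#' @return fine-tuned model, provenance family `"pre+TL"`.
#' @export
finetune <- function(base, target, i_minutes, cfg = NULL) {
  stopifnot(inherits(base, "mri4d_model"))
  if (is.null(base$history)) stop("base model is untrained")
  if (is.null(cfg)) cfg <- base$train_config
  ts <- target_sets(target, i_minutes)
  d <- dim(ts$train[[1]]$navigator)
  if (!all(d == base$arch$in_shape[1:2]))
    stop("target slice shape does not match base architecture")
  if (cfg$epochs == 0) {
    out <- base
  } else {
    out <- train(base, ts$train, ts$val, cfg, ts$norms)
  }
  out$provenance$family <- "pre+TL"
  out$provenance$target_minutes <- i_minutes
  out
}

#' Train a model from scratch on a target subject
#'
#' The direct-learning baseline: identical data budget and recipe as
#' [finetune()], but starting from a random initialization.
#'
#' @param target a list with `subject` and `sequences`.
#' @param i_minutes target data budget in minutes.
#' @param cfg a [train_config()].
#' @param arch an [arch_config()].
#' @param seed initialization seed.
#' @return trained model, provenance family `"direct"`.
#' @export
train_direct <- function(target, i_minutes, cfg = train_config(),
                         arch = arch_config(), seed = 1L) {
  ts <- target_sets(target, i_minutes)
  model <- build_unet(arch, seed = seed)
  fit <- train(model, ts$train, ts$val, cfg, ts$norms)
  fit$provenance$family <- "direct"
  fit$provenance$target_minutes <- i_minutes
  fit$provenance$seed <- as.integer(seed)
  fit
}

#' Build an ensemble from fine-tuned members
#'
#' @param members nonempty list of trained models sharing one
#'   architecture and target subject.
#' @return object of class `mri4d_ensemble`.
#' @export
ensemble <- function(members) {
  if (length(members) < 1) stop("ensemble must have at least one member")
  b0 <- members[[1]]$arch$base_filters
  if (any(vapply(members, function(m) m$arch$base_filters, 0) != b0))
    stop("ensemble members must share the architecture")
  structure(list(members = members, N = length(members)),
            class = "mri4d_ensemble")
}

#' @export
print.mri4d_ensemble <- function(x, ...) {
  cat(sprintf("<mri4d_ensemble> N = %d members (%s)\n", x$N,
              paste(unique(vapply(x$members, function(m) m$provenance$family, "")),
                    collapse = ", ")))
  invisible(x)
}

#' Ensemble prediction
#'
#' Each member predicts, its output is de-normalized with the member's
#' subject parameters, and the de-normalized predictions are averaged
#' voxelwise.  Member outputs are retained for the uncertainty map.
#'
#' @param ens an [ensemble()].
#' @param x input stack (H, W, 3) or batch (H, W, 3, N).
#' @param subject_id subject whose normalization to reverse.
#' @return list with `mean` (array) and `members` (list of arrays),
#'   all on the original intensity scale.
#' @export
ensemble_predict <- function(ens, x, subject_id) {
  stopifnot(inherits(ens, "mri4d_ensemble"))
  preds <- lapply(ens$members, function(m) {
    nm <- m$norms[[subject_id]]
    if (is.null(nm)) stop("member lacks normalization for ", subject_id)
    denormalize(predict(m, x), nm)
  })
  mean_pred <- Reduce(`+`, preds) / length(preds)
  list(mean = mean_pred, members = preds)
}

#' Voxelwise coefficient-of-variation uncertainty map
#'
#' Computes, per voxel, the standard deviation across the de-normalized
#' member predictions divided by their mean (population formula by
#' default).  Voxels whose absolute mean falls below `eps` times the
#' intensity range are set to zero and flagged.
#'
#' @param member_preds list of >= 2 arrays (de-normalized predictions).
#' @param eps relative guard threshold for near-zero means.
#' @param sample_sd use the n-1 (sample) formula instead of population.
#' @return object of class `mri4d_uncertainty`: `values` (CoV array),
#'   `mean` (companion mean prediction), `flagged` (logical array).
#' @export
uncertainty_map <- function(member_preds, eps = 1e-6, sample_sd = FALSE) {
  if (length(member_preds) < 2)
    stop("CoV undefined for a single member")
  n <- length(member_preds)
  mu <- Reduce(`+`, member_preds) / n
  ssq <- Reduce(`+`, lapply(member_preds, function(p) (p - mu)^2))
  sdv <- sqrt(ssq / if (sample_sd) (n - 1) else n)
  rng <- max(abs(range(unlist(lapply(member_preds, range)))))
  guard <- abs(mu) < eps * max(rng, .Machine$double.eps)
  cov <- array(0, dim(mu))
  cov[!guard] <- sdv[!guard] / abs(mu[!guard])
  structure(list(values = cov, mean = mu, flagged = guard),
            class = "mri4d_uncertainty")
}

#' @export
print.mri4d_uncertainty <- function(x, ...) {
  cat(sprintf("<mri4d_uncertainty> CoV in [%.4g, %.4g], %d voxels guarded\n",
              min(x$values), max(x$values), sum(x$flagged)))
  invisible(x)
}
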