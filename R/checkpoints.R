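# Run-directory checkpoints: weights plus a JSON manifest carrying
# provenance (family, budgets, seed), the architecture, and the
# training log as CSV.  Ensembles are directories of member
# checkpoints with their own manifest.

#' Save a model checkpoint
#'
#' Writes `weights.rds`, `manifest.json` (provenance, architecture,
#' config hash, seed) and, when present, `history.csv` into `dir`.
#'
#' @param model a trained `mri4d_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "mri4d_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(weights = model$weights, norms = model$norms,
               val_loss = model$val_loss), file.path(dir, "weights.rds"))
  arch <- model$arch
  manifest <- list(
    package = "mri4d",
    provenance = model$provenance,
    arch = list(in_shape = arch$in_shape, base_filters = arch$base_filters,
                leaky_slope = arch$leaky_slope,
                dropout_rate = arch$dropout_rate),
    weight_checksum = sum(vapply(model$weights,
                                 function(l) sum(l$w^2) + sum(l$b^2), 0)),
    val_loss = model$val_loss)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [save_model()].
#' @return the restored `mri4d_model`.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  blob <- readRDS(file.path(dir, "weights.rds"))
  arch <- arch_config(manifest$arch$in_shape,
                      base_filters = manifest$arch$base_filters,
                      leaky_slope = manifest$arch$leaky_slope,
                      dropout_rate = manifest$arch$dropout_rate)
  model <- build_unet(arch, seed = manifest$provenance$seed %||% 1L)
  model$weights <- blob$weights
  model$norms <- blob$norms
  model$val_loss <- blob$val_loss
  model$provenance <- manifest$provenance
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) model$history <- utils::read.csv(hist_path)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load an ensemble as a directory of member checkpoints
#'
#' @param ens an [ensemble()].
#' @param dir target directory; members go into `member_01`, ... and a
#'   top-level `manifest.json` records the size.
#' @return `dir` (save) or the restored `mri4d_ensemble` (load).
#' @export
save_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "mri4d_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(ens$N))
    save_model(ens$members[[k]], file.path(dir, sprintf("member_%02d", k)))
  jsonlite::write_json(list(N = ens$N), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ensemble(lapply(seq_len(manifest$N), function(k)
    load_model(file.path(dir, sprintf("member_%02d", k)))))
}
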