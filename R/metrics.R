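# Image-similarity evaluation stack: RMSE, MDISP via 2-D B-spline
# deformable registration, the deformation-normalized DN_RMSE, and
# set-level reports.

#' Root mean squared error of two images
#'
#' `sqrt(mean((pred - label)^2))` over all `W x H` pixels.
#'
#' @param pred,label 2D arrays of identical shape.
#' @return non-negative scalar.
#' @export
rmse <- function(pred, label) {
  if (!all(dim(pred) == dim(label))) stop("shape mismatch")
  sqrt(mean((pred - label)^2))
}

#' Deformable-registration parameters
#'
#' Defaults reproduce the reference parameterization: ANTs-style local
#' neighborhood correlation (radius 2) as similarity; a two-level
#' pyramid (level 1: Gaussian sigma 0.25 then half resolution with
#' linear interpolation; level 2: full resolution, no smoothing); a
#' 4x4 B-spline deformation mesh doubled to 8x8; gradient descent with
#' learning-rate estimation, 20 iterations per level, convergence
#' minimum 1e-7 over a window of 10, and a maximum step of 0.25
#' physical units.  Any override is recorded in downstream reports.
#'
#' @param radius neighborhood-correlation radius in pixels.
#' @param mesh level-1 mesh size (doubled at level 2).
#' @param iterations gradient-descent iterations per level.
#' @param smoothing_sigma level-1 Gaussian sigma (pixels).
#' @param max_step_phys maximum per-iteration step, physical units (mm).
#' @param convergence_min,convergence_window plateau stopping rule.
#' @return list of class `mri4d_reg_params`.
#' @export
reg_params <- function(radius = 2L, mesh = 4L, iterations = 20L,
                       smoothing_sigma = 0.25, max_step_phys = 0.25,
                       convergence_min = 1e-7, convergence_window = 10L) {
  structure(list(similarity = "ANTS-neighborhood-correlation",
                 radius = as.integer(radius), mesh = as.integer(mesh),
                 iterations = as.integer(iterations),
                 smoothing_sigma = smoothing_sigma,
                 max_step_phys = max_step_phys,
                 convergence_min = convergence_min,
                 convergence_window = as.integer(convergence_window)),
            class = "mri4d_reg_params")
}

#' B-spline deformable registration of prediction to label
#'
#' Estimates a dense 2-D displacement field `u` such that
#' `pred(x + u(x)) ~ label(x)` (the prediction is the moving image, the
#' label the fixed image).  Deterministic for fixed inputs.
#'
#' @param pred,label 2D arrays of identical shape, finite.
#' @param params a [reg_params()].
#' @param spacing in-plane pixel spacing in mm (length 1 or 2).
#' @return object of class `mri4d_field`: `u1`, `u2` (displacement in
#'   mm along the two image axes), `spacing`, and the parameters used.
#' @export
register_bspline <- function(pred, label, params = reg_params(), spacing = 1.8) {
  if (!all(dim(pred) == dim(label))) stop("shape mismatch")
  if (!all(is.finite(pred)) || !all(is.finite(label)))
    stop("registration requires finite intensities")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  res <- .register_bspline_cpp(label, pred, params$mesh, 2L * params$mesh,
                               params$radius, params$iterations,
                               params$smoothing_sigma,
                               params$max_step_phys / mean(spacing),
                               params$convergence_min,
                               params$convergence_window)
  if (!all(is.finite(res$ui)) || !all(is.finite(res$uj)))
    stop("registration diverged: non-finite displacement field")
  structure(list(u1 = res$ui * spacing[1], u2 = res$uj * spacing[2],
                 spacing = spacing, params = params,
                 fixed = "label", moving = "pred"),
            class = "mri4d_field")
}

#' @export
print.mri4d_field <- function(x, ...) {
  mag <- sqrt(x$u1^2 + x$u2^2)
  cat(sprintf("<mri4d_field> %dx%d, |u| mean %.3f mm, max %.3f mm\n",
              nrow(x$u1), ncol(x$u1), mean(mag), max(mag)))
  invisible(x)
}

# 16x16 sampling lattice at 8x8 voxel spacing anchored at the mask
# bounding-box corner; returns in-image row/col index pairs.
mdisp_lattice <- function(mask, grid_n = 16L, spacing_vox = 8L, offset = 0L) {
  bb <- which(mask, arr.ind = TRUE)
  if (nrow(bb) == 0) stop("mask too small for grid (empty mask)")
  r0 <- min(bb[, 1]) + offset; c0 <- min(bb[, 2]) + offset
  rows <- r0 + spacing_vox * (seq_len(grid_n) - 1L)
  cols <- c0 + spacing_vox * (seq_len(grid_n) - 1L)
  pts <- expand.grid(row = rows, col = cols)
  pts[pts$row <= nrow(mask) & pts$col <= ncol(mask), , drop = FALSE]
}

#' Mean displacement (MDISP) of a deformation field
#'
#' Samples the dense field on a 16x16 lattice with 8x8 voxel spacing
#' anchored at the liver-mask bounding box, keeps in-mask lattice
#' points, and returns the mean Euclidean norm of the sampled
#' displacement vectors in mm.
#'
#' @param field an `mri4d_field` (displacements already in mm).
#' @param mask logical liver mask on the same grid.
#' @param grid_n,spacing_vox,offset lattice geometry.
#' @return mean displacement in mm.
#' @export
mdisp <- function(field, mask, grid_n = 16L, spacing_vox = 8L, offset = 0L) {
  stopifnot(inherits(field, "mri4d_field"))
  if (!any(mask)) stop("mask too small for grid (empty mask)")
  pts <- mdisp_lattice(mask, grid_n, spacing_vox, offset)
  keep <- mask[as.matrix(pts)]
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) stop("mask too small for grid (no in-mask lattice points)")
  idx <- as.matrix(pts)
  mean(sqrt(field$u1[idx]^2 + field$u2[idx]^2))
}

#' Apply a displacement field to an image
#'
#' `out(x) = img(x + u(x))`, bilinear interpolation, border clamp.
#'
#' @param img 2D array.
#' @param field an `mri4d_field`.
#' @return warped 2D array.
#' @export
apply_field <- function(img, field) {
  .warp_field(img, field$u1 / field$spacing[1], field$u2 / field$spacing[2])
}

#' Deformation-normalized RMSE
#'
#' Registers the prediction to the label, warps the prediction through
#' the recovered field, and computes the RMSE of the warped prediction
#' against the label: appearance error with displacement explained
#' away.
#'
#' @inheritParams register_bspline
#' @param field optional pre-computed registration (avoids repeating
#'   the costly step when MDISP uses the same pair).
#' @return non-negative scalar.
#' @export
dn_rmse <- function(pred, label, params = reg_params(), spacing = 1.8,
                    field = NULL) {
  if (is.null(field)) field <- register_bspline(pred, label, params, spacing)
  rmse(apply_field(pred, field), label)
}

#' Evaluate a set of prediction/label pairs
#'
#' Computes RMSE, MDISP and DN_RMSE per pair (one registration per
#' pair, shared by MDISP and DN_RMSE) and summarizes mean and 95th
#' percentile per group.  The percentile uses linear interpolation
#' (type 7), so the 95th percentile of 1..100 is 95.05.
#'
#' @param pairs list of lists with `pred`, `label`, optionally `mask`
#'   and grouping fields (e.g. `family`, `minutes`, `subject`).
#' @param mask default logical mask used when a pair has none.
#' @param grouping character vector of grouping keys present in pairs.
#' @param params a [reg_params()].
#' @param spacing pixel spacing in mm.
#' @return object of class `mri4d_report`: `samples` (per-pair data
#'   frame) and `summary` (per-group mean and 95th percentile of each
#'   measure).
#' @export
evaluate_set <- function(pairs, mask = NULL, grouping = character(),
                         params = reg_params(), spacing = 1.8) {
  if (length(pairs) == 0) stop("empty pair set")
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    m <- if (!is.null(pr$mask)) pr$mask else mask
    if (is.null(m)) stop("no mask for pair ", i)
    fld <- register_bspline(pr$pred, pr$label, params, spacing)
    row <- data.frame(pair = i,
                      rmse = rmse(pr$pred, pr$label),
                      mdisp = mdisp(fld, m),
                      dn_rmse = dn_rmse(pr$pred, pr$label, params, spacing,
                                        field = fld))
    for (gk in grouping) row[[gk]] <- pr[[gk]]
    row
  })
  samples <- do.call(rbind, rows)
  summary <- summarize_metrics(samples, grouping)
  structure(list(samples = samples, summary = summary,
                 grouping = grouping, params = params,
                 units = c(rmse = "intensity", mdisp = "mm",
                           dn_rmse = "intensity")),
            class = "mri4d_report")
}

summarize_metrics <- function(samples, grouping = character()) {
  measures <- c("rmse", "mdisp", "dn_rmse")
  key <- if (length(grouping)) interaction(samples[grouping], drop = TRUE)
         else factor(rep("all", nrow(samples)))
  out <- lapply(levels(key), function(lv) {
    sub <- samples[key == lv, , drop = FALSE]
    row <- data.frame(group = lv, n = nrow(sub))
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_p95")]] <- unname(quantile(sub[[m]], 0.95, type = 7))
    }
    for (gk in grouping) row[[gk]] <- sub[[gk]][1]
    row
  })
  do.call(rbind, out)
}

#' @export
print.mri4d_report <- function(x, ...) {
  cat(sprintf("<mri4d_report> %d pairs, %d group(s)\n", nrow(x$samples),
              nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a metric report
#'
#' @param report an `mri4d_report`.
#' @param path output path; `.csv` writes the per-group summary table,
#'   `.json` the full report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(samples = report$samples,
                              summary = report$summary),
                         path, dataframe = "rows", digits = NA)
  } else {
    write.csv(report$summary, path, row.names = FALSE)
  }
  invisible(path)
}
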