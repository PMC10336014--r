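# Domain containers, NIfTI I/O, intensity normalization and
# acquisition-budget conversions shared by all modules.

#' Slice acquisition rate
#'
#' One 2D slice (navigator or data) takes 166 ms to acquire, so one
#' minute of scanning yields about 360 slices, i.e. 180 navigator/data
#' pairs.  The constant is exposed so budget conversions are explicit.
#' @format Named list with `ms_per_slice` (166) and `slices_per_minute` (360).
#' @export
acquisition_rate <- list(ms_per_slice = 166, slices_per_minute = 360)

#' Create a 3D volume
#'
#' A volume is a plain 3D array with millimetre voxel spacing.  Axis
#' order is fixed as (LR, AP, SI): the first index runs right-to-left,
#' so `voxels[k, , ]` is the sagittal slice at LR position `k`.
#'
#' @param voxels 3D numeric array ordered (LR, AP, SI).
#' @param spacing voxel spacing in mm, length 1 (isotropic) or 3.
#' @return An object of class `mri4d_volume`.
#' @export
as_volume <- function(voxels, spacing = 1.8) {
  if (length(dim(voxels)) != 3L)
    stop("expected rank 3 voxel array, got rank ", length(dim(voxels)))
  if (!all(is.finite(voxels))) stop("voxel array must be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be strictly positive, length 1 or 3")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 axes = c("LR", "AP", "SI")),
            class = "mri4d_volume")
}

#' @export
print.mri4d_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mri4d_volume> %d x %d x %d (LR, AP, SI), spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read a 3D volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3D image.
#' @return An [as_volume()] object; spacing is taken from the header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected rank 3 NIfTI volume, got rank ", length(dim(img)))
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  as_volume(vox, spacing = RNifti::pixdim(img)[1:3])
}

#' Write a 3D volume to NIfTI
#'
#' @param volume an [as_volume()] object.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mri4d_volume"))
  img <- RNifti::asNifti(volume$voxels)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Create an interleaved navigator/data slice sequence
#'
#' Frames alternate navigator, data, navigator, data, ...  All
#' navigator frames share one fixed LR position (the respiratory
#' surrogate in the right liver lobe); each data frame carries its own
#' LR position.  Timestamps are seconds from sequence start and must be
#' strictly increasing.
#'
#' @param frames list of 2D arrays (AP x SI), all the same shape.
#' @param timestamps_s numeric vector of acquisition times in seconds.
#' @param roles character vector, each `"navigator"` or `"data"`.
#' @param slice_positions integer LR index (1-based) per frame.
#' @param navigator_position the fixed navigator LR index.
#' @return An object of class `mri4d_sequence`.
#' @export
slice_sequence <- function(frames, timestamps_s, roles, slice_positions,
                           navigator_position) {
  n <- length(frames)
  stopifnot(length(timestamps_s) == n, length(roles) == n,
            length(slice_positions) == n)
  if (any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  if (!all(roles %in% c("navigator", "data")))
    stop("roles must be 'navigator' or 'data'")
  if (any(roles != rep(c("navigator", "data"), length.out = n)))
    stop("frames must alternate navigator, data, ...")
  if (any(slice_positions[roles == "navigator"] != navigator_position))
    stop("navigator frames must share navigator_position")
  structure(list(frames = frames, timestamps_s = timestamps_s, roles = roles,
                 slice_positions = as.integer(slice_positions),
                 navigator_position = as.integer(navigator_position)),
            class = "mri4d_sequence")
}

#' @export
print.mri4d_sequence <- function(x, ...) {
  cat(sprintf("<mri4d_sequence> %d frames (%d pairs), navigator at LR %d, %.1f s\n",
              length(x$frames), length(x$frames) %/% 2L, x$navigator_position,
              diff(range(x$timestamps_s))))
  invisible(x)
}

#' Number of navigator/data pairs in a sequence
#' @param x an `mri4d_sequence`.
#' @return integer pair count.
#' @export
n_pairs <- function(x) length(x$frames) %/% 2L

#' Write / read a slice sequence as 4D NIfTI plus JSON sidecar
#'
#' The frames are stored as a (AP, SI, 1, T) NIfTI; roles, positions,
#' timestamps and the navigator position go into `<path>.json`.
#'
#' @param x an `mri4d_sequence`.
#' @param path output NIfTI path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(x, path) {
  stopifnot(inherits(x, "mri4d_sequence"))
  d <- dim(x$frames[[1]])
  arr <- array(unlist(x$frames), dim = c(d[1], d[2], 1L, length(x$frames)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  side <- list(timestamps_s = x$timestamps_s, roles = x$roles,
               slice_positions = x$slice_positions,
               navigator_position = x$navigator_position)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(seq_len(dim(arr)[4]), function(t) arr[, , 1L, t])
  slice_sequence(frames, side$timestamps_s, side$roles,
                 side$slice_positions, side$navigator_position)
}

#' Create a training sample
#'
#' The supervised learning unit: a navigator frame, the two static
#' conditioning slices, and the moving data slice used as label.
#'
#' @param navigator,static_at_nav,static_at_target,label 2D arrays of
#'   identical shape (AP x SI).
#' @param target_position LR index of the label slice.
#' @param subject_id subject tag (used to look up normalization).
#' @return An object of class `mri4d_sample`.
#' @export
training_sample <- function(navigator, static_at_nav, static_at_target,
                            label, target_position, subject_id) {
  dims <- lapply(list(navigator, static_at_nav, static_at_target, label), dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all four images must share one shape")
  structure(list(navigator = navigator, static_at_nav = static_at_nav,
                 static_at_target = static_at_target, label = label,
                 target_position = as.integer(target_position),
                 subject_id = subject_id),
            class = "mri4d_sample")
}

#' Per-subject z-score normalization
#'
#' Pools every voxel of the supplied images (dynamic frames and static
#' volume alike) and whitens them to zero mean and unit standard
#' deviation.  The original first and second moments are kept so the
#' mapping can be reversed after prediction.
#'
#' @param images a numeric array or a list of numeric arrays.
#' @param subject_id subject tag stored with the parameters.
#' @return list with `images` (same structure, normalized) and `params`
#'   (class `mri4d_norm`: `mean`, `std`, `subject_id`).
#' @export
zscore_normalize <- function(images, subject_id = NA_character_) {
  single <- !is.list(images)
  if (single) images <- list(images)
  pool <- unlist(images, use.names = FALSE)
  if (!any(is.finite(pool))) stop("need at least one finite voxel")
  mu <- mean(pool)
  sdv <- sqrt(mean((pool - mu)^2))
  if (sdv == 0) stop("degenerate intensity distribution (constant input)")
  out <- lapply(images, function(im) (im - mu) / sdv)
  params <- structure(list(mean = mu, std = sdv, subject_id = subject_id),
                      class = "mri4d_norm")
  list(images = if (single) out[[1]] else out, params = params)
}

#' Reverse z-score normalization
#'
#' @param normalized a normalized array or list of arrays.
#' @param params an `mri4d_norm` object from [zscore_normalize()].
#' @return the de-whitened images on the original intensity scale.
#' @export
denormalize <- function(normalized, params) {
  if (missing(params) || is.null(params)) stop("normalization params missing")
  if (!inherits(params, "mri4d_norm")) stop("params must be an mri4d_norm")
  if (params$std <= 0) stop("params$std must be > 0")
  f <- function(im) im * params$std + params$mean
  if (is.list(normalized)) lapply(normalized, f) else f(normalized)
}

#' Convert acquisition minutes to navigator/data pairs
#'
#' One acquired slice takes 166 ms, so a minute holds about 360 slices;
#' a navigator/data pair consumes two slices, giving 180 pairs per
#' minute (e.g. 2 minutes = 720 slices = 360 pairs).
#'
#' @param minutes positive acquisition time in minutes.
#' @return integer number of pairs.
#' @export
minutes_to_pairs <- function(minutes) {
  if (any(minutes <= 0)) stop("minutes must be > 0")
  as.integer(round(minutes * acquisition_rate$slices_per_minute) / 2)
}
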