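# Three-channel conditional U-Net: architecture plan, seeded
# initialization, hand-rolled forward/backward over the C++ conv
# primitives, Adam/MSE training with checkpointing, and volume
# reconstruction by batched slice prediction.

#' U-Net architecture configuration
#'
#' The encoder is four blocks of two padded 3x3 convolutions (the
#' second convolution of each block doubles the feature count), each
#' followed by a leaky ReLU; 2x2 max pooling follows the first three
#' blocks, so an input of `H x W x 3` reaches a latent space of
#' `H/8 x W/8` with `16 * base_filters` feature maps (512 for the
#' reference width 32).  The decoder is three blocks of two transposed
#' convolutions with dropout between them: a 2x2 stride-2 up-convolution
#' (halving features), a skip concatenation with the matching encoder
#' block, and a 3x3 stride-1 transposed convolution; a final 1x1
#' convolution maps to one channel.  The concrete channel plan (in
#' units of `base_filters` b) is: up 8b -> cat -> 16b, up 8b -> cat ->
#' 8b, up 2b -> cat -> 2b; with b = 32 the plan has 6,776,513 trainable
#' parameters (6.8 million).
#'
#' @param in_shape input (H, W, channels); H and W divisible by 8.
#' @param base_filters filters of the first convolution (reference: 32).
#' @param leaky_slope negative slope of the leaky ReLU, in (0, 1).
#' @param dropout_rate decoder dropout probability.
#' @return list of class `mri4d_arch` including the per-layer `plan`.
#' @export
arch_config <- function(in_shape = c(128, 128, 3), base_filters = 32,
                        leaky_slope = 0.1, dropout_rate = 0.5) {
  levels <- 3L
  if (any(in_shape[1:2] %% 2^levels != 0))
    stop("input H and W must be divisible by ", 2^levels)
  if (base_filters < 1) stop("base_filters must be >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1) stop("leaky_slope must be in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  b <- as.integer(base_filters)
  cin <- as.integer(in_shape[3])
  plan <- list(
    e1a = list(k = 3L, cin = cin,     cout = b),
    e1b = list(k = 3L, cin = b,       cout = 2L * b),
    e2a = list(k = 3L, cin = 2L * b,  cout = 2L * b),
    e2b = list(k = 3L, cin = 2L * b,  cout = 4L * b),
    e3a = list(k = 3L, cin = 4L * b,  cout = 4L * b),
    e3b = list(k = 3L, cin = 4L * b,  cout = 8L * b),
    e4a = list(k = 3L, cin = 8L * b,  cout = 8L * b),
    e4b = list(k = 3L, cin = 8L * b,  cout = 16L * b),
    u1  = list(k = 2L, cin = 16L * b, cout = 8L * b,  up = TRUE),
    v1  = list(k = 3L, cin = 16L * b, cout = 16L * b),
    u2  = list(k = 2L, cin = 16L * b, cout = 8L * b,  up = TRUE),
    v2  = list(k = 3L, cin = 12L * b, cout = 8L * b),
    u3  = list(k = 2L, cin = 8L * b,  cout = 2L * b,  up = TRUE),
    v3  = list(k = 3L, cin = 4L * b,  cout = 2L * b),
    out = list(k = 1L, cin = 2L * b,  cout = 1L))
  structure(list(in_shape = as.integer(in_shape), base_filters = b,
                 levels = levels, latent_features = 16L * b,
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 plan = plan),
            class = "mri4d_arch")
}

#' Count trainable parameters
#'
#' @param x an [arch_config()] or a built model.
#' @return total number of trainable weights and biases.
#' @export
count_parameters <- function(x) {
  arch <- if (inherits(x, "mri4d_model")) x$arch else x
  stopifnot(inherits(arch, "mri4d_arch"))
  sum(vapply(arch$plan, function(l) l$k^2 * l$cin * l$cout + l$cout, 0))
}

#' Build a seeded U-Net model
#'
#' Weights use scaled (He-style) normal initialization; the same seed
#' reproduces identical initial weights.
#'
#' @param arch an [arch_config()].
#' @param seed integer seed for the initialization.
#' @return object of class `mri4d_model` (a "model handle"): weights,
#'   architecture, per-subject normalization parameters (filled at
#'   training time) and a provenance record (family `pre` / `pre+TL` /
#'   `direct`, data budgets in minutes, seed).
#' @export
build_unet <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "mri4d_arch"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  weights <- lapply(arch$plan, function(l) {
    fan_in <- l$k^2 * l$cin
    list(w = array(rnorm(l$k^2 * l$cin * l$cout, 0, sqrt(2 / fan_in)),
                   dim = c(l$k, l$k, l$cin, l$cout)),
         b = numeric(l$cout))
  })
  structure(list(weights = weights, arch = arch, norms = list(),
                 provenance = list(family = NA_character_,
                                   source_minutes = NA_real_,
                                   target_minutes = NA_real_,
                                   seed = as.integer(seed)),
                 history = NULL),
            class = "mri4d_model")
}

lrelu <- function(x, slope) { x[x < 0] <- x[x < 0] * slope; x }
lrelu_bw <- function(post, d, slope) { d[post < 0] <- d[post < 0] * slope; d }

ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass.  x: (H, W, 3, N).  When `training`, activations needed
# by the backward pass are cached and dropout is active (inverted
# scaling), drawing its masks from the current R RNG.
unet_forward <- function(weights, x, arch, training = FALSE) {
  s <- arch$leaky_slope
  p <- if (training) arch$dropout_rate else 0
  cv <- function(nm, inp) .conv2d_fw(inp, weights[[nm]]$w, weights[[nm]]$b)
  up <- function(nm, inp) .tconv2_fw(inp, weights[[nm]]$w, weights[[nm]]$b)
  drop_mask <- function(a) {
    if (p <= 0) return(NULL)
    array(stats::rbinom(length(a), 1, 1 - p) / (1 - p), dim = dim(a))
  }
  cache <- if (training) list(x = x) else NULL
  e1a <- lrelu(cv("e1a", x), s);   e1b <- lrelu(cv("e1b", e1a), s)
  p1 <- .maxpool2_fw(e1b)
  e2a <- lrelu(cv("e2a", p1$y), s); e2b <- lrelu(cv("e2b", e2a), s)
  p2 <- .maxpool2_fw(e2b)
  e3a <- lrelu(cv("e3a", p2$y), s); e3b <- lrelu(cv("e3b", e3a), s)
  p3 <- .maxpool2_fw(e3b)
  e4a <- lrelu(cv("e4a", p3$y), s); e4b <- lrelu(cv("e4b", e4a), s)

  d1u <- lrelu(up("u1", e4b), s)
  m1 <- drop_mask(d1u); if (!is.null(m1)) d1u <- d1u * m1
  c1 <- ccat(d1u, e3b)
  d1 <- lrelu(cv("v1", c1), s)
  d2u <- lrelu(up("u2", d1), s)
  m2 <- drop_mask(d2u); if (!is.null(m2)) d2u <- d2u * m2
  c2 <- ccat(d2u, e2b)
  d2 <- lrelu(cv("v2", c2), s)
  d3u <- lrelu(up("u3", d2), s)
  m3 <- drop_mask(d3u); if (!is.null(m3)) d3u <- d3u * m3
  c3 <- ccat(d3u, e1b)
  d3 <- lrelu(cv("v3", c3), s)
  out <- cv("out", d3)
  if (training)
    cache <- list(x = x, e1a = e1a, e1b = e1b, p1 = p1, e2a = e2a, e2b = e2b,
                  p2 = p2, e3a = e3a, e3b = e3b, p3 = p3, e4a = e4a, e4b = e4b,
                  d1u = d1u, m1 = m1, c1 = c1, d1 = d1, d2u = d2u, m2 = m2,
                  c2 = c2, d2 = d2, d3u = d3u, m3 = m3, c3 = c3, d3 = d3)
  list(out = out, cache = cache)
}

unet_backward <- function(weights, cache, dout, arch) {
  s <- arch$leaky_slope
  g <- list()
  bw_cv <- function(nm, inp, d) {
    r <- .conv2d_bw(inp, weights[[nm]]$w, d)
    g[[nm]] <<- list(w = r$dw, b = r$db)
    r$dx
  }
  bw_up <- function(nm, inp, d) {
    r <- .tconv2_bw(inp, weights[[nm]]$w, d)
    g[[nm]] <<- list(w = r$dw, b = r$db)
    r$dx
  }
  split_cat <- function(d, c1n) {
    list(a = d[, , seq_len(c1n), , drop = FALSE],
         b = d[, , -seq_len(c1n), , drop = FALSE])
  }
  dd3 <- bw_cv("out", cache$d3, dout)
  dc3 <- bw_cv("v3", cache$c3, lrelu_bw(cache$d3, dd3, s))
  sp <- split_cat(dc3, dim(cache$d3u)[3])
  dd3u <- sp$a; de1b_skip <- sp$b
  if (!is.null(cache$m3)) dd3u <- dd3u * cache$m3
  dd2 <- bw_up("u3", cache$d2, lrelu_bw(cache$d3u, dd3u, s))
  dc2 <- bw_cv("v2", cache$c2, lrelu_bw(cache$d2, dd2, s))
  sp <- split_cat(dc2, dim(cache$d2u)[3])
  dd2u <- sp$a; de2b_skip <- sp$b
  if (!is.null(cache$m2)) dd2u <- dd2u * cache$m2
  dd1 <- bw_up("u2", cache$d1, lrelu_bw(cache$d2u, dd2u, s))
  dc1 <- bw_cv("v1", cache$c1, lrelu_bw(cache$d1, dd1, s))
  sp <- split_cat(dc1, dim(cache$d1u)[3])
  dd1u <- sp$a; de3b_skip <- sp$b
  if (!is.null(cache$m1)) dd1u <- dd1u * cache$m1
  de4b <- bw_up("u1", cache$e4b, lrelu_bw(cache$d1u, dd1u, s))

  de4a <- bw_cv("e4b", cache$e4a, lrelu_bw(cache$e4b, de4b, s))
  dp3 <- bw_cv("e4a", cache$p3$y, lrelu_bw(cache$e4a, de4a, s))
  de3b <- .maxpool2_bw(dp3, cache$p3$idx, dim(cache$e3b)) + de3b_skip
  de3a <- bw_cv("e3b", cache$e3a, lrelu_bw(cache$e3b, de3b, s))
  dp2 <- bw_cv("e3a", cache$p2$y, lrelu_bw(cache$e3a, de3a, s))
  de2b <- .maxpool2_bw(dp2, cache$p2$idx, dim(cache$e2b)) + de2b_skip
  de2a <- bw_cv("e2b", cache$e2a, lrelu_bw(cache$e2b, de2b, s))
  dp1 <- bw_cv("e2a", cache$p1$y, lrelu_bw(cache$e2a, de2a, s))
  de1b <- .maxpool2_bw(dp1, cache$p1$idx, dim(cache$e1b)) + de1b_skip
  de1a <- bw_cv("e1b", cache$e1a, lrelu_bw(cache$e1b, de1b, s))
  bw_cv("e1a", cache$x, lrelu_bw(cache$e1a, de1a, s))
  g
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate
#' 0.0004, mean-squared-error loss, batch size 64, 200 epochs,
#' checkpointing on the best validation loss, and seeded augmentation
#' in a physiologically plausible range (in-plane translation up to
#' 5 voxels, rotation up to 5 degrees, intensity scaling within 10%).
#'
#' @param learning_rate Adam step size.
#' @param epochs training epochs (checkpoint evaluated every epoch).
#' @param batch_size minibatch size.
#' @param augment logical; apply random augmentation each epoch.
#' @param augment_ranges list with `translate_vox`, `rotate_deg`,
#'   `intensity`.
#' @param seed integer seed pinning shuffling, augmentation and dropout.
#' @return list of class `mri4d_train_config`.
#' @export
train_config <- function(learning_rate = 4e-4, epochs = 200L, batch_size = 64L,
                         augment = TRUE,
                         augment_ranges = list(translate_vox = 5,
                                               rotate_deg = 5,
                                               intensity = 0.1),
                         seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), augment = augment,
                 augment_ranges = augment_ranges, seed = as.integer(seed),
                 verbose = verbose),
            class = "mri4d_train_config")
}

#' Assemble the three-channel input stack of a sample
#'
#' Channel order is semantic: (1) navigator, (2) static slice at the
#' navigator position, (3) static slice at the target position.  All
#' channels are whitened with the subject's normalization parameters.
#'
#' @param sample an [training_sample()].
#' @param norm the subject's `mri4d_norm` parameters.
#' @return array (H, W, 3).
#' @export
assemble_input <- function(sample, norm) {
  stopifnot(inherits(sample, "mri4d_sample"), inherits(norm, "mri4d_norm"))
  d <- dim(sample$navigator)
  z <- function(im) (im - norm$mean) / norm$std
  array(c(z(sample$navigator), z(sample$static_at_nav),
          z(sample$static_at_target)), dim = c(d[1], d[2], 3L))
}

#' Jointly augment a training sample
#'
#' Draws one rigid in-plane transform (translation, rotation) and one
#' intensity scale from the current R RNG state and applies it
#' identically to the navigator, the label, and the two static
#' conditioning channels, so the geometric relation between input and
#' label is preserved.  All-zero ranges give the identity.
#'
#' @param sample an [training_sample()].
#' @param ranges list with `translate_vox`, `rotate_deg`, `intensity`.
#' @return the augmented [training_sample()].
#' @export
augment <- function(sample, ranges = list(translate_vox = 5, rotate_deg = 5,
                                          intensity = 0.1)) {
  stopifnot(inherits(sample, "mri4d_sample"))
  ti <- runif(1, -ranges$translate_vox, ranges$translate_vox)
  tj <- runif(1, -ranges$translate_vox, ranges$translate_vox)
  th <- runif(1, -ranges$rotate_deg, ranges$rotate_deg)
  sc <- 1 + runif(1, -ranges$intensity, ranges$intensity)
  f <- function(im) sc * .warp_rigid(im, th, ti, tj)
  training_sample(f(sample$navigator), f(sample$static_at_nav),
                  f(sample$static_at_target), f(sample$label),
                  sample$target_position, sample$subject_id)
}

# Stack samples into training tensors using per-subject normalization.
samples_to_stacks <- function(samples, norms) {
  d <- dim(samples[[1]]$navigator)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], 3L, n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    sm <- samples[[i]]
    nm <- norms[[sm$subject_id]]
    if (is.null(nm)) stop("no normalization params for subject ", sm$subject_id)
    x[, , , i] <- assemble_input(sm, nm)
    y[, , 1L, i] <- (sm$label - nm$mean) / nm$std
  }
  list(x = x, y = y,
       subject = vapply(samples, function(s) s$subject_id, ""))
}

# Per-epoch stack augmentation: one rigid+intensity transform per
# sample, applied to all three input channels and the label.
augment_stacks <- function(x, y, ranges) {
  n <- dim(x)[4]
  for (i in seq_len(n)) {
    ti <- runif(1, -ranges$translate_vox, ranges$translate_vox)
    tj <- runif(1, -ranges$translate_vox, ranges$translate_vox)
    th <- runif(1, -ranges$rotate_deg, ranges$rotate_deg)
    sc <- 1 + runif(1, -ranges$intensity, ranges$intensity)
    for (c in 1:3) x[, , c, i] <- sc * .warp_rigid(x[, , c, i], th, ti, tj)
    y[, , 1, i] <- sc * .warp_rigid(y[, , 1, i], th, ti, tj)
  }
  list(x = x, y = y)
}

adam_init <- function(weights)
  lapply(weights, function(l) list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
                                   mb = numeric(length(l$b)), vb = numeric(length(l$b))))

adam_step <- function(weights, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(weights)) {
    st <- state[[nm]]; gr <- grads[[nm]]
    st$mw <- b1 * st$mw + (1 - b1) * gr$w
    st$vw <- b2 * st$vw + (1 - b2) * gr$w^2
    st$mb <- b1 * st$mb + (1 - b1) * gr$b
    st$vb <- b2 * st$vb + (1 - b2) * gr$b^2
    mhw <- st$mw / (1 - b1^t); vhw <- st$vw / (1 - b2^t)
    mhb <- st$mb / (1 - b1^t); vhb <- st$vb / (1 - b2^t)
    weights[[nm]]$w <- weights[[nm]]$w - lr * mhw / (sqrt(vhw) + eps)
    weights[[nm]]$b <- weights[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

mse_of <- function(pred, y) mean((pred - y)^2)

#' Train a slice-prediction model
#'
#' Runs seeded minibatch Adam/MSE training with per-epoch augmentation
#' and returns the weights of the epoch with the smallest validation
#' loss.  The history records train/validation loss per epoch.
#'
#' @param model a [build_unet()] model (fresh or pre-trained).
#' @param train_samples,val_samples nonempty lists of
#'   [training_sample()] objects.
#' @param cfg a [train_config()].
#' @param norms named list of per-subject `mri4d_norm` parameters
#'   covering every subject in the samples.
#' @return the trained `mri4d_model`; `$history` holds the loss curves,
#'   `$val_loss` the checkpointed validation loss.
#' @export
train <- function(model, train_samples, val_samples, cfg = train_config(),
                  norms) {
  stopifnot(inherits(model, "mri4d_model"), inherits(cfg, "mri4d_train_config"))
  if (length(train_samples) == 0 || length(val_samples) == 0)
    stop("training and validation sets must be nonempty")
  tr <- samples_to_stacks(train_samples, norms)
  va <- samples_to_stacks(val_samples, norms)
  model$norms <- utils::modifyList(model$norms, norms)
  fitted <- train_stacks(model, tr, va, cfg)
  fitted
}

# Engine working directly on prepared stacks.
train_stacks <- function(model, tr, va, cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  weights <- model$weights
  arch <- model$arch
  n <- dim(tr$x)[4]
  state <- adam_init(weights)
  best <- list(loss = Inf, weights = weights)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  tstep <- 0
  for (ep in seq_len(cfg$epochs)) {
    if (cfg$augment) {
      ag <- augment_stacks(tr$x, tr$y, cfg$augment_ranges)
    } else ag <- tr
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- ag$x[, , , idx, drop = FALSE]
      yb <- ag$y[, , , idx, drop = FALSE]
      fw <- unet_forward(weights, xb, arch, training = TRUE)
      loss <- mse_of(fw$out, yb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (diverged; reduce learning rate)")
      dout <- 2 * (fw$out - yb) / length(yb)
      grads <- unet_backward(weights, fw$cache, dout, arch)
      tstep <- tstep + 1
      upd <- adam_step(weights, grads, state, cfg$learning_rate, tstep)
      weights <- upd$weights; state <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    val_pred <- unet_forward(weights, va$x, arch, training = FALSE)$out
    vloss <- mse_of(val_pred, va$y)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vloss))
    if (vloss < best$loss) best <- list(loss = vloss, weights = weights)
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      ep_loss / nb, vloss))
  }
  model$weights <- best$weights
  model$history <- hist
  model$val_loss <- best$loss
  model$train_config <- cfg
  model
}

#' Predict slices from assembled input stacks
#'
#' @param object a trained `mri4d_model`.
#' @param newdata array (H, W, 3, N) of normalized input stacks, or a
#'   single (H, W, 3) stack.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return array (H, W, 1, N) of normalized predictions.
#' @export
predict.mri4d_model <- function(object, newdata, batch_size = 64L, ...) {
  x <- newdata
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    o <- unet_forward(object$weights, x[, , , idx, drop = FALSE],
                      object$arch, training = FALSE)$out
    out <- if (is.null(out)) o else {
      tmp <- array(0, c(dim(o)[1:3], dim(out)[4] + dim(o)[4]))
      tmp[, , , seq_len(dim(out)[4])] <- out
      tmp[, , , dim(out)[4] + seq_len(dim(o)[4])] <- o
      tmp
    }
  }
  out
}

#' Reconstruct a 3D volume from one navigator frame
#'
#' Builds the three-channel stack for every LR position of the static
#' volume (same navigator, varying target slice), predicts all
#' positions in one batched forward pass, de-normalizes, and assembles
#' the volume in position order.  Mapping over a list of navigators
#' reconstructs a 2D+t series or a full 4D sequence.
#'
#' @param model a trained `mri4d_model`.
#' @param navigator 2D navigator frame (AP x SI).
#' @param static_volume the subject's static [as_volume()].
#' @param norm the subject's `mri4d_norm` parameters.
#' @param navigator_position LR index of the navigator plane in the
#'   static volume (conditioning channel 2).
#' @param positions LR indices to predict (default: all).
#' @param batch_size forward chunk size.
#' @return an [as_volume()] with predicted voxels (LR, AP, SI).
#' @export
reconstruct_volume <- function(model, navigator, static_volume, norm,
                               navigator_position, positions = NULL,
                               batch_size = 64L) {
  stopifnot(inherits(model, "mri4d_model"), inherits(norm, "mri4d_norm"))
  d <- dim(navigator)
  hw <- model$arch$in_shape[1:2]
  if (!all(d == hw))
    stop(sprintf("navigator shape %dx%d does not match model input %dx%d",
                 d[1], d[2], hw[1], hw[2]))
  vox <- static_volume$voxels
  if (is.null(positions)) positions <- seq_len(dim(vox)[1])
  z <- function(im) (im - norm$mean) / norm$std
  x <- array(0, c(d[1], d[2], 3L, length(positions)))
  znav <- z(navigator)
  zsn <- z(vox[navigator_position, , ])
  for (i in seq_along(positions)) {
    x[, , 1, i] <- znav
    x[, , 2, i] <- zsn
    x[, , 3, i] <- z(vox[positions[i], , ])
  }
  pred <- predict(model, x, batch_size = batch_size)
  out <- array(0, c(length(positions), d[1], d[2]))
  for (i in seq_along(positions)) out[i, , ] <- denormalize(pred[, , 1, i], norm)
  as_volume(out, static_volume$spacing)
}

#' Reconstruct a 2D+t series or 4D sequence
#'
#' Maps [reconstruct_volume()] over a list of navigator frames; each
#' navigator yields one 3D volume (4D = one volume per time point).
#'
#' @inheritParams reconstruct_volume
#' @param navigators list of 2D navigator frames.
#' @return list of [as_volume()] objects, one per navigator.
#' @export
reconstruct_series <- function(model, navigators, static_volume, norm,
                               navigator_position, positions = NULL,
                               batch_size = 64L) {
  lapply(navigators, function(nav)
    reconstruct_volume(model, nav, static_volume, norm, navigator_position,
                       positions, batch_size))
}

#' @export
print.mri4d_model <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("<mri4d_model> %s  input %s  base %d  params %s\n",
              if (is.na(pr$family)) "(untrained)" else pr$family,
              paste(x$arch$in_shape, collapse = "x"), x$arch$base_filters,
              format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best val MSE %.5f\n",
                nrow(x$history), x$val_loss))
  invisible(x)
}

#' @export
summary.mri4d_model <- function(object, ...) {
  cat("Three-channel conditional U-Net\n")
  print(object)
  plan <- object$arch$plan
  for (nm in names(plan)) {
    l <- plan[[nm]]
    cat(sprintf("  %-4s %dx%d conv  %4d -> %4d  (%s params)\n", nm, l$k, l$k,
                l$cin, l$cout,
                format(l$k^2 * l$cin * l$cout + l$cout, big.mark = ",")))
  }
  cat(sprintf("  total trainable parameters: %s (%.1f million)\n",
              format(count_parameters(object), big.mark = ","),
              count_parameters(object) / 1e6))
  invisible(object)
}

#' @export
coef.mri4d_model <- function(object, ...) object$weights

#' @export
plot.mri4d_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE",
                    main = "training history", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Residual maps of a model on labelled samples
#'
#' @param object a trained `mri4d_model`.
#' @param samples list of [training_sample()] objects.
#' @param ... unused.
#' @return list of 2D arrays, prediction minus label, original scale.
#' @export
residuals.mri4d_model <- function(object, samples, ...) {
  lapply(samples, function(sm) {
    nm <- object$norms[[sm$subject_id]]
    if (is.null(nm)) stop("no normalization params for subject ", sm$subject_id)
    p <- predict(object, assemble_input(sm, nm))
    denormalize(p[, , 1, 1], nm) - sm$label
  })
}
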