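# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Default 64^3 subject used by phantom and metric tests.
fx_subject <- function() memo("subject64", function() make_subject(seed = 2))

# A liver slice of that subject plus its mask, away from the liver edge.
fx_liver_slice <- function() memo("liver_slice", function() {
  sub <- fx_subject()
  k <- sub$navigator_position + 6L
  list(img = sub$static$voxels[k, , ], mask = sub$mask[k, , ], lr = k,
       subject = sub)
})

# Small 32^3 subject (drawn through the cohort generator so the
# anatomy fits the smaller field of view).
fx_subject32 <- function() memo("subject32", function()
  make_cohort(1, 1, 0, seed = 1, grid = 32L)$source[[1]])

# Rigid in-plane shift of an image by (di, dj) pixels.
shift_img <- function(img, di, dj)
  mri4d:::.warp_field(img, matrix(di, nrow(img), ncol(img)),
                      matrix(dj, nrow(img), ncol(img)))

# Tiny trained model on a synthetic linear mapping; exercises the
# optimizer end to end in about a second.
fx_tiny_fit <- function() memo("tiny_fit", function() {
  arch <- arch_config(c(16, 16, 3), base_filters = 2, dropout_rate = 0)
  smps <- lapply(1:10, function(i) {
    set.seed(100 + i)
    nav <- matrix(rnorm(256), 16, 16)
    s1 <- matrix(rnorm(256), 16, 16)
    s2 <- matrix(rnorm(256), 16, 16)
    training_sample(nav, s1, s2, label = 0.8 * s2 + 0.2 * nav, 5L, "sub")
  })
  nrm <- zscore_normalize(lapply(smps, `[[`, "label"), "sub")$params
  cfg <- train_config(epochs = 15, batch_size = 4, augment = FALSE,
                      seed = 9, learning_rate = 2e-3)
  list(model = train(build_unet(arch, 1), smps[1:8], smps[9:10], cfg,
                     list(sub = nrm)),
       arch = arch, samples = smps, norm = nrm, cfg = cfg)
})

# Micro experiment configuration for harness determinism tests.
fx_micro_cfg <- function()
  experiment_config("ci", n_source = 2L, n_target = 1L, n_sequences = 4L,
                    eval_pairs_per_seq = 3L, epochs = 3L)
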