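# Shared fixtures.  The scaled-down training run used by the learnability
# and explanation tests is expensive, so it is trained once per session and
# cached.

.fixture_cache <- new.env(parent = emptyenv())

# The scaled-down training protocol: 200 synthetic images at 64 px, the
# reference architecture at base width 8, 30 epochs under seed 42
# (batch 8, AdamW lr 1e-3, no augmentation; held-out metrics measured once
# at the end).
learnability_fixture <- function() {
  if (is.null(.fixture_cache$learn)) {
    samples <- generate_synthetic(
      synthetic_spec(n_images = 200, image_size = 64, seed = 42))
    splits <- split_dataset(samples, seed = 42)
    model <- build_munet(
      network_config(input_size = 64, base_filters = 8, seed = 42))
    cfg <- train_config(learning_rate = 1e-3, epochs = 30, batch_size = 8,
                        seed = 42, augment = NULL)
    res <- train_munet(model, list(train = splits$train, val = NULL), cfg)
    heldout <- lapply(splits$test, function(s) {
      pm <- predict_mask(model, s$image)
      metric_report(pm$mask[, , 1, 1], s$mask, s$id)
    })
    .fixture_cache$learn <- list(
      model = model, history = res$history, splits = splits,
      heldout = aggregate_reports(heldout))
  }
  .fixture_cache$learn
}

# A tiny trainable configuration (32 px input, base width 4) for fast
# training-behaviour tests.
tiny_setup <- function(n = 12L, seed = 7L) {
  samples <- generate_synthetic(
    synthetic_spec(n_images = n, image_size = 32, seed = seed))
  model <- build_munet(network_config(input_size = 32, base_filters = 4,
                                      seed = seed))
  list(samples = samples, model = model)
}

# An identity-configured residual block: batch norms frozen, attention
# bypassed, main path zeroed, 1x1 shortcut set to the identity.
identity_cbres <- function(channels = 3L) {
  blk <- cbres_block(channels, block_config(
    channels, bn_identity = TRUE, cbam = cbam_config(enabled = FALSE)))
  munetseg:::block_zero_weights(blk)
  for (i in seq_len(channels))
    blk$children$conv_s$params$w[1, 1, i, i] <- 1
  blk
}
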