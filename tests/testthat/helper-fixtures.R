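# Shared fixtures, built lazily and memoized so only suites that need the
# trained codec pay for it once.

.fixture_env <- new.env(parent = emptyenv())

tiny_scaffold <- function() {
  default_scaffold(image_shape = c(12L, 12L), n_classes = 10L, k = 24L,
                   post_merge_units = 32L)
}

tiny_corpus <- function(n = 200L) {
  key <- paste0("corpus_", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(n, scaffold = tiny_scaffold(),
                                           d = 64L, seed = 11L)
  }
  .fixture_env[[key]]
}

# Codec used for reconstruction-fidelity checks (wider latent code).
fidelity_codec <- function() {
  if (is.null(.fixture_env$fid_codec)) {
    .fixture_env$fid_codec <- train_codec(
      tiny_corpus(), k = 48L, d = 64L, epochs = 450L, warmup_epochs = 150L,
      sharpen_epochs = 80L, seed = 3L)
  }
  .fixture_env$fid_codec
}

# Codec matching the end-to-end smoke configuration (k = 24).
smoke_codec <- function() {
  if (is.null(.fixture_env$smoke_codec)) {
    .fixture_env$smoke_codec <- train_codec(
      tiny_corpus(), k = 24L, d = 64L, epochs = 300L, warmup_epochs = 120L,
      sharpen_epochs = 60L, seed = 3L)
  }
  .fixture_env$smoke_codec
}

tiny_images <- function() {
  if (is.null(.fixture_env$images)) {
    .fixture_env$images <- make_synthetic_images(
      synthetic_image_config(n_classes = 10L, shape = c(12L, 12L),
                             n_train = 224L, n_eval = 96L), seed = 2L)
  }
  .fixture_env$images
}

smoke_backend <- function(epochs = 15L) {
  codec <- smoke_codec()
  pool <- unique(t(vapply(tiny_corpus(), function(s)
    encode_genotype(codec, s), integer(codec$k))))
  serann_backend(codec, tiny_images(), tiny_scaffold(), pool,
                 epochs = epochs, batch = 32L, lr = 3e-3)
}
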