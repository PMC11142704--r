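# Shared desk-scale fixtures, built once per test run.

# Small planted-signal dataset + matching provider and stores.
fixture_env <- new.env(parent = emptyenv())

small_synthetic <- function() {
  if (is.null(fixture_env$syn)) {
    cfg <- synthetic_config(n_proteins = 25L, n_molecules = 25L,
                            n_pairs = 300L, seed = 101L)
    gen <- generate_dataset(cfg)
    provider <- synthetic_embedding_provider(
      embedding_spec(d_p = 32L, d_s = 16L), seed = 101L,
      signal_tokens = synthetic_signal_tokens(cfg))
    stores <- embed_dataset(provider, gen$dataset)
    fixture_env$syn <- list(cfg = cfg, dataset = gen$dataset,
                            manifest = gen$manifest, provider = provider,
                            stores = stores)
  }
  fixture_env$syn
}

# A compact encoder trained briefly on the small dataset (enough for
# deterministic downstream tests; not meant to converge).
small_trained_encoder <- function() {
  if (is.null(fixture_env$enc)) {
    fx <- small_synthetic()
    sp <- make_split(fx$dataset,
                     split_spec("random", n_repeats = 1L, seed = 101L))[[1]]
    cfg <- joint_encoder_config(preset = "compact", epochs = 4L, seed = 101L)
    model <- train_encoder(fx$dataset[sp$train], fx$stores, cfg,
                           val = fx$dataset[sp$val])
    fixture_env$enc <- list(model = model, split = sp)
  }
  fixture_env$enc
}

# Tiny random token matrices for direct encoder-level tests.
random_token_matrix <- function(n, d, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), n, d)
  class(m) <- c("token_embedding_matrix", "matrix", "array")
  m
}

expect_psinter_error <- function(expr, class) {
  expect_error(expr, class = class)
}
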