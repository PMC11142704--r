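test_that("planted scores follow the factor model exactly", {
  cfg <- synthetic_config(motifs = "ACD", fragments = "N", weights = 1,
                          effect_size = 2)
  # two motif occurrences x fragment present x weight 1 -> 2 * effect_size
  expect_equal(planted_score("ACDKKACDKK", "CCN", cfg), 4)
  expect_equal(planted_score("ACDKKACDKK", "CCO", cfg), 0)  # no fragment
  # appending a motif occurrence increases the matched term
  expect_gt(planted_score("ACDKKACDKKACD", "CCN", cfg),
            planted_score("ACDKKACDKK", "CCN", cfg))
  # overlapping occurrences are counted
  cfg2 <- synthetic_config(motifs = "AAA", fragments = "N", weights = 1)
  expect_equal(planted_score("AAAA", "CN", cfg2), 2)
  # zero effect size silences everything
  cfg0 <- synthetic_config(motifs = "ACD", fragments = "N", weights = 1,
                           effect_size = 0)
  expect_equal(planted_score("ACDACD", "CCN", cfg0), 0)
})

test_that("generation is reproducible and honors degenerate noise", {
  cfg <- synthetic_config(n_proteins = 15L, n_molecules = 15L,
                          n_pairs = 120L, noise_sd = 0, seed = 31L)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset, g2$dataset)
  expect_identical(g1$manifest$score, g2$manifest$score)
  # zero noise: labels equal the planted scores exactly
  expect_equal(g1$dataset$label, g1$manifest$score)
  # manifest scores agree with recomputation from first principles
  idx <- sample(nrow(g1$dataset), 10)
  for (i in idx)
    expect_equal(planted_score(g1$dataset$sequence[i],
                               g1$dataset$smiles[i], cfg),
                 g1$manifest$score[i])
  # sequences respect the length range and alphabet
  lens <- nchar(unique(g1$dataset$sequence))
  expect_true(all(lens >= cfg$protein_length_range[1] &
                    lens <= cfg$protein_length_range[2]))
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]",
                         g1$dataset$sequence)))
})

test_that("classification labels hit the target positive fraction", {
  cfg <- synthetic_config(n_pairs = 4000L, n_proteins = 80L,
                          n_molecules = 80L,
                          task = "binary_classification", seed = 32L)
  gen <- generate_dataset(cfg)
  frac <- mean(gen$dataset$label)
  expect_gte(frac, 0.23); expect_lte(frac, 0.27)
  expect_identical(attr(gen$dataset, "task"), "binary_classification")
  # no spread in scores -> the requested fraction is unreachable
  flat <- synthetic_config(n_pairs = 200L, n_proteins = 20L,
                           n_molecules = 20L, effect_size = 0,
                           task = "binary_classification", seed = 1L)
  expect_error(generate_dataset(flat), class = "psinter_generation_error")
})

test_that("the generative features support near-perfect recovery", {
  # oracle learnability: boosted trees on the true latent factors
  cfg <- synthetic_config(n_pairs = 1200L, noise_sd = 0, seed = 33L)
  gen <- generate_dataset(cfg)
  man <- gen$manifest
  X <- as.matrix(man[, grep("^(motif_count_|fragment_)", names(man))])
  y <- gen$dataset$label
  n_tr <- 1000L
  m <- train_gbm(X[1:n_tr, ], y[1:n_tr],
                 gbm_hyperparams(num_rounds = 300L, learning_rate = 0.1),
                 "regression", seed = 1L)
  hold <- (n_tr + 1):nrow(X)
  r2 <- regression_metrics(y[hold], predict(m, X[hold, ]))$r_squared
  expect_gte(r2, 0.9)
  # permuting labels destroys the recoverable signal
  set.seed(9)
  yp <- sample(y)
  mp <- train_gbm(X[1:n_tr, ], yp[1:n_tr],
                  gbm_hyperparams(num_rounds = 300L, learning_rate = 0.1),
                  "regression", seed = 1L)
  r2p <- regression_metrics(yp[hold], predict(mp, X[hold, ]))$r_squared
  expect_lte(r2p, 0.1)
})
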