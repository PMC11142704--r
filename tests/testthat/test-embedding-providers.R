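test_that("SMILES tokenization follows the regex contract", {
  expect_equal(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_equal(tokenize_smiles("[NH4+]"), "[NH4+]")
  expect_equal(tokenize_smiles("CC(=O)Cl"),
               c("C", "C", "(", "=", "O", ")", "Cl"))
  # tokens concatenate back to a prefix of the input
  for (s in sample(smiles_library(), 40)) {
    toks <- tokenize_smiles(s)
    expect_identical(paste(toks, collapse = ""),
                     substr(s, 1, sum(nchar(toks))))
  }
  # truncation to the maximum token count
  long <- paste(rep("C", 300), collapse = "")
  expect_length(tokenize_smiles(long), 256L)
  expect_error(tokenize_smiles("C XO"), class = "psinter_tokenize_error")
})

test_that("protein tokenization supports residue and k-mer schemes", {
  expect_equal(tokenize_protein("MKVL", scheme = "residue"),
               c("M", "K", "V", "L"))
  expect_equal(tokenize_protein("MKVL", scheme = "kmer", k = 3),
               c("MKV", "KVL"))
  long <- paste(rep("A", 1500), collapse = "")
  expect_length(tokenize_protein(long, scheme = "residue"), 1024L)
})

test_that("synthetic provider embeddings are deterministic and well-shaped", {
  spec <- embedding_spec(d_p = 24L, d_s = 16L)
  prov <- synthetic_embedding_provider(spec, seed = 9L)
  m1 <- embed_tokens(prov, c("C", "C", "O"), "molecule")
  m2 <- embed_tokens(prov, c("C", "C", "O"), "molecule")
  expect_identical(m1, m2)
  expect_identical(m1[1, ], m1[2, ])          # same token, same row
  expect_equal(dim(m1), c(3L, 16L))

  # embeddings depend on the seed
  prov2 <- synthetic_embedding_provider(spec, seed = 10L)
  expect_false(isTRUE(all.equal(m1, embed_tokens(prov2, c("C", "C", "O"),
                                                 "molecule"))))

  # a 1500-residue protein is truncated to the first 1024 tokens
  long <- paste(rep("ACDEFGHIKL", 150), collapse = "")
  prov_res <- synthetic_embedding_provider(spec, seed = 9L,
                                           protein_scheme = "residue")
  expect_equal(nrow(embed_sequence(prov_res, long)), 1024L)
})

test_that("token-identity equivariance: permuting tokens permutes rows", {
  prov <- synthetic_embedding_provider(embedding_spec(d_p = 24L, d_s = 16L),
                                       seed = 4L)
  toks <- c("C", "O", "N", "Cl", "C", "=")
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  m <- embed_tokens(prov, toks, "molecule")
  mp <- embed_tokens(prov, toks[perm], "molecule")
  expect_equal(unname(unclass(mp)), unname(m[perm, ]),
               ignore_attr = TRUE)
})

test_that("signal tokens occupy indicator dimensions", {
  prov <- synthetic_embedding_provider(
    embedding_spec(d_p = 24L, d_s = 16L), seed = 4L,
    signal_tokens = list(protein = c("ACD", "GHK"), molecule = c("N", "O")))
  m <- embed_tokens(prov, c("N", "C", "O"), "molecule")
  expect_equal(unname(m[, 1]), c(1, 0, 0))
  expect_equal(unname(m[, 2]), c(0, 0, 1))
  p <- embed_tokens(prov, c("ACD", "CDE", "GHK"), "protein")
  expect_equal(unname(p[, 1]), c(1, 0, 0))
  expect_equal(unname(p[, 2]), c(0, 0, 1))
})

test_that("strict providers reject unknown tokens by name", {
  prov <- synthetic_embedding_provider(
    embedding_spec(d_p = 8L, d_s = 8L), seed = 1L,
    vocabulary = list(molecule = c("C", "O"), protein = LETTERS))
  err <- tryCatch(embed_tokens(prov, c("C", "Zz"), "molecule"),
                  psinter_embedding_error = identity)
  expect_s3_class(err, "psinter_embedding_error")
  expect_match(conditionMessage(err), "Zz")
})

test_that("mean pooling is the column mean and commutes with permutation", {
  m <- rbind(c(0, 2), c(2, 0))
  expect_equal(as.numeric(mean_pool(m)), c(1, 1))
  v <- c(3.2, -1.5, 0.7)
  expect_equal(as.numeric(mean_pool(rbind(v, v, v))), v)
  set.seed(2)
  m2 <- matrix(rnorm(40), 8, 5)
  expect_equal(as.numeric(mean_pool(m2)),
               as.numeric(mean_pool(m2[sample(8), ])))
  expect_error(mean_pool(matrix(numeric(), 0, 4)),
               class = "psinter_value_error")
  # paper-scale width passes through
  prov <- synthetic_embedding_provider(embedding_spec(), seed = 1L)
  expect_length(mean_pool(embed_tokens(prov, c("M", "K"), "protein")), 1280L)
})
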