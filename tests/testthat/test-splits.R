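split_fixture <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      gen <- generate_dataset(synthetic_config(
        n_proteins = 30L, n_molecules = 30L, n_pairs = 600L, seed = 21L))
      ds <<- gen$dataset
    }
    ds
  }
})

test_that("random splits hit the 80/10/10 fractions within one record", {
  ds <- split_fixture()
  res <- make_split(ds, split_spec("random", n_repeats = 3L, seed = 2L))
  expect_length(res, 3L)
  for (r in res) {
    expect_equal(sort(c(r$train, r$val, r$test)), seq_len(nrow(ds)))
    expect_lte(abs(length(r$train) - 0.8 * nrow(ds)), 1)
    expect_lte(abs(length(r$val) - 0.1 * nrow(ds)), 1)
    expect_lte(abs(length(r$test) - 0.1 * nrow(ds)), 1)
  }
  # determinism
  res2 <- make_split(ds, split_spec("random", n_repeats = 3L, seed = 2L))
  expect_identical(res, res2)
})

test_that("cold scenarios enforce exact entity disjointness", {
  ds <- split_fixture()
  for (scenario in c("cold_target", "cold_drug", "cold_both")) {
    res <- make_split(ds, split_spec(scenario, n_repeats = 3L, seed = 5L))
    for (r in res) {
      held_out <- c(r$val, r$test)
      if (scenario %in% c("cold_target", "cold_both"))
        expect_length(intersect(ds$protein_id[r$train],
                                ds$protein_id[held_out]), 0L)
      if (scenario %in% c("cold_drug", "cold_both"))
        expect_length(intersect(ds$smiles[r$train], ds$smiles[held_out]), 0L)
      # parts never overlap
      expect_length(intersect(r$train, held_out), 0L)
      expect_length(intersect(r$val, r$test), 0L)
      if (scenario != "cold_both")
        expect_equal(sort(c(r$train, held_out)), seq_len(nrow(ds)))
      else
        expect_equal(sort(c(r$train, held_out, r$discarded)),
                     seq_len(nrow(ds)))
    }
  }
})

test_that("pair-exclusive splits keep replicate pairs together", {
  ds <- split_fixture()
  # add replicate measurements of existing pairs
  reps <- suppressWarnings(interaction_dataset(
    c(ds$protein_id, ds$protein_id[1:40]),
    c(ds$sequence, ds$sequence[1:40]),
    c(ds$smiles, ds$smiles[1:40]),
    c(ds$label, ds$label[1:40] + 0.1)))
  res <- make_split(reps, split_spec("same_pair_excluded", n_repeats = 2L,
                                     seed = 3L))
  for (r in res) {
    key <- paste(reps$protein_id, reps$smiles)
    expect_length(intersect(key[r$train], key[r$test]), 0L)
    expect_length(intersect(key[r$train], key[r$val]), 0L)
  }
})

test_that("infeasible cold splits raise a feasibility error", {
  ds <- suppressWarnings(interaction_dataset(
    rep("P1", 6), rep("MKVLYA", 6),
    c("CC", "CO", "CN", "CS", "CCl", "CCC"), rnorm(6)))
  expect_error(make_split(ds, split_spec("cold_target")),
               class = "psinter_feasibility_error")
})

test_that("occurrence-controlled splits give each chosen drug exactly k train rows", {
  ds <- split_fixture()
  for (k in c(1L, 3L, 10L)) {
    r <- occurrence_controlled_split(ds, k = k, n_test_drugs = 5L, seed = 4L)
    sel <- r$manifest$selected_molecules
    expect_length(sel, 5L)
    for (mol in sel) {
      train_rows <- which(ds$smiles[r$train] == mol)
      expect_length(train_rows, k)
      # the k training pairs use distinct proteins
      expect_length(unique(ds$protein_id[r$train][train_rows]), k)
      expect_gte(sum(ds$smiles[r$test] == mol), 1L)
    }
    parts <- c(r$train, r$val, r$test, r$discarded)
    expect_length(parts, length(unique(parts)))
  }
  expect_error(
    occurrence_controlled_split(ds, k = 100L, n_test_drugs = 5L, seed = 1L),
    class = "psinter_feasibility_error")
})

test_that("stratified metrics partition the test set over bins", {
  set.seed(8)
  y <- rnorm(100); p <- y + rnorm(100, sd = 0.5)
  vals <- runif(100, 0, 10)
  out <- stratified_metrics(vals, y, p, bin_edges = c(0, 5, 10.01),
                            metric = "mse")
  expect_equal(sum(out$count), 100L)
  # one-bin degeneracy: bin metric equals the global metric
  one <- stratified_metrics(vals, y, p, bin_edges = c(0, 10.01),
                            metric = "mse")
  expect_equal(one$value, mean((y - p)^2))
  expect_error(stratified_metrics(vals, y, p, c(0, 10), metric = "nope"),
               class = "psinter_key_error")
})

test_that("per-bin MCC matches a hand computation on a two-bin case", {
  y <- c(1, 0, 1, 0, 1, 0, 1, 0)
  p <- c(0.9, 0.2, 0.4, 0.1, 0.8, 0.7, 0.6, 0.3)
  vals <- c(1, 1, 1, 1, 5, 5, 5, 5)
  out <- stratified_metrics(vals, y, p, bin_edges = c(0, 3, 6),
                            metric = "mcc")
  mcc_bin1 <- binary_metrics(y[1:4], p[1:4])$mcc
  mcc_bin2 <- binary_metrics(y[5:8], p[5:8])$mcc
  expect_equal(out$value, c(mcc_bin1, mcc_bin2))
  expect_equal(out$count, c(4L, 4L))
  # empty bins are reported with zero count and NA metric
  out2 <- stratified_metrics(vals, y, p, bin_edges = c(0, 3, 4, 6),
                             metric = "mcc")
  expect_equal(out2$count[2], 0L)
  expect_true(is.na(out2$value[2]))
})
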