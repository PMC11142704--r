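#' Specification of a train/validation/test split
#'
#' Scenarios: `random` (record-level split), `cold_target` (no protein of
#' the validation/test sets occurs in training), `cold_drug` (same for
#' molecules), `cold_both` (both; records whose protein and molecule land
#' in different parts are discarded, as in the cold-split procedure this
#' follows), and `same_pair_excluded` (all replicate records of one
#' (protein, molecule) pair stay in one part - the Michaelis-constant
#' scenario). Cold scenarios partition entities first and then assign
#' records, so record-level fractions only approximate the requested
#' fractions.
#'
#' @param scenario one of the five scenario names.
#' @param fractions train/validation/test fractions summing to 1.
#' @param n_repeats number of repeated random splits.
#' @param seed integer seed; repeat `r` uses a seed derived from
#'   `(seed, r)`.
#' @return a `split_spec` list.
#' @export
split_spec <- function(scenario = c("random", "cold_target", "cold_drug",
                                    "cold_both", "same_pair_excluded"),
                       fractions = c(0.8, 0.1, 0.1), n_repeats = 5L,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions <= 0))
    ps_abort("fractions must be three positive numbers summing to 1",
             "psinter_value_error")
  if (n_repeats < 1L)
    ps_abort("n_repeats must be >= 1", "psinter_value_error")
  structure(list(scenario = scenario, fractions = fractions,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "split_spec")
}

#' Generate repeated train/validation/test splits
#'
#' @param data an [interaction_dataset()].
#' @param spec a [split_spec()].
#' @return list of `split_result` objects of length `spec$n_repeats`.
#'   Each holds disjoint integer index vectors `train`, `val`, `test`
#'   into `data`, plus a `manifest` (scenario, repeat, seed, part sizes,
#'   entity-overlap report, and discarded indices for `cold_both`).
#' @export
make_split <- function(data, spec) {
  stopifnot(inherits(data, "interaction_dataset"), inherits(spec, "split_spec"))
  if (spec$scenario %in% c("cold_target", "cold_both") &&
      length(unique(data$protein_id)) < 3L)
    ps_abort("cold target splits need at least 3 distinct proteins",
             "psinter_feasibility_error")
  if (spec$scenario %in% c("cold_drug", "cold_both") &&
      length(unique(data$smiles)) < 3L)
    ps_abort("cold drug splits need at least 3 distinct molecules",
             "psinter_feasibility_error")
  lapply(seq_len(spec$n_repeats), function(r) {
    one_split(data, spec, repeat_id = r,
              seed = derive_seed("split", spec$seed, spec$scenario, r))
  })
}

# split n items into three groups of sizes as close as possible to
# fractions, every group non-empty when n >= 3
three_way_sizes <- function(n, fractions) {
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  n_train <- min(n_train, n - 2L)
  n_val <- max(1L, min(n_val, n - n_train - 1L))
  c(n_train, n_val, n - n_train - n_val)
}

partition_entities <- function(entities, fractions) {
  n <- length(entities)
  sizes <- three_way_sizes(n, fractions)
  shuffled <- sample(entities)
  list(train = shuffled[seq_len(sizes[1])],
       val = shuffled[sizes[1] + seq_len(sizes[2])],
       test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

one_split <- function(data, spec, repeat_id, seed) {
  n <- nrow(data)
  discarded <- integer()
  with_seed(seed, {
    if (spec$scenario == "random") {
      sizes <- three_way_sizes(n, spec$fractions)
      shuffled <- sample.int(n)
      train <- shuffled[seq_len(sizes[1])]
      val <- shuffled[sizes[1] + seq_len(sizes[2])]
      test <- shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])]
    } else if (spec$scenario == "cold_target") {
      parts <- partition_entities(unique(data$protein_id), spec$fractions)
      train <- which(data$protein_id %in% parts$train)
      val <- which(data$protein_id %in% parts$val)
      test <- which(data$protein_id %in% parts$test)
    } else if (spec$scenario == "cold_drug") {
      parts <- partition_entities(unique(data$smiles), spec$fractions)
      train <- which(data$smiles %in% parts$train)
      val <- which(data$smiles %in% parts$val)
      test <- which(data$smiles %in% parts$test)
    } else if (spec$scenario == "cold_both") {
      pp <- partition_entities(unique(data$protein_id), spec$fractions)
      mp <- partition_entities(unique(data$smiles), spec$fractions)
      part_of <- function(x, parts)
        ifelse(x %in% parts$train, "train",
               ifelse(x %in% parts$val, "val", "test"))
      ppart <- part_of(data$protein_id, pp)
      mpart <- part_of(data$smiles, mp)
      agree <- ppart == mpart
      train <- which(agree & ppart == "train")
      val <- which(agree & ppart == "val")
      test <- which(agree & ppart == "test")
      discarded <- which(!agree)
    } else { # same_pair_excluded
      pair_key <- paste(data$protein_id, data$smiles, sep = "\r")
      parts <- partition_entities(unique(pair_key), spec$fractions)
      train <- which(pair_key %in% parts$train)
      val <- which(pair_key %in% parts$val)
      test <- which(pair_key %in% parts$test)
    }
  })
  if (!length(train) || !length(val) || !length(test))
    ps_abort(sprintf("scenario '%s' produced an empty part (repeat %d)",
                     spec$scenario, repeat_id), "psinter_feasibility_error")
  manifest <- list(
    scenario = spec$scenario, repeat_id = repeat_id, seed = seed,
    sizes = c(train = length(train), val = length(val), test = length(test)),
    n_discarded = length(discarded),
    protein_overlap = length(intersect(data$protein_id[train],
                                       data$protein_id[c(val, test)])),
    molecule_overlap = length(intersect(data$smiles[train],
                                        data$smiles[c(val, test)])))
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 discarded = sort(discarded), manifest = manifest),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<split_result> %s (repeat %d): train %d / val %d / test %d%s\n",
    m$scenario, m$repeat_id, m$sizes[1], m$sizes[2], m$sizes[3],
    if (m$n_discarded) sprintf(" (%d discarded)", m$n_discarded) else ""))
  invisible(x)
}

#' Split controlling the training-set occurrence count of test drugs
#'
#' Builds a split in which each of `n_test_drugs` randomly selected
#' molecules occurs exactly `k` times in the training set (each time
#' paired with a distinct protein) and at least once in the test set;
#' records of a selected molecule beyond those allocations are discarded.
#' Records of non-selected molecules are split randomly by `fractions`.
#'
#' @param data an [interaction_dataset()].
#' @param k training occurrence count for each selected molecule
#'   (typically 1, 3, 10, 30, or 100).
#' @param n_test_drugs number of molecules to select.
#' @param seed integer seed.
#' @param fractions train/val/test fractions for the non-selected records.
#' @return a `split_result`; the manifest lists the selected molecules.
#' @export
occurrence_controlled_split <- function(data, k, n_test_drugs = 15L, seed = 1L,
                                        fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(data, "interaction_dataset"))
  k <- as.integer(k)
  counts <- table(data$smiles)
  # a molecule needs k train records with distinct proteins plus >= 1 test
  distinct_prot <- tapply(data$protein_id, data$smiles,
                          function(p) length(unique(p)))
  eligible <- names(counts)[counts > k & distinct_prot[names(counts)] >= k]
  if (length(eligible) < n_test_drugs)
    ps_abort(sprintf(
      "only %d molecule(s) have > %d records with >= %d distinct proteins (need %d)",
      length(eligible), k, k, n_test_drugs),
      "psinter_feasibility_error", shortfall = n_test_drugs - length(eligible))
  with_seed(derive_seed("occ_split", seed, k), {
    selected <- sample(eligible, n_test_drugs)
    train <- integer(); test <- integer(); val <- integer()
    discarded <- integer()
    for (mol in selected) {
      idx <- which(data$smiles == mol)
      idx <- sample(idx)
      # pick k records with pairwise distinct proteins for training
      keep <- idx[!duplicated(data$protein_id[idx])][seq_len(k)]
      rest <- setdiff(idx, keep)
      train <- c(train, keep)
      test <- c(test, rest[1])
      discarded <- c(discarded, rest[-1])
    }
    other <- setdiff(seq_len(nrow(data)), which(data$smiles %in% selected))
    sizes <- three_way_sizes(length(other), fractions)
    shuffled <- sample(other)
    train <- c(train, shuffled[seq_len(sizes[1])])
    val <- shuffled[sizes[1] + seq_len(sizes[2])]
    test <- c(test, shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
  })
  manifest <- list(scenario = "occurrence_controlled", k = k, seed = seed,
                   selected_molecules = selected,
                   sizes = c(train = length(train), val = length(val),
                             test = length(test)),
                   n_discarded = length(discarded))
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 discarded = sort(discarded), manifest = manifest),
            class = "split_result")
}

#' Per-subset metrics stratified by a record-level key
#'
#' Bins test records by a stratification value (training occurrence
#' count, maximum sequence identity to the training set, or maximum
#' molecule similarity to the training set - any numeric key) and
#' computes one metric per bin. Bins are left-closed, right-open over
#' `bin_edges`; empty bins are reported with count 0 and `NA` metric.
#'
#' @param values numeric stratification value per test record.
#' @param y,yhat observed values and predictions, aligned with `values`.
#' @param bin_edges increasing numeric vector of bin boundaries; values
#'   outside `[min, max)` fall into no bin and are dropped with a warning.
#' @param metric metric name: one of `"mse"`, `"r_squared"`,
#'   `"pearson_r"`, `"concordance_index"`, `"rm_squared"`, `"accuracy"`,
#'   `"mcc"`, `"roc_auc"`.
#' @return data frame with one row per bin: `bin` label, `lower`,
#'   `upper`, `count`, `value`.
#' @export
stratified_metrics <- function(values, y, yhat, bin_edges, metric = "mse") {
  metric_funs <- list(
    mse = function(y, p) mean((y - p)^2),
    r_squared = function(y, p) regression_metrics(y, p)$r_squared,
    pearson_r = function(y, p) regression_metrics(y, p)$pearson_r,
    concordance_index = concordance_index,
    rm_squared = function(y, p) rm_squared(y, p)$rm_squared,
    accuracy = function(y, p) binary_metrics(y, p)$accuracy,
    mcc = function(y, p) binary_metrics(y, p)$mcc,
    roc_auc = function(y, p) binary_metrics(y, p)$roc_auc)
  if (!metric %in% names(metric_funs))
    ps_abort(sprintf("unknown metric key '%s'", metric), "psinter_key_error")
  if (length(values) != length(y) || length(y) != length(yhat))
    ps_abort("values, y and yhat must align", "psinter_shape_error")
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    ps_abort("bin_edges must be strictly increasing", "psinter_value_error")
  bin <- cut(values, breaks = bin_edges, right = FALSE,
             include.lowest = FALSE)
  if (anyNA(bin))
    ps_warn(sprintf("%d record(s) outside the bin range dropped", sum(is.na(bin))),
            "psinter_bin_drop")
  f <- metric_funs[[metric]]
  out <- data.frame(bin = levels(bin),
                    lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1],
                    count = as.integer(table(bin)),
                    value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sel <- which(as.integer(bin) == i)
    if (length(sel))
      out$value[i] <- tryCatch(f(y[sel], yhat[sel]),
                               psinter_error = function(e) NA_real_)
  }
  out
}
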