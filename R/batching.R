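#' Plan chunk-wise iteration over protein-molecule pairs
#'
#' Training on large datasets cannot keep every protein and molecule
#' embedding in memory. Proteins and molecules are therefore grouped into
#' chunks of `chunk_size` (in the order the ids are given, matching the
#' chunk layout of [store_chunks()]), and one epoch iterates over all
#' (protein chunk, molecule chunk) blocks, visiting each pair exactly once
#' - in the unique block that holds both its protein's and its molecule's
#' chunk.
#'
#' @param protein_ids unique protein keys, in store order.
#' @param molecule_ids unique molecule keys, in store order.
#' @param pairs data frame with columns `protein_id` and `smiles`
#'   referencing those keys (one row per record).
#' @param chunk_size chunk size used for both modalities.
#' @return a `batch_plan`: list of blocks, each a list with
#'   `protein_chunk`, `molecule_chunk`, and `pair_idx` (row indices into
#'   `pairs`). Empty blocks are retained with zero indices.
#' @export
plan_subset_batches <- function(protein_ids, molecule_ids, pairs,
                                chunk_size = 1000L) {
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L)
    ps_abort("chunk_size must be >= 1", "psinter_value_error")
  pi <- match(pairs$protein_id, protein_ids)
  mi <- match(pairs$smiles, molecule_ids)
  if (anyNA(pi))
    ps_abort(sprintf("pair references unknown protein id '%s'",
                     pairs$protein_id[which(is.na(pi))[1]]),
             "psinter_plan_error")
  if (anyNA(mi))
    ps_abort(sprintf("pair references unknown molecule '%s'",
                     pairs$smiles[which(is.na(mi))[1]]),
             "psinter_plan_error")
  pc <- ceiling(pi / chunk_size)
  mc <- ceiling(mi / chunk_size)
  n_pc <- ceiling(length(protein_ids) / chunk_size)
  n_mc <- ceiling(length(molecule_ids) / chunk_size)
  blocks <- vector("list", n_pc * n_mc)
  b <- 0L
  for (i in seq_len(n_pc)) {
    for (j in seq_len(n_mc)) {
      b <- b + 1L
      blocks[[b]] <- list(protein_chunk = i, molecule_chunk = j,
                          pair_idx = which(pc == i & mc == j))
    }
  }
  structure(blocks, class = "batch_plan", chunk_size = chunk_size,
            n_pairs = nrow(pairs))
}

# Block plan aligned with the actual chunk layout of a pair of stores
# (chunk ids taken from the store indexes, not recomputed).
plan_from_stores <- function(stores, data) {
  pc <- store_chunk_of(stores$protein, data$protein_id)
  mc <- store_chunk_of(stores$molecule, data$smiles)
  blocks <- list()
  for (i in sort(unique(pc))) {
    for (j in sort(unique(mc))) {
      idx <- which(pc == i & mc == j)
      if (length(idx))
        blocks[[length(blocks) + 1L]] <-
          list(protein_chunk = i, molecule_chunk = j, pair_idx = idx)
    }
  }
  structure(blocks, class = "batch_plan", chunk_size = NA_integer_,
            n_pairs = nrow(data))
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("<batch_plan> %d block(s) covering %d pair(s), chunk_size = %d\n",
              length(x), attr(x, "n_pairs"), attr(x, "chunk_size")))
  invisible(x)
}
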