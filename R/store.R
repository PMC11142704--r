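# Chunked on-disk store for keyed embedding matrices.
#
# Matrices are grouped into chunks of `chunk_size` keys; each chunk is one
# serialized file next to a plain-text index. Sequential chunk-wise
# iteration keeps at most one chunk in memory, which is what makes training
# on datasets larger than RAM possible. Round trips are bit-identical.

#' Write keyed matrices into a chunked store
#'
#' @param matrices named list of numeric matrices; names are the record
#'   keys (e.g. protein ids or SMILES strings).
#' @param path directory to create the store in.
#' @param chunk_size number of keys per chunk.
#' @return an `embedding_store` handle.
#' @export
store_chunks <- function(matrices, path, chunk_size = 1000L) {
  keys <- names(matrices)
  if (is.null(keys) || any(!nzchar(keys)))
    ps_abort("matrices must be a named list", "psinter_value_error")
  if (anyDuplicated(keys))
    ps_abort("store keys must be unique", "psinter_value_error")
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L)
    ps_abort("chunk_size must be >= 1", "psinter_value_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(matrices)
  chunk_of <- ceiling(seq_len(n) / chunk_size)
  for (cid in unique(chunk_of)) {
    saveRDS(matrices[chunk_of == cid],
            file.path(path, sprintf("chunk_%05d.rds", cid)))
  }
  index <- data.frame(key = keys, chunk = chunk_of, stringsAsFactors = FALSE)
  utils::write.table(index, file.path(path, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  open_store(path)
}

#' Open an existing chunked store
#'
#' @param path store directory created by [store_chunks()].
#' @return an `embedding_store` handle.
#' @export
open_store <- function(path) {
  idx_path <- file.path(path, "index.tsv")
  if (!file.exists(idx_path))
    ps_abort(sprintf("no store index at %s", path), "psinter_io_error")
  index <- utils::read.delim(idx_path, stringsAsFactors = FALSE,
                             colClasses = c("character", "integer"))
  structure(list(path = path, index = index,
                 cache = new.env(parent = emptyenv())),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d keys in %d chunk(s) at %s\n",
              nrow(x$index), length(unique(x$index$chunk)), x$path))
  invisible(x)
}

#' Store accessors
#'
#' `store_keys` lists all keys; `store_n_chunks` the number of chunks;
#' `store_read` fetches one matrix by key; `store_read_chunk` loads a whole
#' chunk (a named list of matrices). Reads cache only the most recently
#' used chunk.
#'
#' @param store an `embedding_store`.
#' @param key a record key.
#' @param chunk a chunk id (1-based).
#' @return see individual descriptions.
#' @export
store_keys <- function(store) store$index$key

#' @rdname store_keys
#' @export
store_n_chunks <- function(store) length(unique(store$index$chunk))

#' @rdname store_keys
#' @export
store_read_chunk <- function(store, chunk) {
  if (!chunk %in% store$index$chunk)
    ps_abort(sprintf("no chunk %s in store", chunk), "psinter_not_found_error")
  if (!identical(store$cache$chunk_id, chunk)) {
    store$cache$chunk_id <- chunk
    store$cache$data <- readRDS(file.path(store$path,
                                          sprintf("chunk_%05d.rds", chunk)))
  }
  store$cache$data
}

#' @rdname store_keys
#' @export
store_read <- function(store, key) {
  i <- match(key, store$index$key)
  if (is.na(i))
    ps_abort(sprintf("key '%s' not found in store", key),
             "psinter_not_found_error", key = key)
  store_read_chunk(store, store$index$chunk[[i]])[[key]]
}

#' Chunk id for each of a set of keys
#' @rdname store_keys
#' @param keys character vector of keys.
#' @export
store_chunk_of <- function(store, keys) {
  i <- match(keys, store$index$key)
  if (anyNA(i))
    ps_abort(sprintf("key '%s' not found in store", keys[which(is.na(i))[1]]),
             "psinter_not_found_error")
  store$index$chunk[i]
}

#' Embed every protein and molecule of a dataset into chunked stores
#'
#' Computes per-token embedding matrices for each unique protein (keyed by
#' `protein_id`) and each unique molecule (keyed by SMILES string) and
#' persists them in two chunked stores under `dir`.
#'
#' @param provider an embedding provider.
#' @param ds an [interaction_dataset()].
#' @param dir directory for the stores (subdirectories `protein/` and
#'   `molecule/` are created).
#' @param chunk_size keys per chunk.
#' @return list with elements `protein` and `molecule` (two
#'   `embedding_store` handles) and `provider_info`.
#' @export
embed_dataset <- function(provider, ds, dir = tempfile("psinter_store_"),
                          chunk_size = 1000L) {
  stopifnot(inherits(ds, "interaction_dataset"))
  prot <- !duplicated(ds$protein_id)
  prot_mats <- lapply(seq_len(nrow(ds))[prot],
                      function(i) embed_sequence(provider, ds$sequence[[i]]))
  names(prot_mats) <- ds$protein_id[prot]
  mol_smiles <- unique(ds$smiles)
  mol_mats <- lapply(mol_smiles, function(s) embed_smiles(provider, s))
  names(mol_mats) <- mol_smiles
  stores <- list(
    protein = store_chunks(prot_mats, file.path(dir, "protein"), chunk_size),
    molecule = store_chunks(mol_mats, file.path(dir, "molecule"), chunk_size),
    provider_info = list(name = provider$name, version = provider$version,
                         d_p = provider$spec$d_p, d_s = provider$spec$d_s))
  stores
}
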