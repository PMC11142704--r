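#' Embedding dimensions and length limits
#'
#' Defaults mirror the upstream language models the framework was designed
#' around: 1280-dimensional per-residue protein embeddings, 600-dimensional
#' SMILES token embeddings, at most 1024 protein tokens and 256 SMILES
#' tokens (longer inputs are truncated to their first tokens).
#'
#' @param d_p protein token embedding width.
#' @param d_s SMILES token embedding width.
#' @param max_protein_tokens,max_smiles_tokens truncation limits.
#' @return an `embedding_spec` list.
#' @export
embedding_spec <- function(d_p = 1280L, d_s = 600L,
                           max_protein_tokens = 1024L,
                           max_smiles_tokens = 256L) {
  for (v in c(d_p, d_s, max_protein_tokens, max_smiles_tokens))
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      ps_abort("embedding_spec fields must be positive integers",
               "psinter_value_error")
  structure(list(d_p = as.integer(d_p), d_s = as.integer(d_s),
                 max_protein_tokens = as.integer(max_protein_tokens),
                 max_smiles_tokens = as.integer(max_smiles_tokens)),
            class = "embedding_spec")
}

#' Deterministic synthetic embedding provider
#'
#' A self-contained provider of per-token embeddings, usable wherever a
#' pretrained protein/chemical language model adapter would be plugged in.
#' Each token's embedding is a fixed pseudo-random unit-variance vector
#' derived from a hash of (modality, token, seed), with a leading
#' deterministic "signal block": one indicator dimension per configured
#' signal token. Planted signals built from those tokens are therefore
#' linearly decodable from the embeddings, so learning tests can
#' distinguish "the model cannot learn" from "there is nothing to learn".
#'
#' Proteins are tokenized as overlapping k-mers by this provider (default
#' k = 3) so that short sequence motifs are visible at the token level;
#' adapters for per-residue language models use `protein_scheme =
#' "residue"`. Upstream begin/end special tokens are not included in the
#' per-token matrices (recorded in the provider metadata).
#'
#' @param spec an [embedding_spec()].
#' @param seed integer seed; embeddings depend only on
#'   (modality, token, seed).
#' @param signal_tokens list with character vectors `protein` and
#'   `molecule`: the tokens that receive indicator dimensions.
#' @param protein_scheme protein tokenization scheme, `"kmer"` or
#'   `"residue"`.
#' @param k k-mer width when `protein_scheme = "kmer"`.
#' @param vocabulary optional named list of allowed tokens per modality;
#'   when supplied the provider is strict and errors on unknown tokens.
#' @return an object of class `embedding_provider`.
#' @export
synthetic_embedding_provider <- function(spec = embedding_spec(),
                                         seed = 1L,
                                         signal_tokens = list(
                                           protein = character(),
                                           molecule = character()),
                                         protein_scheme = c("kmer", "residue"),
                                         k = 3L,
                                         vocabulary = NULL) {
  protein_scheme <- match.arg(protein_scheme)
  stopifnot(inherits(spec, "embedding_spec"))
  n_sig_p <- length(signal_tokens$protein %||% character())
  n_sig_m <- length(signal_tokens$molecule %||% character())
  if (n_sig_p >= spec$d_p || n_sig_m >= spec$d_s)
    ps_abort("embedding width must exceed the number of signal tokens",
             "psinter_value_error")
  structure(list(
    name = "synthetic-hash",
    version = "1.0",
    modalities = c("protein", "molecule"),
    spec = spec,
    seed = as.integer(seed),
    signal_tokens = list(protein = signal_tokens$protein %||% character(),
                         molecule = signal_tokens$molecule %||% character()),
    protein_scheme = protein_scheme,
    k = as.integer(k),
    vocabulary = vocabulary,
    special_tokens_included = FALSE,
    cache = new.env(parent = emptyenv())
  ), class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider> %s v%s  (d_p = %d, d_s = %d, seed = %d)\n",
              x$name, x$version, x$spec$d_p, x$spec$d_s, x$seed))
  invisible(x)
}

provider_width <- function(provider, modality) {
  switch(modality, protein = provider$spec$d_p, molecule = provider$spec$d_s,
         ps_abort(sprintf("unknown modality '%s'", modality),
                  "psinter_value_error"))
}

#' Embed a token list into a per-token embedding matrix
#'
#' @param provider an embedding provider.
#' @param tokens character vector of tokens (already truncated to the
#'   spec's maximum by the tokenizers).
#' @param modality `"protein"` or `"molecule"`.
#' @return a `token_embedding_matrix`: numeric matrix with one row per
#'   token (rownames are the tokens) and width given by the provider spec.
#' @export
embed_tokens <- function(provider, tokens, modality = c("protein", "molecule")) {
  modality <- match.arg(modality)
  if (!modality %in% provider$modalities)
    ps_abort(sprintf("provider '%s' does not support modality '%s'",
                     provider$name, modality), "psinter_value_error")
  if (!length(tokens))
    ps_abort("cannot embed an empty token list", "psinter_value_error")
  limit <- switch(modality, protein = provider$spec$max_protein_tokens,
                  molecule = provider$spec$max_smiles_tokens)
  tokens <- utils::head(tokens, limit)
  if (!is.null(provider$vocabulary)) {
    unknown <- setdiff(tokens, provider$vocabulary[[modality]])
    if (length(unknown))
      ps_abort(sprintf("unknown %s token '%s' for strict provider",
                       modality, unknown[[1]]),
               "psinter_embedding_error", token = unknown[[1]])
  }
  d <- provider_width(provider, modality)
  m <- matrix(0, nrow = length(tokens), ncol = d)
  uniq <- unique(tokens)
  rows <- vapply(uniq, function(tok) synthetic_token_vector(provider, tok, modality),
                 numeric(d))
  m[] <- t(rows)[match(tokens, uniq), , drop = FALSE]
  rownames(m) <- tokens
  if (!all(is.finite(m)))
    ps_abort("non-finite embedding values", "psinter_numeric_error")
  structure(m, modality = modality, class = c("token_embedding_matrix", "matrix", "array"))
}

synthetic_token_vector <- function(provider, token, modality) {
  key <- paste(modality, token, sep = "\r")
  hit <- provider$cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- provider_width(provider, modality)
  sig <- provider$signal_tokens[[modality]]
  M <- length(sig)
  v <- with_seed(derive_seed("psinter-token", provider$seed, modality, token),
                 stats::rnorm(d - M))
  out <- c(as.numeric(token == sig), v)
  provider$cache[[key]] <- out
  out
}

#' Embed a protein sequence or a SMILES string
#'
#' Tokenizes with the provider's scheme (and the spec's truncation limits)
#' and embeds the tokens.
#'
#' @param provider an embedding provider.
#' @param x a protein sequence (for `embed_sequence`) or SMILES string
#'   (for `embed_smiles`).
#' @return a `token_embedding_matrix`.
#' @export
embed_sequence <- function(provider, x) {
  tokens <- tokenize_protein(x, provider$spec, scheme = provider$protein_scheme,
                             k = provider$k)
  embed_tokens(provider, tokens, "protein")
}

#' @rdname embed_sequence
#' @export
embed_smiles <- function(provider, x) {
  tokens <- tokenize_smiles(x, provider$spec)
  embed_tokens(provider, tokens, "molecule")
}

#' Mean-pool a token embedding matrix
#'
#' The element-wise mean across token embeddings: one vector summarizing a
#' protein (width `d_p`) or a molecule (width `d_s`).
#'
#' @param m a `token_embedding_matrix`.
#' @return numeric vector with attribute `modality`.
#' @export
mean_pool <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L)
    ps_abort("cannot mean-pool an empty matrix", "psinter_value_error")
  structure(colMeans(m), modality = attr(m, "modality"))
}
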