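#' Extended-connectivity fingerprint (1024-bit)
#'
#' Computes a radius-2 circular (extended-connectivity) fingerprint for a
#' molecule and folds it to a 1024-length binary vector (bitwise OR over
#' congruent positions). Folding preserves determinism: the same SMILES
#' always yields the same bits.
#'
#' @param smiles a single SMILES string.
#' @param nbits fingerprint length after folding.
#' @return an object of class `ecfp_fingerprint`: integer 0/1 vector of
#'   length `nbits` with attribute `source_smiles`.
#' @export
ecfp_fingerprint <- function(smiles, nbits = 1024L) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    ps_abort("`smiles` must be a single non-empty string", "psinter_value_error")
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "ECFP4")),
    error = function(e)
      ps_abort(sprintf("SMILES string '%s' could not be parsed", smiles),
               "psinter_parse_error", smiles = smiles))
  raw <- as.numeric(raw)
  if (!length(raw) || sum(raw) == 0)
    ps_abort(sprintf("SMILES string '%s' produced an empty fingerprint", smiles),
             "psinter_parse_error", smiles = smiles)
  idx <- (which(raw != 0) - 1L) %% nbits + 1L
  bits <- integer(nbits)
  bits[idx] <- 1L
  structure(bits, source_smiles = smiles, class = "ecfp_fingerprint")
}

#' Jaccard similarity between two fingerprints
#'
#' `1 - Jaccard distance`: the fraction of matching positions among all
#' positions where at least one fingerprint has a set bit, i.e.
#' `|intersection| / |union|` of the bit sets.
#'
#' @param a,b binary fingerprint vectors of equal length, each with at
#'   least one set bit.
#' @param rescale optional `function(x)` applied to the similarity (the
#'   raw score already lies in `[0, 1]`, so the default is the identity);
#'   provided for exact-replication workflows that post-scale scores.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b, rescale = identity) {
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  if (length(a) != length(b))
    ps_abort("fingerprints must have equal length", "psinter_shape_error")
  union <- sum(a | b)
  if (union == 0)
    ps_abort("Jaccard similarity undefined for two all-zero fingerprints",
             "psinter_metric_undefined")
  rescale(sum(a & b) / union)
}

#' Maximum similarity of a query molecule to a reference set
#'
#' Used to stratify test molecules by how structurally close they are to
#' the training set.
#'
#' @param query a fingerprint (see [ecfp_fingerprint()]).
#' @param reference a list of fingerprints.
#' @return the maximum pairwise [jaccard_similarity()].
#' @export
max_similarity_to_set <- function(query, reference) {
  if (!length(reference))
    ps_abort("reference fingerprint set is empty", "psinter_value_error")
  max(vapply(reference, function(r) jaccard_similarity(query, r), numeric(1)))
}

#' Global-alignment sequence identity (percent)
#'
#' Percent identity between two amino-acid sequences under global
#' (Needleman-Wunsch) alignment with match +1, mismatch 0, and a linear
#' gap cost of -1 per gap position, computed as
#' `matches / alignment length * 100`.
#' The scoring scheme is fixed so that results are deterministic and
#' tool-independent; it is symmetric in its arguments.
#'
#' @param a,b amino-acid strings.
#' @return identity percentage in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b))
    ps_abort("sequences must be non-empty", "psinter_value_error")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = identity_substitution_matrix(),
    gapOpening = 0, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / alen
}

identity_substitution_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c(AA_ALPHABET20, "X", "B", "J", "O", "U", "Z")
      m <- diag(1, length(letters))
      dimnames(m) <- list(letters, letters)
      cache <<- m
    }
    cache
  }
})

#' Pairwise similarity matrix for a set of molecules
#'
#' @param smiles character vector of SMILES strings.
#' @return symmetric matrix of Jaccard similarities with `smiles` as
#'   dimnames.
#' @export
similarity_matrix <- function(smiles) {
  fps <- lapply(smiles, ecfp_fingerprint)
  n <- length(fps)
  out <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- jaccard_similarity(fps[[i]], fps[[j]])
    }
  }
  dimnames(out) <- list(smiles, smiles)
  out
}
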