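# The standard SMILES regex tokenizer: bracket atoms are atomic units,
# two-letter elements (Cl, Br) are kept together, ring-closure digits,
# branches, bonds and stereo marks are single tokens.
SMILES_TOKEN_REGEX <- paste0(
  "(\\[[^\\]]+\\]",              # bracket atoms, e.g. [NH4+], [C@@H]
  "|Br|Cl",                      # two-letter organic-subset elements
  "|[BCNOSPFI]",                 # one-letter organic-subset elements
  "|[bcnops]",                   # aromatic atoms
  "|%[0-9]{2}",                  # two-digit ring closures
  "|[0-9]",                      # ring closures
  "|[=#\\-\\+\\(\\)/\\\\\\.:~@\\*\\$])" # bonds, branches, stereo, misc
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens using the
#' published SMILES regular expression (bracket atoms as single tokens,
#' `Cl`/`Br` kept together, ring digits, bonds and branches as single
#' characters). Strings longer than `spec$max_smiles_tokens` are truncated
#' to the first `max_smiles_tokens` tokens.
#'
#' @param smiles a single SMILES string.
#' @param spec an [embedding_spec()]; only `max_smiles_tokens` is used.
#' @return character vector of tokens whose concatenation is a prefix of
#'   the input.
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("[NH4+]")
#' @export
tokenize_smiles <- function(smiles, spec = embedding_spec()) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    ps_abort("`smiles` must be a single non-empty string",
             "psinter_tokenize_error")
  m <- gregexpr(SMILES_TOKEN_REGEX, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L)
    ps_abort(sprintf("SMILES string '%s' yields no tokens", smiles),
             "psinter_tokenize_error")
  tokens <- regmatches(smiles, list(m))[[1]]
  if (!identical(paste(tokens, collapse = ""), smiles))
    ps_abort(sprintf("SMILES string '%s' contains untokenizable characters",
                     smiles), "psinter_tokenize_error")
  utils::head(tokens, spec$max_smiles_tokens)
}

#' Tokenize a protein sequence
#'
#' Residue-level tokenization (`scheme = "residue"`, one token per amino
#' acid, as protein language models use) or overlapping k-mer tokenization
#' (`scheme = "kmer"`, used by the synthetic provider so that short sequence
#' motifs are visible to token-level models). Sequences are truncated to
#' the first `spec$max_protein_tokens` tokens.
#'
#' @param sequence a single amino-acid string.
#' @param spec an [embedding_spec()].
#' @param scheme `"residue"` or `"kmer"`.
#' @param k k-mer width for `scheme = "kmer"`.
#' @return character vector of tokens.
#' @export
tokenize_protein <- function(sequence, spec = embedding_spec(),
                             scheme = c("residue", "kmer"), k = 3L) {
  scheme <- match.arg(scheme)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    ps_abort("`sequence` must be a single non-empty string",
             "psinter_tokenize_error")
  tokens <- if (scheme == "residue") {
    strsplit(sequence, "")[[1]]
  } else {
    n <- nchar(sequence)
    if (n < k) sequence
    else substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }
  utils::head(tokens, spec$max_protein_tokens)
}
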