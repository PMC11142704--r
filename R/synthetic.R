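#' Configuration of the synthetic interaction-data generator
#'
#' The generator plants a recoverable protein-by-molecule interaction
#' signal: a fixed list of protein 3-mer motifs and SMILES fragment
#' tokens, with one weight per (motif, fragment) factor. A pair's latent
#' score is `effect_size * sum_m w_m * count(motif_m, sequence) *
#' has(fragment_m, smiles)`. Protein sequences are uniform random over
#' the 20-letter alphabet with motif occurrences implanted at
#' Poisson(`motif_rate`) counts (uniform sequences alone essentially
#' never contain a given 3-mer, which would leave no signal variance).
#' Molecules are drawn from the bundled library of small valid SMILES.
#'
#' Defaults emulate desk-scale versions of the benchmark datasets:
#' continuous labels with Gaussian noise for affinity-style regression,
#' or binary labels thresholded at a positive fraction of 0.25 (the
#' 1-to-3 positive-to-negative ratio used in enzyme-substrate data).
#'
#' @param n_proteins,n_molecules,n_pairs dataset dimensions
#'   (`n_pairs <= n_proteins * n_molecules`; pairs are sampled without
#'   replacement).
#' @param task `"regression"` or `"binary_classification"`.
#' @param effect_size multiplier on the planted score.
#' @param noise_sd standard deviation of the additive Gaussian label
#'   noise (regression).
#' @param positive_fraction target fraction of positive labels
#'   (classification).
#' @param protein_length_range sequence length range (uniform).
#' @param motifs character vector of protein 3-mers.
#' @param fragments character vector of SMILES tokens, one per motif.
#' @param weights numeric factor weights, one per motif.
#' @param motif_rate Poisson mean of implanted occurrences per
#'   (protein, motif).
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 60L, n_molecules = 60L,
                             n_pairs = 1500L,
                             task = c("regression", "binary_classification"),
                             effect_size = 1, noise_sd = 0.5,
                             positive_fraction = 0.25,
                             protein_length_range = c(30L, 50L),
                             motifs = c("ACD", "GHK", "LMN", "PQR"),
                             fragments = c("N", "O", "S", "Cl"),
                             weights = c(1, -1, 0.75, -0.5),
                             motif_rate = 1, seed = 1L) {
  task <- match.arg(task)
  if (length(motifs) != length(fragments) ||
      length(motifs) != length(weights))
    ps_abort("motifs, fragments and weights must have equal length",
             "psinter_value_error")
  if (n_pairs > n_proteins * n_molecules)
    ps_abort("n_pairs cannot exceed n_proteins * n_molecules",
             "psinter_value_error")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    ps_abort("positive_fraction must be in (0, 1)", "psinter_value_error")
  if (effect_size < 0 || noise_sd < 0)
    ps_abort("effect_size and noise_sd must be >= 0", "psinter_value_error")
  structure(list(
    n_proteins = as.integer(n_proteins), n_molecules = as.integer(n_molecules),
    n_pairs = as.integer(n_pairs), task = task, effect_size = effect_size,
    noise_sd = noise_sd, positive_fraction = positive_fraction,
    protein_length_range = as.integer(protein_length_range),
    motifs = motifs, fragments = fragments, weights = weights,
    motif_rate = motif_rate, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' The bundled small-molecule library
#'
#' ~220 small, chemically valid SMILES strings spanning the fragment
#' vocabulary of the synthetic generator.
#'
#' @return character vector of SMILES strings.
#' @export
smiles_library <- function() {
  path <- system.file("extdata", "smiles_library.tsv", package = "psinter")
  utils::read.delim(path, stringsAsFactors = FALSE)$smiles
}

count_motif <- function(sequence, motif) {
  # overlapping occurrences
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Latent interaction score of one (protein, molecule) pair
#'
#' `effect_size * sum_m weights[m] * count(motif_m in sequence) *
#' has(fragment_m among the molecule's tokens)`. This is the generative
#' ground truth that labels are derived from.
#'
#' @param sequence amino-acid string.
#' @param smiles SMILES string.
#' @param cfg a [synthetic_config()].
#' @return numeric score.
#' @export
planted_score <- function(sequence, smiles, cfg) {
  tokens <- tokenize_smiles(smiles)
  f <- vapply(cfg$motifs, function(m) count_motif(sequence, m), integer(1))
  g <- as.numeric(cfg$fragments %in% tokens)
  cfg$effect_size * sum(cfg$weights * f * g)
}

#' Signal tokens matching a synthetic configuration
#'
#' Convenience wiring for [synthetic_embedding_provider()]: the provider's
#' indicator dimensions are placed on exactly the motif and fragment
#' tokens that generate the planted signal.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `protein` and `molecule`.
#' @export
synthetic_signal_tokens <- function(cfg) {
  list(protein = cfg$motifs, molecule = cfg$fragments)
}

#' Generate a synthetic interaction dataset with planted signal
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (an [interaction_dataset()]) and
#'   `manifest`: a data frame of per-record latent quantities (score and
#'   per-factor motif counts / fragment indicators) plus attributes
#'   `protein_motif_counts`, `molecule_fragments`, and (classification)
#'   `threshold`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  library_smiles <- smiles_library()
  if (cfg$n_molecules > length(library_smiles))
    ps_abort(sprintf("n_molecules exceeds the bundled library (%d)",
                     length(library_smiles)), "psinter_generation_error")
  M <- length(cfg$motifs)
  with_seed(derive_seed("synthetic", cfg$seed), {
    lens <- sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    sequences <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
      character(1))
    # implant motif occurrences (overwrite at random positions)
    for (i in seq_len(cfg$n_proteins)) {
      s <- sequences[i]
      for (m in seq_len(M)) {
        n_occ <- stats::rpois(1, cfg$motif_rate)
        if (n_occ > 0) {
          starts <- sample(seq_len(nchar(s) - nchar(cfg$motifs[m]) + 1L),
                           min(n_occ, 3L))
          for (st in starts)
            substr(s, st, st + nchar(cfg$motifs[m]) - 1L) <- cfg$motifs[m]
        }
      }
      sequences[i] <- s
    }
    protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
    mols <- sample(library_smiles, cfg$n_molecules)

    # per-entity factor values
    fmat <- vapply(sequences, function(s)
      vapply(cfg$motifs, function(m) count_motif(s, m), integer(1)),
      integer(M))
    fmat <- if (is.matrix(fmat)) t(fmat) else matrix(fmat, ncol = 1L)
    gmat <- vapply(mols, function(s)
      as.numeric(cfg$fragments %in% tokenize_smiles(s)), numeric(M))
    gmat <- if (is.matrix(gmat)) t(gmat) else matrix(gmat, ncol = 1L)

    # sample record pairs without replacement from the full grid
    pair_idx <- sample.int(cfg$n_proteins * cfg$n_molecules, cfg$n_pairs)
    pi <- ((pair_idx - 1L) %% cfg$n_proteins) + 1L
    mi <- ((pair_idx - 1L) %/% cfg$n_proteins) + 1L
    score_mat <- cfg$effect_size *
      (fmat * matrix(cfg$weights, nrow(fmat), M, byrow = TRUE)) %*% t(gmat)
    scores <- score_mat[cbind(pi, mi)]

    if (cfg$task == "regression") {
      labels <- scores + stats::rnorm(cfg$n_pairs, sd = cfg$noise_sd)
      label_kind <- "raw"
      threshold <- NA_real_
    } else {
      if (length(unique(scores)) < 2L)
        ps_abort(sprintf(
          "positive_fraction %.2f is unreachable: planted scores have no spread",
          cfg$positive_fraction), "psinter_generation_error")
      n_pos <- round(cfg$n_pairs * cfg$positive_fraction)
      threshold <- sort(scores, decreasing = TRUE)[n_pos]
      labels <- as.numeric(scores > threshold)
      # scores carry point masses (integer factor combinations); pairs
      # tied at the threshold are promoted at random up to the target
      ties <- which(scores == threshold)
      need <- n_pos - sum(labels)
      if (need > 0) labels[sample(ties, need)] <- 1
      label_kind <- "binary"
    }

    ds <- interaction_dataset(
      protein_id = protein_ids[pi], sequence = sequences[pi],
      smiles = mols[mi], label = labels, label_kind = label_kind,
      task = cfg$task)
    manifest <- data.frame(protein_id = protein_ids[pi], smiles = mols[mi],
                           score = scores, stringsAsFactors = FALSE)
    for (m in seq_len(M)) {
      manifest[[paste0("motif_count_", cfg$motifs[m])]] <- fmat[pi, m]
      manifest[[paste0("fragment_", cfg$fragments[m])]] <- gmat[mi, m]
    }
    rownames(fmat) <- protein_ids; colnames(fmat) <- cfg$motifs
    rownames(gmat) <- mols; colnames(gmat) <- cfg$fragments
    attr(manifest, "protein_motif_counts") <- fmat
    attr(manifest, "molecule_fragments") <- gmat
    attr(manifest, "threshold") <- threshold
    list(dataset = ds, manifest = manifest)
  })
}
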