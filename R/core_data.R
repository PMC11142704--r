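LABEL_KINDS <- c("pkd", "ic50", "binary", "log_km", "raw")

#' Construct an interaction dataset
#'
#' An interaction dataset holds one record per measured (protein, small
#' molecule) pair: the protein identifier and amino-acid sequence, the SMILES
#' string of the molecule, and a numeric label whose semantics are given by
#' `label_kind` (`pkd` for log-transformed dissociation constants, `ic50`,
#' `binary` for classification tasks, `log_km` for Michaelis constants on a
#' log scale, or `raw`).
#'
#' @param protein_id character vector of protein identifiers.
#' @param sequence amino-acid sequences (20-letter alphabet; letters such as
#'   X/B/U are accepted and passed through to embedding providers).
#' @param smiles SMILES strings.
#' @param label numeric labels; must be 0/1 when `label_kind = "binary"`.
#' @param label_kind one label kind shared by all records.
#' @param task `"regression"` or `"binary_classification"`; inferred from
#'   `label_kind` when missing.
#' @return An object of class `interaction_dataset`: a data frame with
#'   columns `protein_id`, `sequence`, `smiles`, `label` and attributes
#'   `label_kind` and `task`.
#' @examples
#' ds <- interaction_dataset(
#'   protein_id = c("P1", "P2"),
#'   sequence   = c("MKV", "MLA"),
#'   smiles     = c("CCO", "CO"),
#'   label      = c(7.2, 5.1),
#'   label_kind = "pkd")
#' nrow(ds)
#' @export
interaction_dataset <- function(protein_id, sequence, smiles, label,
                                label_kind = "raw", task = NULL) {
  label_kind <- match.arg(label_kind, LABEL_KINDS)
  n <- length(sequence)
  if (length(protein_id) != n || length(smiles) != n || length(label) != n)
    ps_abort("protein_id, sequence, smiles and label must have equal length",
             "psinter_value_error")
  if (is.null(task))
    task <- if (label_kind == "binary") "binary_classification" else "regression"
  task <- match.arg(task, c("regression", "binary_classification"))

  bad_seq <- which(!nzchar(sequence) | is.na(sequence))
  if (length(bad_seq))
    ps_abort(sprintf("empty amino-acid sequence in row(s) %s",
                     paste(utils::head(bad_seq, 5L), collapse = ", ")),
             "psinter_validation_error", rows = bad_seq)
  bad_smi <- which(!nzchar(smiles) | is.na(smiles))
  if (length(bad_smi))
    ps_abort(sprintf("empty SMILES string in row(s) %s",
                     paste(utils::head(bad_smi, 5L), collapse = ", ")),
             "psinter_validation_error", rows = bad_smi)
  if (!is.numeric(label) || anyNA(label))
    ps_abort("labels must be numeric and non-missing", "psinter_validation_error")
  if (task == "binary_classification" && label_kind != "binary")
    ps_abort("binary_classification requires label_kind = \"binary\"",
             "psinter_value_error")
  if (label_kind == "binary" && !all(label %in% c(0, 1)))
    ps_abort("binary labels must be 0 or 1", "psinter_validation_error")

  dup <- duplicated(paste(protein_id, smiles, sep = "\r"))
  if (any(dup))
    ps_warn(sprintf(
      "%d duplicate (protein, molecule) pair(s) kept as replicate measurements",
      sum(dup)), "psinter_duplicate_pairs")

  out <- data.frame(protein_id = as.character(protein_id),
                    sequence = as.character(sequence),
                    smiles = as.character(smiles),
                    label = as.numeric(label),
                    stringsAsFactors = FALSE)
  structure(out, label_kind = label_kind, task = task,
            class = c("interaction_dataset", "data.frame"))
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("<interaction_dataset> %d records, %d proteins, %d molecules\n",
              nrow(x), length(unique(x$protein_id)),
              length(unique(x$smiles))))
  cat(sprintf("  task: %s   label_kind: %s\n",
              attr(x, "task"), attr(x, "label_kind")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

# Subsetting keeps class + attributes (used pervasively by the splits module)
#' @export
`[.interaction_dataset` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label_kind = attr(x, "label_kind"), task = attr(x, "task"),
            class = c("interaction_dataset", "data.frame"))
}

#' Read an interaction table from a delimited file
#'
#' Reads a generic TSV/CSV of protein-small molecule interaction records.
#' Column names are mapped through `column_map`, so arbitrary headers can be
#' used. Sequences may alternatively live in a FASTA file joined by
#' `protein_id`.
#'
#' @param path path to the delimited file.
#' @param column_map named character vector mapping the canonical names
#'   (`protein_id`, `sequence`, `smiles`, `label`) to the file's column
#'   names. Defaults to identity. `sequence` may be omitted when `fasta`
#'   is supplied.
#' @param task `"regression"` or `"binary_classification"`.
#' @param label_kind label semantics (see [interaction_dataset()]); defaults
#'   to `"binary"` for classification and `"raw"` for regression.
#' @param delim field delimiter; guessed from the file extension by default
#'   (`","` for `.csv`, tab otherwise).
#' @param fasta optional FASTA file of protein sequences whose names are
#'   matched against `protein_id`.
#' @return An [interaction_dataset()] with one record per data row, in file
#'   order.
#' @export
read_interaction_table <- function(path, column_map = NULL,
                                   task = c("regression", "binary_classification"),
                                   label_kind = NULL, delim = NULL,
                                   fasta = NULL) {
  task <- match.arg(task)
  if (!file.exists(path))
    ps_abort(sprintf("file not found: %s", path), "psinter_io_error")
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)

  cmap <- c(protein_id = "protein_id", sequence = "sequence",
            smiles = "smiles", label = "label")
  if (!is.null(column_map)) cmap[names(column_map)] <- unname(column_map)

  need <- c("protein_id", "smiles", "label",
            if (is.null(fasta)) "sequence")
  for (canon in need) {
    if (!cmap[[canon]] %in% names(tab))
      ps_abort(sprintf("required column '%s' (mapped from '%s') is missing",
                       cmap[[canon]], canon),
               "psinter_schema_error", column = cmap[[canon]])
  }

  sequence <- if (!is.null(fasta)) {
    seqs <- read_fasta_sequences(fasta)
    ids <- as.character(tab[[cmap[["protein_id"]]]])
    missing <- setdiff(unique(ids), names(seqs))
    if (length(missing))
      ps_abort(sprintf("no FASTA sequence for protein id(s): %s",
                       paste(utils::head(missing, 5L), collapse = ", ")),
               "psinter_schema_error")
    unname(seqs[ids])
  } else {
    as.character(tab[[cmap[["sequence"]]]])
  }

  if (is.null(label_kind))
    label_kind <- if (task == "binary_classification") "binary" else "raw"

  ds <- interaction_dataset(
    protein_id = tab[[cmap[["protein_id"]]]],
    sequence = sequence,
    smiles = tab[[cmap[["smiles"]]]],
    label = tab[[cmap[["label"]]]],
    label_kind = label_kind, task = task)
  message(sprintf("read %d interaction records from %s", nrow(ds), path))
  ds
}

read_fasta_sequences <- function(path) {
  if (!file.exists(path))
    ps_abort(sprintf("FASTA file not found: %s", path), "psinter_io_error")
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an interaction dataset (or predictions) as TSV
#'
#' @param ds an [interaction_dataset()].
#' @param path output path.
#' @param predictions optional numeric vector of per-record predictions,
#'   written as an extra `prediction` column.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(ds, path, predictions = NULL) {
  stopifnot(inherits(ds, "interaction_dataset"))
  out <- as.data.frame(ds)
  if (!is.null(predictions)) {
    if (length(predictions) != nrow(out))
      ps_abort("predictions length must match the dataset",
               "psinter_value_error")
    out$prediction <- predictions
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert between affinity label scales
#'
#' The dissociation-constant transform used for drug-target affinity work:
#' `pKd = -log10(Kd / 1e9)` with `Kd` in nM, and its inverse. Michaelis
#' constants are handled analogously on the log10 scale (`log_km` from/to
#' `km_raw` values in the same unit the data were recorded in).
#'
#' @param value numeric vector of label values.
#' @param from_kind,to_kind one of `"kd_nM"`, `"pkd"`, `"km_raw"`,
#'   `"log_km"`.
#' @return transformed numeric vector.
#' @examples
#' transform_affinity(1, "kd_nM", "pkd")      # 9
#' transform_affinity(10000, "kd_nM", "pkd")  # 5
#' @export
transform_affinity <- function(value, from_kind, to_kind) {
  kinds <- c("kd_nM", "pkd", "km_raw", "log_km")
  from_kind <- match.arg(from_kind, kinds)
  to_kind <- match.arg(to_kind, kinds)
  if (from_kind == to_kind) return(value)
  key <- paste(from_kind, to_kind, sep = "->")
  switch(key,
    "kd_nM->pkd" = {
      if (any(value <= 0))
        ps_abort("Kd must be > 0 for the log transform", "psinter_domain_error")
      -log10(value / 1e9)
    },
    "pkd->kd_nM" = 1e9 * 10^(-value),
    "km_raw->log_km" = {
      if (any(value <= 0))
        ps_abort("K_M must be > 0 for the log transform", "psinter_domain_error")
      log10(value)
    },
    "log_km->km_raw" = 10^value,
    ps_abort(sprintf("no transform from '%s' to '%s'", from_kind, to_kind),
             "psinter_value_error")
  )
}
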