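#' Extract per-record representation bundles
#'
#' For every record, three feature blocks: the updated classification
#' vector from the trained encoder (evaluation mode, width `hidden_dim`),
#' the mean-pooled protein token embedding (width `d_p`), and the
#' mean-pooled molecule token embedding (width `d_s`). The pooled vectors
#' depend only on the upstream embeddings, not on the encoder.
#'
#' @param model a trained `joint_encoder`.
#' @param data an [interaction_dataset()].
#' @param stores embedding stores from [embed_dataset()].
#' @return a `representation_bundles` object: list with matrices `cls`
#'   (n x hidden_dim), `protein_mean` (n x d_p), `molecule_mean`
#'   (n x d_s), rows aligned with `data`.
#' @export
extract_representations <- function(model, data, stores) {
  stopifnot(inherits(model, "joint_encoder"),
            inherits(data, "interaction_dataset"))
  ep <- encoder_predict(model, data, stores)
  uniq_p <- unique(data$protein_id)
  pool_p <- vapply(uniq_p,
                   function(k) as.numeric(mean_pool(store_read(stores$protein, k))),
                   numeric(model$d_p))
  uniq_m <- unique(data$smiles)
  pool_m <- vapply(uniq_m,
                   function(k) as.numeric(mean_pool(store_read(stores$molecule, k))),
                   numeric(model$d_s))
  bundles <- list(
    cls = ep$cls,
    protein_mean = t(pool_p)[match(data$protein_id, uniq_p), , drop = FALSE],
    molecule_mean = t(pool_m)[match(data$smiles, uniq_m), , drop = FALSE])
  for (nm in names(bundles)) {
    rownames(bundles[[nm]]) <- NULL
    if (!all(is.finite(bundles[[nm]])))
      ps_abort(sprintf("non-finite values in %s representations", nm),
               "psinter_numeric_error")
  }
  structure(bundles, class = "representation_bundles", n = nrow(data))
}

#' Assemble a feature matrix from representation bundles
#'
#' The three feature variants feeding the gradient-boosting ensemble:
#' `cls_only` (the joint classification vector), `pooled_pair` (protein
#' mean concatenated with molecule mean), and `all` (cls, then protein
#' mean, then molecule mean - concatenation order fixed and part of the
#' contract). At the full-scale embedding dimensions (hidden 768,
#' d_p 1280, d_s 600) the widths are 768, 1880 and 2648.
#'
#' @param bundles a `representation_bundles` object.
#' @param variant `"cls_only"`, `"pooled_pair"` or `"all"`.
#' @return numeric feature matrix, rows in record order.
#' @export
assemble_features <- function(bundles,
                              variant = c("cls_only", "pooled_pair", "all")) {
  variant <- match.arg(variant)
  stopifnot(inherits(bundles, "representation_bundles"))
  n <- unique(c(nrow(bundles$cls), nrow(bundles$protein_mean),
                nrow(bundles$molecule_mean)))
  if (length(n) != 1L || n == 0L)
    ps_abort("bundles have inconsistent or zero row counts",
             "psinter_consistency_error")
  switch(variant,
    cls_only = bundles$cls,
    pooled_pair = cbind(bundles$protein_mean, bundles$molecule_mean),
    all = cbind(bundles$cls, bundles$protein_mean, bundles$molecule_mean))
}

FEATURE_VARIANTS <- c("cls_only", "pooled_pair", "all")
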