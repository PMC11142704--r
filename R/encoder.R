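#' Configuration of the joint protein-molecule encoder
#'
#' The `"paper"` preset holds the full-scale constants the framework is
#' documented with: 6 attention layers with 6 heads of dimension 128
#' (hidden dimension 768 = 6 x 128), GELU feed-forward blocks, a
#' prediction head with one hidden layer of 32 ReLU units, learning rate
#' 1e-5, 100 epochs, batch size 12 (variants used in large-scale work:
#' batch 24 for the enzyme-substrate task, batch 192 with learning rate
#' 1.5e-5 for IC50 warm-start pretraining). The `"compact"` preset is the
#' desk-scale configuration used throughout the test suite: 2 layers, 2
#' heads of dimension 32 (hidden 64), 30 epochs, batch 32, learning rate
#' 1e-3 (an Adam step size at which a freshly initialized small model
#' converges within 30 epochs).
#'
#' @param preset `"paper"` or `"compact"`.
#' @param ... named overrides of any field.
#' @return a `joint_encoder_config` list. Fields: `hidden_dim`,
#'   `num_layers`, `num_heads`, `head_dim`, `ffn_mult` (feed-forward
#'   width multiplier), `ffn_activation` (GELU, computed with the
#'   standard sigmoid approximation `x * sigmoid(1.702 x)`),
#'   `pool_activation`, `head_hidden_dim`, `learning_rate`, `epochs`,
#'   `batch_size`, `positional` (add learned positional embeddings; off
#'   by default because the upstream per-token embeddings are already
#'   position-aware), `selection_metric` (`"loss"`), `seed`.
#' @export
joint_encoder_config <- function(preset = c("paper", "compact"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    hidden_dim = 768L, num_layers = 6L, num_heads = 6L, head_dim = 128L,
    ffn_mult = 4L, ffn_activation = "gelu", pool_activation = "relu",
    head_hidden_dim = 32L, learning_rate = 1e-5, epochs = 100L,
    batch_size = 12L, positional = FALSE,
    max_positions = 1282L, selection_metric = "loss", seed = 1L)
  if (preset == "compact") {
    cfg$hidden_dim <- 64L; cfg$num_layers <- 2L; cfg$num_heads <- 2L
    cfg$head_dim <- 32L; cfg$ffn_mult <- 2L; cfg$learning_rate <- 1e-3
    cfg$epochs <- 30L; cfg$batch_size <- 32L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    ps_abort(sprintf("unknown config field(s): %s",
                     paste(unknown, collapse = ", ")), "psinter_value_error")
  cfg[names(dots)] <- dots
  if (cfg$hidden_dim != cfg$num_heads * cfg$head_dim)
    ps_abort(sprintf(
      "hidden_dim (%d) must equal num_heads x head_dim (%d x %d)",
      cfg$hidden_dim, cfg$num_heads, cfg$head_dim), "psinter_value_error")
  structure(cfg, class = "joint_encoder_config")
}

#' @export
print.joint_encoder_config <- function(x, ...) {
  cat(sprintf(
    "<joint_encoder_config> %d layer(s), %d head(s) x %d = hidden %d, lr %g, %d epoch(s)\n",
    x$num_layers, x$num_heads, x$head_dim, x$hidden_dim,
    x$learning_rate, x$epochs))
  invisible(x)
}

# ---- parameter initialization -------------------------------------------

#' Initialize an untrained joint encoder
#'
#' Weights are drawn N(0, 0.02^2) (the usual transformer initialization);
#' layer-norm gains start at 1 and biases at 0.
#'
#' @param cfg a [joint_encoder_config()].
#' @param d_p,d_s widths of the incoming protein / molecule token
#'   embeddings.
#' @param task `"regression"` or `"binary_classification"`.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return an object of class `joint_encoder`.
#' @export
init_joint_encoder <- function(cfg, d_p, d_s,
                               task = c("regression", "binary_classification"),
                               seed = cfg$seed) {
  task <- match.arg(task)
  H <- cfg$hidden_dim; FF <- cfg$ffn_mult * H
  sd0 <- 0.02
  params <- with_seed(as.integer(seed), {
    p <- list(
      pool_p_W = matrix(stats::rnorm(d_p * H, sd = sd0), d_p, H),
      pool_p_b = numeric(H),
      pool_s_W = matrix(stats::rnorm(d_s * H, sd = sd0), d_s, H),
      pool_s_b = numeric(H))
    for (l in seq_len(cfg$num_layers)) {
      pre <- sprintf("l%d.", l)
      p[[paste0(pre, "Wq")]] <- matrix(stats::rnorm(H * H, sd = sd0), H, H)
      p[[paste0(pre, "Wk")]] <- matrix(stats::rnorm(H * H, sd = sd0), H, H)
      p[[paste0(pre, "Wv")]] <- matrix(stats::rnorm(H * H, sd = sd0), H, H)
      p[[paste0(pre, "Wo")]] <- matrix(stats::rnorm(H * H, sd = sd0), H, H)
      p[[paste0(pre, "bq")]] <- numeric(H)
      p[[paste0(pre, "bk")]] <- numeric(H)
      p[[paste0(pre, "bv")]] <- numeric(H)
      p[[paste0(pre, "bo")]] <- numeric(H)
      p[[paste0(pre, "ln1_g")]] <- rep(1, H)
      p[[paste0(pre, "ln1_b")]] <- numeric(H)
      p[[paste0(pre, "W1")]] <- matrix(stats::rnorm(H * FF, sd = sd0), H, FF)
      p[[paste0(pre, "b1")]] <- numeric(FF)
      p[[paste0(pre, "W2")]] <- matrix(stats::rnorm(FF * H, sd = sd0), FF, H)
      p[[paste0(pre, "b2")]] <- numeric(H)
      p[[paste0(pre, "ln2_g")]] <- rep(1, H)
      p[[paste0(pre, "ln2_b")]] <- numeric(H)
    }
    if (isTRUE(cfg$positional))
      p$pos <- matrix(stats::rnorm(cfg$max_positions * H, sd = sd0),
                      cfg$max_positions, H)
    p$head_W1 <- matrix(stats::rnorm(H * cfg$head_hidden_dim, sd = sd0),
                        H, cfg$head_hidden_dim)
    p$head_b1 <- numeric(cfg$head_hidden_dim)
    p$head_W2 <- matrix(stats::rnorm(cfg$head_hidden_dim, sd = sd0),
                        cfg$head_hidden_dim, 1)
    p$head_b2 <- 0
    p
  })
  structure(list(cfg = cfg, params = params, task = task,
                 d_p = as.integer(d_p), d_s = as.integer(d_s),
                 history = NULL, best_epoch = NA_integer_),
            class = "joint_encoder")
}

#' @export
print.joint_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<joint_encoder> task: %s, %d parameters (d_p = %d, d_s = %d)\n",
              x$task, np, x$d_p, x$d_s))
  print(x$cfg)
  invisible(x)
}

# ---- elementary pieces ---------------------------------------------------

relu <- function(x) x * (x > 0)

add_bias <- function(x, b) x + rep(b, each = nrow(x))

LAYER_FIELDS <- c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo",
                  "ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b")

layer_param_list <- function(params, cfg) {
  lapply(seq_len(cfg$num_layers), function(l) {
    lp <- params[paste0(sprintf("l%d.", l), LAYER_FIELDS)]
    names(lp) <- LAYER_FIELDS
    lp
  })
}

# ---- assembled single-example API ---------------------------------------

#' Assemble one protein + molecule pair into an encoder input
#'
#' Builds the joint input sequence: a classification row (all ones), the
#' protein token rows mapped into the hidden dimension by the protein
#' pooling layer (single affine map + ReLU), a separator row (all zeros),
#' and the molecule token rows mapped by the molecule pooling layer. The
#' two constant rows are not passed through the pooling layers.
#'
#' @param prot protein `token_embedding_matrix` (rows already truncated to
#'   the spec's limits).
#' @param mol molecule `token_embedding_matrix`.
#' @param pools pooling parameters: a `joint_encoder` or a list with
#'   `pool_p_W`, `pool_p_b`, `pool_s_W`, `pool_s_b`.
#' @param cfg a [joint_encoder_config()].
#' @return an `assembled_input`: list with `matrix`
#'   (`1 + n_prot + 1 + n_mol` rows x `hidden_dim`), `attention_mask`
#'   (all ones), and `segment_labels` (`"cls"`, `"protein"`, `"sep"`,
#'   `"molecule"` per row).
#' @export
assemble_input <- function(prot, mol, pools, cfg) {
  if (inherits(pools, "joint_encoder")) pools <- pools$params
  H <- cfg$hidden_dim
  if (ncol(prot) != nrow(pools$pool_p_W) || ncol(pools$pool_p_W) != H)
    ps_abort(sprintf(
      "protein width %d does not match pooling parameters (%d -> %d, hidden %d)",
      ncol(prot), nrow(pools$pool_p_W), ncol(pools$pool_p_W), H),
      "psinter_shape_error")
  if (ncol(mol) != nrow(pools$pool_s_W) || ncol(pools$pool_s_W) != H)
    ps_abort(sprintf(
      "molecule width %d does not match pooling parameters (%d -> %d, hidden %d)",
      ncol(mol), nrow(pools$pool_s_W), ncol(pools$pool_s_W), H),
      "psinter_shape_error")
  pp <- relu(add_bias(prot %*% pools$pool_p_W, pools$pool_p_b))
  ms <- relu(add_bias(mol %*% pools$pool_s_W, pools$pool_s_b))
  x <- rbind(rep(1, H), pp, rep(0, H), ms)
  rownames(x) <- NULL
  segments <- c("cls", rep("protein", nrow(pp)), "sep", rep("molecule", nrow(ms)))
  structure(list(matrix = x, attention_mask = rep(1L, nrow(x)),
                 segment_labels = segments),
            class = "assembled_input")
}

#' Run the encoder on one assembled input (evaluation mode)
#'
#' Deterministic forward pass. Rows whose `attention_mask` entry is 0 are
#' excluded from every attention computation, so padding rows cannot
#' influence the classification vector or the prediction.
#'
#' @param model a `joint_encoder`.
#' @param x an [assemble_input()] result (optionally with masked padding
#'   rows appended).
#' @param task task kind; defaults to the model's task.
#' @return list with `prediction` (probability in (0,1) for
#'   classification) and `cls_vector` (the updated classification row).
#' @export
encoder_forward <- function(model, x, task = model$task) {
  stopifnot(inherits(x, "assembled_input"))
  if (ncol(x$matrix) != model$cfg$hidden_dim)
    ps_abort("assembled input width does not match the model",
             "psinter_shape_error")
  n <- nrow(x$matrix)
  res <- encoder_layers_fwd(model$params, model$cfg, x$matrix,
                            idx_list = list(seq_len(n)),
                            mask = x$attention_mask, keep_cache = FALSE)
  head_out <- head_fwd(model$params, res$X[1, , drop = FALSE], task)
  list(prediction = as.numeric(head_out$pred),
       cls_vector = as.numeric(res$X[1, ]))
}

# ---- batched internals ---------------------------------------------------

# Pools raw token matrices and assembles the stacked row matrix for a
# batch of examples. Returns assembly bookkeeping needed by the backward
# pass.
pool_assemble_fwd <- function(params, cfg, prot_list, mol_list) {
  H <- cfg$hidden_dim
  np <- vapply(prot_list, nrow, integer(1))
  ns <- vapply(mol_list, nrow, integer(1))
  PA <- do.call(rbind, prot_list)
  MA <- do.call(rbind, mol_list)
  pre_p <- add_bias(PA %*% params$pool_p_W, params$pool_p_b)
  pre_s <- add_bias(MA %*% params$pool_s_W, params$pool_s_b)
  Pp <- relu(pre_p); Ms <- relu(pre_s)
  len <- 1L + np + 1L + ns
  offs <- cumsum(c(0L, len[-length(len)]))
  N <- sum(len)
  cls_rows <- offs + 1L
  sep_rows <- offs + np + 2L
  prot_rows <- unlist(mapply(function(o, n) o + 1L + seq_len(n), offs, np,
                             SIMPLIFY = FALSE))
  mol_rows <- unlist(mapply(function(o, n_p, n_s) o + n_p + 2L + seq_len(n_s),
                            offs, np, ns, SIMPLIFY = FALSE))
  X <- matrix(0, N, H)
  X[cls_rows, ] <- 1
  X[prot_rows, ] <- Pp
  X[mol_rows, ] <- Ms
  if (isTRUE(cfg$positional)) {
    pos_idx <- unlist(lapply(len, seq_len))
    X <- X + params$pos[pos_idx, , drop = FALSE]
  } else pos_idx <- NULL
  idx_list <- mapply(function(o, l) (o + 1L):(o + l), offs, len,
                     SIMPLIFY = FALSE)
  list(X = X, idx_list = idx_list, cls_rows = cls_rows,
       prot_rows = prot_rows, mol_rows = mol_rows, pos_idx = pos_idx,
       PA = PA, MA = MA, pre_p = pre_p, pre_s = pre_s)
}

pool_assemble_bwd <- function(params, cfg, asm, dX) {
  grads <- list()
  dPp <- dX[asm$prot_rows, , drop = FALSE]
  dMs <- dX[asm$mol_rows, , drop = FALSE]
  dpre_p <- dPp * (asm$pre_p > 0)
  dpre_s <- dMs * (asm$pre_s > 0)
  grads$pool_p_W <- crossprod(asm$PA, dpre_p)
  grads$pool_p_b <- colSums(dpre_p)
  grads$pool_s_W <- crossprod(asm$MA, dpre_s)
  grads$pool_s_b <- colSums(dpre_s)
  if (isTRUE(cfg$positional)) {
    dpos <- matrix(0, nrow(params$pos), cfg$hidden_dim)
    # accumulate by position index
    for (p in unique(asm$pos_idx))
      dpos[p, ] <- colSums(dX[asm$pos_idx == p, , drop = FALSE])
    grads$pos <- dpos
  }
  grads
}

# Forward through all attention layers on stacked rows X (C++ kernel).
# idx_list: per-example row index ranges; mask: 0/1 per row (0 = padding).
encoder_layers_fwd <- function(params, cfg, X, idx_list, mask = NULL,
                               keep_cache = TRUE) {
  ex_start <- vapply(idx_list, function(i) i[1] - 1L, integer(1))
  ex_len <- lengths(idx_list)
  if (is.null(mask)) mask <- rep(1L, nrow(X))
  res <- tryCatch(
    .enc_layers_fwd(layer_param_list(params, cfg), X, ex_start, ex_len,
                    cfg$num_heads, cfg$head_dim, as.integer(mask),
                    keep_cache),
    error = function(e) ps_abort(conditionMessage(e), "psinter_numeric_error"))
  list(X = res$X, caches = res$caches, ex_start = ex_start, ex_len = ex_len,
       mask = as.integer(mask))
}

flatten_layer_grads <- function(res_grads, params, cfg) {
  grads <- list()
  for (l in seq_len(cfg$num_layers)) {
    gl <- res_grads[[l]]
    for (f in LAYER_FIELDS) {
      g <- gl[[f]]
      if (!is.matrix(params[[paste0(sprintf("l%d.", l), f)]]))
        g <- as.numeric(g)
      grads[[paste0(sprintf("l%d.", l), f)]] <- g
    }
  }
  grads
}

head_fwd <- function(params, C, task) {
  h1pre <- add_bias(C %*% params$head_W1, params$head_b1)
  h1 <- relu(h1pre)
  out <- as.numeric(h1 %*% params$head_W2) + params$head_b2
  pred <- if (task == "binary_classification") stats::plogis(out) else out
  list(pred = pred, out = out, h1 = h1, h1pre = h1pre, C = C)
}

head_bwd <- function(params, hf, dout) {
  dh1 <- (dout %*% t(params$head_W2)) * (hf$h1pre > 0)
  list(grads = list(head_W2 = crossprod(hf$h1, dout),
                    head_b2 = sum(dout),
                    head_W1 = crossprod(hf$C, dh1),
                    head_b1 = colSums(dh1)),
       dC = dh1 %*% t(params$head_W1))
}

# Full forward + backward for one mini-batch of raw token matrices
# (fused C++ step). Returns loss, predictions and the gradient list for
# every parameter.
batch_grad <- function(model, prot_list, mol_list, y) {
  cfg <- model$cfg; params <- model$params
  asm <- pool_assemble_fwd(params, cfg, prot_list, mol_list)
  res <- tryCatch(
    .enc_train_step(
      layer_param_list(params, cfg),
      params[c("head_W1", "head_b1", "head_W2", "head_b2")],
      asm$X,
      vapply(asm$idx_list, function(i) i[1] - 1L, integer(1)),
      lengths(asm$idx_list),
      cfg$num_heads, cfg$head_dim, asm$cls_rows - 1L, y,
      model$task == "binary_classification"),
    error = function(e) ps_abort(conditionMessage(e), "psinter_numeric_error"))
  grads <- c(res$head_grads, flatten_layer_grads(res$grads, params, cfg),
             pool_assemble_bwd(params, cfg, asm, res$dX))
  grads$head_b1 <- as.numeric(grads$head_b1)
  list(loss = res$loss, pred = as.numeric(res$pred), grads = grads)
}

# Evaluation-mode forward for a batch; returns predictions and cls matrix.
batch_eval <- function(model, prot_list, mol_list) {
  asm <- pool_assemble_fwd(model$params, model$cfg, prot_list, mol_list)
  fwd <- encoder_layers_fwd(model$params, model$cfg, asm$X, asm$idx_list,
                            keep_cache = FALSE)
  C <- fwd$X[asm$cls_rows, , drop = FALSE]
  hf <- head_fwd(model$params, C, model$task)
  list(pred = hf$pred, cls = C)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- training ------------------------------------------------------------

#' Train the joint encoder end-to-end
#'
#' Trains pooling layers, attention stack and prediction head jointly with
#' Adam at `cfg$learning_rate`, minimizing mean squared error (regression)
#' or binary cross-entropy (classification). Iteration follows the
#' chunk-block plan of [plan_subset_batches()], so only one protein chunk
#' and one molecule chunk of embeddings are resident at a time. Model
#' parameters are snapshotted after every epoch and the snapshot with the
#' best validation performance is returned (early stopping); the default
#' selection criterion is validation loss.
#'
#' @param data training [interaction_dataset()].
#' @param stores embedding stores from [embed_dataset()].
#' @param cfg a [joint_encoder_config()].
#' @param val validation [interaction_dataset()] (non-empty).
#' @param warm_start optional `joint_encoder` (or checkpoint path) used as
#'   initial parameters. All parameter shapes must match the configuration;
#'   the prediction head is reinitialized when the task kind changes.
#' @param verbose print per-epoch losses.
#' @return a trained `joint_encoder` with elements `history` (per-epoch
#'   train/val losses) and `best_epoch`.
#' @export
train_encoder <- function(data, stores, cfg, val, warm_start = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(data, "interaction_dataset"))
  if (!inherits(val, "interaction_dataset") || nrow(val) == 0L)
    ps_abort("a non-empty validation dataset is required", "psinter_value_error")
  task <- attr(data, "task")
  d_p <- ncol(store_read(stores$protein, store_keys(stores$protein)[1]))
  d_s <- ncol(store_read(stores$molecule, store_keys(stores$molecule)[1]))

  model <- init_joint_encoder(cfg, d_p, d_s, task = task, seed = cfg$seed)
  if (!is.null(warm_start)) {
    ck <- if (is.character(warm_start)) load_encoder(warm_start) else warm_start
    model$params <- warm_start_params(model, ck)
  }

  plan <- plan_from_stores(stores, data)
  if (cfg$epochs == 0L) {
    model$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric())
    return(model)
  }

  opt <- adam_init(model$params)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  best <- list(val = Inf, params = model$params, epoch = NA_integer_)
  set.seed(derive_seed("train_encoder", cfg$seed))
  for (epoch in seq_len(cfg$epochs)) {
    epoch_loss <- 0; n_seen <- 0L
    for (block in plan) {
      if (!length(block$pair_idx)) next
      pchunk <- store_read_chunk(stores$protein, block$protein_chunk)
      mchunk <- store_read_chunk(stores$molecule, block$molecule_chunk)
      order_idx <- sample(block$pair_idx)
      starts <- seq(1L, length(order_idx), by = cfg$batch_size)
      for (s in starts) {
        take <- order_idx[s:min(s + cfg$batch_size - 1L, length(order_idx))]
        prot_list <- pchunk[data$protein_id[take]]
        mol_list <- mchunk[data$smiles[take]]
        bg <- batch_grad(model, prot_list, mol_list, data$label[take])
        upd <- adam_step(model$params, bg$grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + bg$loss * length(take)
        n_seen <- n_seen + length(take)
      }
    }
    vp <- encoder_predict(model, val, stores)
    val_loss <- if (task == "binary_classification") {
      p <- pmin(pmax(vp$prediction, 1e-12), 1 - 1e-12)
      -mean(val$label * log(p) + (1 - val$label) * log(1 - p))
    } else mean((val$label - vp$prediction)^2)
    history$train_loss[epoch] <- epoch_loss / n_seen
    history$val_loss[epoch] <- val_loss
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, epoch = epoch)
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      history$train_loss[epoch], val_loss))
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

warm_start_params <- function(model, ck) {
  head_names <- c("head_W1", "head_b1", "head_W2", "head_b2")
  new <- model$params
  body_names <- setdiff(names(new), head_names)
  missing <- setdiff(body_names, names(ck$params))
  mism <- character()
  for (nm in body_names) {
    if (nm %in% missing) next
    if (!identical(dim(new[[nm]]), dim(ck$params[[nm]])) ||
        length(new[[nm]]) != length(ck$params[[nm]]))
      mism <- c(mism, nm)
  }
  if (length(missing) || length(mism))
    ps_abort(sprintf(
      "warm-start checkpoint incompatible; missing: [%s]; shape mismatch: [%s]",
      paste(missing, collapse = ", "), paste(mism, collapse = ", ")),
      "psinter_checkpoint_error", missing = missing, mismatched = mism)
  for (nm in body_names) new[[nm]] <- ck$params[[nm]]
  if (identical(ck$task, model$task)) {
    for (nm in head_names)
      if (!is.null(ck$params[[nm]])) new[[nm]] <- ck$params[[nm]]
  }
  new
}

#' Predict with a trained encoder
#'
#' Evaluation-mode forward pass over a dataset; follows the chunk-block
#' plan so memory use stays bounded.
#'
#' @param model a trained `joint_encoder`.
#' @param data an [interaction_dataset()].
#' @param stores embedding stores from [embed_dataset()].
#' @param batch_size forward batch size.
#' @return list with `prediction` (numeric vector aligned with `data`
#'   rows) and `cls` (matrix of updated classification vectors, one row
#'   per record).
#' @export
encoder_predict <- function(model, data, stores, batch_size = 64L) {
  plan <- plan_from_stores(stores, data)
  pred <- numeric(nrow(data))
  cls <- matrix(NA_real_, nrow(data), model$cfg$hidden_dim)
  for (block in plan) {
    if (!length(block$pair_idx)) next
    pchunk <- store_read_chunk(stores$protein, block$protein_chunk)
    mchunk <- store_read_chunk(stores$molecule, block$molecule_chunk)
    starts <- seq(1L, length(block$pair_idx), by = batch_size)
    for (s in starts) {
      take <- block$pair_idx[s:min(s + batch_size - 1L, length(block$pair_idx))]
      be <- batch_eval(model, pchunk[data$protein_id[take]],
                       mchunk[data$smiles[take]])
      pred[take] <- be$pred
      cls[take, ] <- be$cls
    }
  }
  list(prediction = pred, cls = cls)
}

#' Save / load encoder checkpoints
#'
#' Checkpoints are self-describing: they carry the configuration, task
#' kind, input widths and all parameter tensors.
#'
#' @param model a `joint_encoder`.
#' @param path file path.
#' @return `save_encoder` returns `path` invisibly; `load_encoder` the
#'   restored `joint_encoder`.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "joint_encoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  if (!file.exists(path))
    ps_abort(sprintf("no checkpoint at %s", path), "psinter_io_error")
  model <- readRDS(path)
  if (!inherits(model, "joint_encoder"))
    ps_abort("file is not an encoder checkpoint", "psinter_checkpoint_error")
  model
}
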