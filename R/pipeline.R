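#' Default pipeline configuration
#'
#' A nested configuration covering every stage of the workflow:
#' `data` (synthetic-generator settings, or `path`/`column_map`/`task`
#' for a user table), `provider` (embedding widths and seed), `encoder`
#' (preset and overrides), `split` (scenario, fractions, repeats), and
#' `gbm` (search-space preset and number of random-search iterations).
#' `pipeline_config()` returns the defaults; pass a named list (or a
#' YAML file path) with any subset of fields to override.
#'
#' @param config optional named list or YAML file path with overrides.
#' @return a `pipeline_config` nested list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    data = list(synthetic = TRUE, path = NULL, column_map = NULL,
                task = "regression",
                n_proteins = 60L, n_molecules = 60L, n_pairs = 1500L,
                effect_size = 1, noise_sd = 0.5, positive_fraction = 0.25,
                permute_labels = FALSE),
    provider = list(d_p = 64L, d_s = 32L),
    encoder = list(preset = "compact"),
    split = list(scenario = "random", fractions = c(0.8, 0.1, 0.1),
                 n_repeats = 1L),
    gbm = list(space_preset = "compact", n_iter = 50L),
    baselines = FALSE,
    store_dir = NULL)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
      ps_abort(sprintf("unknown config section(s): %s",
                       paste(unknown, collapse = ", ")),
               "psinter_schema_error")
    defaults <- utils::modifyList(defaults, config)
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full interaction-prediction workflow
#'
#' Executes, in order: data simulation (or ingestion), token embedding
#' into chunked stores, splitting, end-to-end encoder training (with the
#' validation set for early stopping), representation extraction, random
#' hyperparameter search for the three gradient-boosting models,
#' simplex-grid ensemble weight fitting on validation predictions,
#' retraining of the finalists on train + validation, and - last -
#' evaluation on the untouched test set. With `n_repeats > 1` the whole
#' procedure is repeated on independent splits and metrics are
#' aggregated as mean and standard deviation.
#'
#' @param config a [pipeline_config()], a named list of overrides, or a
#'   YAML path.
#' @param verbose print per-stage progress.
#' @return a `pipeline_result`: list with `reports` (per-repeat metric
#'   lists), `summary` (data frame of mean/sd per metric), `manifest`
#'   (config echo, seeds, provider info, split manifests, per-stage
#'   timings, stage log), and `last_run` (models and predictions of the
#'   final repeat).
#' @export
run_experiment <- function(config = pipeline_config(), verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  t_start <- Sys.time()
  stage_log <- character()
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    stage_log <<- c(stage_log, stage)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (verbose) message(sprintf("[%s] %.1fs", stage, timings[[stage]]))
    out
  }

  # -- simulate / ingest ---------------------------------------------------
  if (isTRUE(config$data$synthetic)) {
    syn_cfg <- synthetic_config(
      n_proteins = config$data$n_proteins,
      n_molecules = config$data$n_molecules,
      n_pairs = config$data$n_pairs, task = config$data$task,
      effect_size = config$data$effect_size,
      noise_sd = config$data$noise_sd,
      positive_fraction = config$data$positive_fraction,
      seed = config$seed)
    gen <- tick("simulate", generate_dataset(syn_cfg))
    ds <- gen$dataset
    signal <- synthetic_signal_tokens(syn_cfg)
  } else {
    ds <- tick("ingest", read_interaction_table(
      config$data$path, column_map = config$data$column_map,
      task = config$data$task))
    signal <- list(protein = character(), molecule = character())
  }
  task <- attr(ds, "task")
  if (isTRUE(config$data$permute_labels)) {
    # negative control: break every protein-molecule-label association
    ds$label <- with_seed(derive_seed("permute", config$seed),
                          sample(ds$label))
  }

  # -- embed ---------------------------------------------------------------
  provider <- synthetic_embedding_provider(
    spec = embedding_spec(d_p = config$provider$d_p,
                          d_s = config$provider$d_s),
    seed = config$seed, signal_tokens = signal)
  stores <- tick("embed", embed_dataset(
    provider, ds, dir = config$store_dir %||% tempfile("psinter_store_")))

  # -- split ---------------------------------------------------------------
  sspec <- split_spec(scenario = config$split$scenario,
                      fractions = config$split$fractions,
                      n_repeats = config$split$n_repeats,
                      seed = config$seed)
  splits <- tick("split", make_split(ds, sspec))

  reports <- vector("list", length(splits))
  last_run <- NULL
  for (r in seq_along(splits)) {
    run <- pipeline_one_repeat(ds, stores, splits[[r]], config, task,
                               repeat_id = r, tick = tick)
    reports[[r]] <- run$report
    last_run <- run
  }

  metric_names <- names(reports[[1]])
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m)
      mean(vapply(reports, function(x) x[[m]], numeric(1))), numeric(1)),
    sd = vapply(metric_names, function(m)
      stats::sd(vapply(reports, function(x) x[[m]], numeric(1))), numeric(1)),
    row.names = NULL)

  manifest <- list(
    config = unclass(config), seed = config$seed, task = task,
    provider = stores$provider_info,
    n_records = nrow(ds),
    split_manifests = lapply(splits, function(s) s$manifest),
    stage_log = stage_log, timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  structure(list(reports = reports, summary = summary, manifest = manifest,
                 last_run = last_run, dataset = ds),
            class = "pipeline_result")
}

pipeline_one_repeat <- function(ds, stores, split, config, task, repeat_id,
                                tick) {
  tag <- function(stage) sprintf("%s[%d]", stage, repeat_id)
  tr <- ds[split$train]; va <- ds[split$val]; te <- ds[split$test]
  seed_r <- derive_seed("repeat", config$seed, repeat_id)

  enc_cfg <- do.call(joint_encoder_config,
                     c(list(preset = config$encoder$preset %||% "compact"),
                       config$encoder[setdiff(names(config$encoder), "preset")],
                       list(seed = seed_r)))
  model <- tick(tag("train-encoder"), train_encoder(tr, stores, enc_cfg, va))

  reps <- tick(tag("extract"), list(
    train = extract_representations(model, tr, stores),
    val = extract_representations(model, va, stores),
    test = extract_representations(model, te, stores)))
  feats <- lapply(reps, function(b)
    stats::setNames(lapply(FEATURE_VARIANTS, function(v)
      assemble_features(b, v)), FEATURE_VARIANTS))

  space <- gbm_search_space(config$gbm$space_preset %||% "compact")
  if (task == "regression") space$negative_class_weight <- NULL
  searches <- tick(tag("train-ensemble"), lapply(FEATURE_VARIANTS, function(v)
    random_search(feats$train[[v]], tr$label, feats$val[[v]], va$label,
                  task = task, space = space,
                  n_iter = config$gbm$n_iter, seed = seed_r)))
  names(searches) <- FEATURE_VARIANTS
  best_hp <- lapply(searches, `[[`, "best_hp")

  val_models <- lapply(FEATURE_VARIANTS, function(v)
    train_gbm(feats$train[[v]], tr$label, best_hp[[v]], task, seed = seed_r))
  names(val_models) <- FEATURE_VARIANTS
  val_preds <- lapply(FEATURE_VARIANTS, function(v)
    predict(val_models[[v]], feats$val[[v]]))
  weights <- fit_ensemble_weights(val_preds, va$label, task = task)

  # audit keyed on record identity: a record index may only sit in one part
  ensemble <- finalize_models(
    feats$train, feats$val, tr$label, va$label, best_hp, weights,
    task = task, seed = seed_r,
    train_keys = split$train, val_keys = split$val, test_keys = split$test)

  pred_test <- tick(tag("predict"), ensemble_predict(ensemble, feats$test))
  per_model_test <- lapply(FEATURE_VARIANTS, function(v)
    predict(ensemble$models[[v]], feats$test[[v]]))
  names(per_model_test) <- FEATURE_VARIANTS

  report <- tick(tag("evaluate"), {
    rep_all <- as.list(metric_report(te$label, pred_test, task))
    key <- if (task == "regression") "r_squared" else "mcc"
    for (v in FEATURE_VARIANTS) {
      rep_all[[paste0(key, "_", v)]] <-
        single_metric(te$label, per_model_test[[v]], task)
    }
    rep_all
  })

  if (isTRUE(config$baselines)) {
    base_feats <- list(
      protein_only = lapply(reps, function(b) b$protein_mean),
      molecule_only = lapply(reps, function(b) b$molecule_mean))
    for (bn in names(base_feats)) {
      bf <- base_feats[[bn]]
      bs <- random_search(bf$train, tr$label, bf$val, va$label, task = task,
                          space = space, n_iter = config$gbm$n_iter,
                          seed = seed_r)
      bm <- train_gbm(rbind(bf$train, bf$val), c(tr$label, va$label),
                      bs$best_hp, task, seed = seed_r)
      key <- if (task == "regression") "r_squared" else "mcc"
      report[[paste0(key, "_", bn)]] <-
        single_metric(te$label, predict(bm, bf$test), task)
    }
  }

  list(report = report, model = model, ensemble = ensemble,
       weights = weights, split = split,
       predictions = list(test = pred_test, per_model = per_model_test))
}

single_metric <- function(y, p, task) {
  if (task == "regression") regression_metrics(y, p)$r_squared
  else tryCatch(binary_metrics(y, p)$mcc, psinter_error = function(e) 0)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> task: %s, %d repeat(s), %.0fs total\n",
              x$manifest$task, length(x$reports),
              x$manifest$total_seconds))
  print(x$summary, digits = 4)
  invisible(x)
}
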