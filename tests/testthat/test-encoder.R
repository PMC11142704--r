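test_that("config enforces the head-dimension identity", {
  cfg <- joint_encoder_config()
  expect_equal(cfg$hidden_dim, 768L)
  expect_equal(cfg$num_heads * cfg$head_dim, 768L)
  small <- joint_encoder_config(preset = "compact")
  expect_equal(small$hidden_dim, small$num_heads * small$head_dim)
  expect_error(joint_encoder_config(hidden_dim = 100L),
               class = "psinter_value_error")
  expect_error(joint_encoder_config(not_a_field = 1),
               class = "psinter_value_error")
})

test_that("assembled inputs have the contract layout", {
  cfg <- joint_encoder_config(preset = "compact", seed = 2L)
  model <- init_joint_encoder(cfg, d_p = 12L, d_s = 8L)
  prot <- random_token_matrix(10, 12, seed = 1)
  mol <- random_token_matrix(5, 8, seed = 2)
  x <- assemble_input(prot, mol, model, cfg)
  expect_equal(nrow(x$matrix), 17L)  # 1 + 10 + 1 + 5
  expect_equal(ncol(x$matrix), cfg$hidden_dim)
  expect_equal(unname(x$matrix[1, ]), rep(1, cfg$hidden_dim))   # cls
  expect_equal(unname(x$matrix[12, ]), rep(0, cfg$hidden_dim))  # sep
  expect_equal(x$segment_labels,
               c("cls", rep("protein", 10), "sep", rep("molecule", 5)))
  expect_error(assemble_input(random_token_matrix(4, 9), mol, model, cfg),
               class = "psinter_shape_error")
})

test_that("evaluation forward is deterministic; classification bounded", {
  cfg <- joint_encoder_config(preset = "compact", seed = 2L)
  model <- init_joint_encoder(cfg, 12L, 8L, task = "binary_classification")
  x <- assemble_input(random_token_matrix(6, 12), random_token_matrix(4, 8),
                      model, cfg)
  o1 <- encoder_forward(model, x)
  o2 <- encoder_forward(model, x)
  expect_identical(o1, o2)
  expect_gt(o1$prediction, 0); expect_lt(o1$prediction, 1)
  expect_length(o1$cls_vector, cfg$hidden_dim)
})

test_that("masked padding rows cannot influence the prediction", {
  cfg <- joint_encoder_config(preset = "compact", seed = 3L)
  model <- init_joint_encoder(cfg, 12L, 8L)
  x <- assemble_input(random_token_matrix(7, 12), random_token_matrix(3, 8),
                      model, cfg)
  base <- encoder_forward(model, x)
  set.seed(4)
  pad <- matrix(rnorm(5 * cfg$hidden_dim, sd = 10), 5)
  xp <- x
  xp$matrix <- rbind(x$matrix, pad)
  xp$attention_mask <- c(x$attention_mask, rep(0L, 5))
  xp$segment_labels <- c(x$segment_labels, rep("molecule", 5))
  padded <- encoder_forward(model, xp)
  expect_lt(abs(padded$prediction - base$prediction), 1e-5)
  expect_lt(max(abs(padded$cls_vector - base$cls_vector)), 1e-5)
})

test_that("analytic gradients match central differences", {
  cfg <- joint_encoder_config(preset = "compact", hidden_dim = 16L,
                              num_heads = 2L, head_dim = 8L, ffn_mult = 2L,
                              head_hidden_dim = 4L, seed = 3L)
  for (task in c("regression", "binary_classification")) {
    model <- init_joint_encoder(cfg, 6L, 5L, task = task, seed = 3L)
    set.seed(11)
    prot <- lapply(c(4, 6, 3), function(n) matrix(rnorm(n * 6), n, 6))
    mol <- lapply(c(3, 2, 5), function(n) matrix(rnorm(n * 5), n, 5))
    y <- if (task == "regression") rnorm(3) else c(0, 1, 1)
    bg <- psinter:::batch_grad(model, prot, mol, y)
    loss_at <- function(params) {
      m2 <- model; m2$params <- params
      psinter:::batch_grad(m2, prot, mol, y)$loss
    }
    eps <- 1e-5
    for (nm in names(model$params)) {
      idx <- sample(length(model$params[[nm]]),
                    min(2L, length(model$params[[nm]])))
      for (i in idx) {
        pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        ana <- bg$grads[[nm]][i]
        expect_true(abs(num - ana) < 1e-6 ||
                      abs(num - ana) / (abs(num) + abs(ana)) < 1e-3,
                    label = sprintf("gradient of %s[%d] (%s)", nm, i, task))
      }
    }
  }
})

test_that("training reduces loss on a small planted dataset", {
  fx <- small_synthetic()
  sp <- make_split(fx$dataset, split_spec("random", n_repeats = 1L,
                                          seed = 7L))[[1]]
  cfg <- joint_encoder_config(preset = "compact", epochs = 8L, seed = 7L)
  model <- train_encoder(fx$dataset[sp$train], fx$stores, cfg,
                         val = fx$dataset[sp$val])
  h <- model$history
  expect_equal(nrow(h), 8L)
  expect_lt(h$train_loss[8], h$train_loss[1])
  # returned snapshot is the validation-loss argmin
  expect_equal(model$best_epoch, which.min(h$val_loss))
  # reproducible end-to-end
  model2 <- train_encoder(fx$dataset[sp$train], fx$stores, cfg,
                          val = fx$dataset[sp$val])
  expect_equal(model$params, model2$params)
})

test_that("warm starts respect shapes and zero-epoch identity", {
  enc <- small_trained_encoder()
  fx <- small_synthetic()
  sp <- enc$split
  cfg0 <- joint_encoder_config(preset = "compact", epochs = 0L, seed = 7L)
  same <- train_encoder(fx$dataset[sp$train], fx$stores, cfg0,
                        val = fx$dataset[sp$val], warm_start = enc$model)
  expect_equal(same$params, enc$model$params)

  # checkpoint round trip through disk
  path <- withr::local_tempfile(fileext = ".rds")
  save_encoder(enc$model, path)
  expect_equal(load_encoder(path)$params, enc$model$params)

  # shape mismatch is reported with the offending tensors
  bad <- enc$model
  bad$params$l1.Wq <- bad$params$l1.Wq[1:8, 1:8]
  err <- tryCatch(
    train_encoder(fx$dataset[sp$train], fx$stores, cfg0,
                  val = fx$dataset[sp$val], warm_start = bad),
    psinter_checkpoint_error = identity)
  expect_s3_class(err, "psinter_checkpoint_error")
  expect_match(conditionMessage(err), "l1.Wq", fixed = TRUE)
})

test_that("task change reinitializes only the prediction head", {
  enc <- small_trained_encoder()
  fx <- small_synthetic()
  sp <- enc$split
  ds_bin <- fx$dataset
  ds_bin$label <- as.numeric(ds_bin$label > stats::median(ds_bin$label))
  attr(ds_bin, "task") <- "binary_classification"
  attr(ds_bin, "label_kind") <- "binary"
  cfg0 <- joint_encoder_config(preset = "compact", epochs = 0L, seed = 7L)
  warm <- train_encoder(ds_bin[sp$train], fx$stores, cfg0,
                        val = ds_bin[sp$val], warm_start = enc$model)
  expect_equal(warm$params$l1.Wq, enc$model$params$l1.Wq)
  expect_false(isTRUE(all.equal(warm$params$head_W1,
                                enc$model$params$head_W1)))
})

test_that("positional embeddings are off by default and change outputs when on", {
  cfg_off <- joint_encoder_config(preset = "compact", seed = 5L)
  expect_false(cfg_off$positional)
  cfg_on <- joint_encoder_config(preset = "compact", positional = TRUE,
                                 max_positions = 64L, seed = 5L)
  m_off <- init_joint_encoder(cfg_off, 6L, 5L)
  m_on <- init_joint_encoder(cfg_on, 6L, 5L)
  prot <- list(random_token_matrix(4, 6, 1)); mol <- list(random_token_matrix(3, 5, 2))
  p_off <- psinter:::batch_eval(m_off, prot, mol)$pred
  p_on <- psinter:::batch_eval(m_on, prot, mol)$pred
  expect_false(isTRUE(all.equal(p_off, p_on)))
})
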