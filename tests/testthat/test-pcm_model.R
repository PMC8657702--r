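test_that("model configuration enforces the three-layer contract", {
  expect_error(model_config(hidden_sizes = c(64L, 32L)), "three")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(lr_halving_patience = 0L), "patience")
  cfg <- model_config()
  expect_equal(cfg$hidden_sizes, c(2048L, 1024L, 512L))
  expect_equal(cfg$early_stop_patience, 10L)
})

test_that("parameter count matches the closed form and init is seeded", {
  cfg <- model_config(variant = "full", hidden_sizes = c(2048L, 1024L, 512L))
  m <- build_pcm_model(cfg, 768L, 256L)
  expected <- (768 + 256) * 2048 + 2048 * 1024 + 1024 * 512 + 512 * 1 +
    2048 + 1024 + 512 + 1
  expect_equal(m$n_params, expected)
  m2 <- build_pcm_model(cfg, 768L, 256L)
  expect_identical(m$nets, m2$nets)
  cfg2 <- model_config(variant = "full", hidden_sizes = c(2048L, 1024L, 512L),
                       seed = 2L)
  expect_false(identical(build_pcm_model(cfg2, 768L, 256L)$nets, m$nets))
})

test_that("the no-interaction variant has structurally separate channels", {
  cfg <- model_config(variant = "no_interaction", hidden_sizes = c(8L, 6L, 4L))
  m <- build_pcm_model(cfg, 10L, 5L)
  expect_named(m$nets, c("compound", "protein"))
  # the protein tower's first weight matrix sees only protein inputs
  expect_equal(nrow(m$nets$protein$W[[1]]), 5L)
  expect_equal(nrow(m$nets$compound$W[[1]]), 10L)
})

test_that("training overfits a linearly separable toy to MCC 1", {
  withr::with_seed(21L, {
    n <- 200L
    Xc <- matrix(rnorm(n * 6), n)
    Xp <- matrix(rnorm(n * 4), n)
  })
  y <- as.integer(Xc[, 1] + Xp[, 1] > 0)
  comp <- embedding_table(sprintf("c%03d", 1:n), Xc)
  prot_ids <- sprintf("p%03d", 1:n)
  prot <- embedding_table(prot_ids, Xp)
  tab <- activity_table(comp$ids, prot_ids, activity = as.numeric(y), label = y)
  sp <- split_random(tab, c(0.8, 0.1, 0.1), seed = 1L)
  cfg <- model_config(variant = "full", hidden_sizes = c(16L, 8L, 4L),
                      dropout = 0, max_epochs = 200L,
                      early_stop_patience = 200L, batch_size = 32L, seed = 3L)
  m <- train_pcm_model(build_pcm_model(cfg, 6L, 4L), sp, tab, comp, prot)
  p_train <- predict(m, tab[sp$train, c("compound_id", "protein_id")], comp, prot)
  expect_equal(mcc(y[sp$train], as.integer(p_train >= 0.5)), 1)
})

test_that("training is deterministic, restores best weights and stops early", {
  ds <- small_sim()
  sp <- split_random(ds$activity, seed = 2L)
  cfg <- tiny_model_config("full", seed = 7L)
  fit <- function() train_pcm_model(build_pcm_model(cfg, 12L, 6L), sp,
                                    ds$activity, ds$compound_embeddings,
                                    ds$protein_embeddings)
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$nets, m2$nets)
  expect_identical(m1$training_log, m2$training_log)
  # reported validation loss equals the minimum of the log
  expect_equal(m1$valid_loss, min(m1$training_log$valid_loss))
  pairs <- ds$activity[sp$test[1:5], c("compound_id", "protein_id")]
  expect_identical(predict(m1, pairs, ds$compound_embeddings, ds$protein_embeddings),
                   predict(m2, pairs, ds$compound_embeddings, ds$protein_embeddings))
  # early stopping: no more than patience epochs after the best one
  best_epoch <- which.min(m1$training_log$valid_loss)
  expect_lte(nrow(m1$training_log), best_epoch + cfg$early_stop_patience)
})

test_that("learning-rate halving fires on a validation plateau", {
  ds <- small_sim()
  sp <- split_random(ds$activity, seed = 2L)
  cfg <- model_config(variant = "full", hidden_sizes = c(24L, 16L, 8L),
                      max_epochs = 40L, lr_halving_patience = 2L,
                      early_stop_patience = 40L, batch_size = 64L, seed = 7L)
  m <- train_pcm_model(build_pcm_model(cfg, 12L, 6L), sp, ds$activity,
                       ds$compound_embeddings, ds$protein_embeddings)
  expect_true(min(m$training_log$lr) < cfg$learning_rate)
  expect_true(all(diff(m$training_log$lr) <= 0))
})

test_that("predictions are probabilities and missing ids are errors", {
  ds <- small_sim()
  sp <- split_random(ds$activity, seed = 4L)
  m <- train_pcm_model(build_pcm_model(tiny_model_config("full"), 12L, 6L),
                       sp, ds$activity, ds$compound_embeddings,
                       ds$protein_embeddings)
  pairs <- ds$activity[1:20, c("compound_id", "protein_id")]
  p <- predict(m, pairs, ds$compound_embeddings, ds$protein_embeddings)
  expect_true(all(p > 0 & p < 1))
  bad <- data.frame(compound_id = "nope", protein_id = pairs$protein_id[1])
  expect_error(predict(m, bad, ds$compound_embeddings, ds$protein_embeddings),
               "unknown id")
})

test_that("no-interaction predictions are exactly additive over 2x2 quartets", {
  ds <- small_sim(gamma = 3)
  sp <- split_random(ds$activity, seed = 5L)
  m <- train_pcm_model(build_pcm_model(tiny_model_config("no_interaction"),
                                       12L, 6L),
                       sp, ds$activity, ds$compound_embeddings,
                       ds$protein_embeddings)
  cids <- unique(ds$activity$compound_id)
  pids <- unique(ds$activity$protein_id)
  withr::with_seed(1L, {
    for (rep in 1:20) {
      cs <- sample(cids, 2L); ps <- sample(pids, 2L)
      quartet <- expand.grid(compound_id = cs, protein_id = ps,
                             stringsAsFactors = FALSE)
      p <- predict(m, quartet, ds$compound_embeddings, ds$protein_embeddings)
      expect_equal(p[1] + p[4], p[2] + p[3], tolerance = 1e-12)
    }
  })
  # the trained full model violates additivity on interaction-heavy data
  mf <- train_pcm_model(build_pcm_model(tiny_model_config("full"), 12L, 6L),
                        sp, ds$activity, ds$compound_embeddings,
                        ds$protein_embeddings)
  contrasts <- withr::with_seed(2L, vapply(1:20, function(i) {
    cs <- sample(cids, 2L); ps <- sample(pids, 2L)
    quartet <- expand.grid(compound_id = cs, protein_id = ps,
                           stringsAsFactors = FALSE)
    p <- predict(mf, quartet, ds$compound_embeddings, ds$protein_embeddings)
    abs(p[1] + p[4] - p[2] - p[3])
  }, numeric(1L)))
  expect_gt(max(contrasts), 1e-3)
})
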