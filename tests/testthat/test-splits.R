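test_that("random splits hit requested sizes and are seed-reproducible", {
  tab <- small_sim()$activity[1:100, ]
  class(tab) <- c("activity_table", "data.frame")
  sp <- split_random(tab, c(0.7, 0.1, 0.2), seed = 1L)
  expect_length(sp$test, 20L)
  expect_length(sp$valid, 10L)
  expect_length(sp$train, 70L)
  expect_identical(sp, split_random(tab, c(0.7, 0.1, 0.2), seed = 1L))
  sp2 <- split_random(tab, c(0.7, 0.1, 0.2), seed = 2L)
  expect_false(identical(sp$test, sp2$test))
  expect_error(split_random(tab[1:2, ], seed = 1L), "at least 3")
  expect_error(split_random(tab, c(0.5, 0.5, 0.5), seed = 1L), "summing to 1")
})

test_that("all regimes produce disjoint covering partitions (property)", {
  ds <- small_sim()
  clust <- cluster_compounds(ds$compound_embeddings, k = 4L, seed = 2L)
  for (seed in 1:5) {
    sps <- list(
      split_random(ds$activity, seed = seed),
      split_lcco(ds$activity, clust, (seed %% 4L) + 1L, seed = seed),
      split_lpo(ds$activity, 4L, (seed %% 4L) + 1L, seed = seed))
    for (sp in sps) {
      idx <- c(sp$train, sp$valid, sp$test)
      expect_equal(sort(idx), seq_len(nrow(ds$activity)))
      expect_equal(anyDuplicated(idx), 0L)
    }
  }
})

test_that("k-means clustering recovers separated blobs and handles edges", {
  # two well-separated blobs on the sphere
  withr::with_seed(4L, {
    c1 <- c(1, rep(0, 9)); c2 <- c(-1, rep(0, 9))
    pts <- rbind(
      matrix(rep(c1, 20), 20, byrow = TRUE) + matrix(rnorm(200, sd = 0.05), 20),
      matrix(rep(c2, 20), 20, byrow = TRUE) + matrix(rnorm(200, sd = 0.05), 20))
  })
  emb <- embedding_table(sprintf("m%02d", 1:40), pts)
  cl <- cluster_compounds(emb, k = 2L, seed = 1L)
  # brute-force nearest-centroid labelling on the normalised points
  unit <- pts / sqrt(rowSums(pts^2))
  truth <- as.integer(unit[, 1] < 0) + 1L
  agree <- max(mean(cl$cluster_of == truth), mean(cl$cluster_of != truth))
  expect_equal(agree, 1)
  # duplicated vectors land together; k = n gives singletons
  dup <- embedding_table(c("a", "b", "c", "d"),
                         rbind(c1, c1, c2, c2))
  cld <- cluster_compounds(dup, k = 2L, seed = 1L)
  expect_equal(cld$cluster_of[["a"]], cld$cluster_of[["b"]])
  sing <- cluster_compounds(emb, k = 40L, seed = 1L)
  expect_equal(sort(as.integer(table(sing$cluster_of))), rep(1L, 40L))
  expect_error(cluster_compounds(emb, k = 41L), "exceeds")
  expect_identical(cl$cluster_of,
                   cluster_compounds(emb, k = 2L, seed = 1L)$cluster_of)
})

test_that("LCCO never leaks a held-out cluster and folds tile the records", {
  ds <- small_sim()
  clust <- cluster_compounds(ds$compound_embeddings, k = 4L, seed = 5L)
  seen_test <- integer(0)
  for (f in 1:4) {
    sp <- split_lcco(ds$activity, clust, f, seed = 9L)
    cl_of_rec <- clust$cluster_of[ds$activity$compound_id]
    expect_true(all(cl_of_rec[sp$test] == f))
    expect_true(all(cl_of_rec[c(sp$train, sp$valid)] != f))
    expect_length(intersect(ds$activity$compound_id[sp$test],
                            ds$activity$compound_id[sp$train]), 0L)
    seen_test <- c(seen_test, sp$test)
  }
  expect_equal(sort(seen_test), seq_len(nrow(ds$activity)))
})

test_that("LPO holds out whole proteins and folds tile the records", {
  ds <- small_sim()
  seen <- integer(0)
  for (f in 1:4) {
    sp <- split_lpo(ds$activity, 4L, f, seed = 3L)
    expect_length(intersect(ds$activity$protein_id[sp$test],
                            ds$activity$protein_id[c(sp$train, sp$valid)]), 0L)
    seen <- c(seen, sp$test)
  }
  expect_equal(sort(seen), seq_len(nrow(ds$activity)))
  # 12 proteins in 6 folds: each fold holds out exactly 2 proteins
  sp <- split_lpo(ds$activity, 6L, 1L, seed = 3L)
  expect_length(sp$held_out$proteins, 2L)
  expect_error(split_lpo(ds$activity, 6L, 7L, seed = 3L), "fold")
  expect_error(split_lpo(ds$activity, 100L, 1L, seed = 3L), "exceeds")
})

test_that("nearest-neighbour diagnostic matches an exhaustive scan", {
  pool <- toy_embeddings(letters[1:5], 6L)
  subset3 <- embedding_table(letters[1:3], pool$vectors[1:3, ])
  expect_equal(nn_distance_diagnostic(subset3, pool), 0)
  tr <- embedding_table(c("t1", "t2"), rbind(c(1, 0, 0), c(0, 1, 0)))
  te <- embedding_table("q", matrix(c(0, 0, 1), 1))
  expect_equal(nn_distance_diagnostic(te, tr), 1)

  withr::with_seed(8L, {
    test_e <- embedding_table(paste0("q", 1:3), matrix(rnorm(18), 3))
    train_e <- embedding_table(paste0("t", 1:5), matrix(rnorm(30), 5))
  })
  brute <- mean(vapply(1:3, function(i) {
    x <- test_e$vectors[i, ]
    1 - max(vapply(1:5, function(j) {
      y <- train_e$vectors[j, ]
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }, numeric(1L)))
  }, numeric(1L)))
  expect_equal(nn_distance_diagnostic(test_e, train_e), brute, tolerance = 1e-12)

  expect_error(nn_distance_diagnostic(test_e, toy_embeddings("a", 3L)),
               "mismatch")
  z <- embedding_table("z", matrix(0, 1, 6))
  expect_error(nn_distance_diagnostic(z, train_e), "zero vector")
})

test_that("split files round-trip through the on-disk format", {
  ds <- small_sim()
  sp <- split_random(ds$activity, seed = 6L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, ds$activity, f)
  back <- read_split(f)
  expect_equal(back$train, sp$train)
  expect_equal(back$valid, sp$valid)
  expect_equal(back$test, sp$test)
  expect_equal(back$regime, sp$regime)
  expect_equal(back$seed, sp$seed)
})
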