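# Train/validation/test partitions of an activity table under three regimes
# of increasing difficulty, plus a nearest-neighbour split-difficulty
# diagnostic.  Validation records are always carved from the training side,
# never from held-out clusters or proteins, so that early stopping cannot
# see test-like matter.

new_split_assignment <- function(regime, fold, train, valid, test,
                                 held_out, seed, n_records) {
  train <- unname(as.integer(train)); valid <- unname(as.integer(valid))
  test <- unname(as.integer(test))
  idx <- sort(c(train, valid, test))
  if (!identical(idx, seq_len(n_records)))
    stop("train/valid/test must partition the records")
  structure(list(regime = regime, fold = as.integer(fold),
                 train = sort(train), valid = sort(valid), test = sort(test),
                 held_out = held_out, seed = as.integer(seed),
                 n_records = as.integer(n_records)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment [%s, fold %d, seed %d]: %d train / %d valid / %d test\n",
              x$regime, x$fold, x$seed,
              length(x$train), length(x$valid), length(x$test)))
  invisible(x)
}

# carve a validation set out of the non-test indices
carve_valid <- function(rest, valid_fraction) {
  n_valid <- max(1L, round(valid_fraction * length(rest)))
  if (n_valid >= length(rest)) stop("validation fraction leaves no training records")
  vi <- sample(length(rest), n_valid)
  list(train = rest[-vi], valid = rest[vi])
}

#' Random split of bioactivity measurements
#'
#' Randomly divides records into train, validation and test sets with the
#' requested fractions (sizes within one record of the target).  Records
#' from the same compound or protein may appear on both sides, which makes
#' this the easiest regime.
#'
#' @param table an [activity_table()].
#' @param fractions numeric length-3 vector `(train, valid, test)`;
#'   positive, summing to 1.
#' @param seed integer seed; the assignment is reproducible for a fixed
#'   seed.
#' @return a `split_assignment`.
#' @export
split_random <- function(table, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 records")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1")
  withr::with_seed(seed, {
    ord <- sample(n)
    n_test <- round(fractions[3L] * n)
    n_valid <- round(fractions[2L] * n)
    if (n_test < 1L || n_valid < 1L || n_test + n_valid >= n)
      stop("fractions leave an empty partition")
    test <- ord[seq_len(n_test)]
    valid <- ord[n_test + seq_len(n_valid)]
    train <- ord[-seq_len(n_test + n_valid)]
  })
  new_split_assignment("random", 0L, train, valid, test, NULL, seed, n)
}

#' Cluster compounds by descriptor similarity
#'
#' k-means on length-normalised descriptor vectors.  On the unit sphere,
#' squared Euclidean distance is proportional to cosine distance, so the
#' clustering groups compounds by descriptor direction.  Deterministic for
#' a fixed seed.
#'
#' @param embeddings an [embedding_table()] of compound vectors (zero
#'   vectors are an error).
#' @param k number of clusters (default 10); `2 <= k <=` number of
#'   compounds.
#' @param seed integer seed.
#' @return a `compound_clustering`: list with `compound_ids`, `cluster_of`
#'   (named integer vector), `k`, `metric`.
#' @export
cluster_compounds <- function(embeddings, k = 10L, seed = 1L) {
  k <- as.integer(k)
  n <- length(embeddings$ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of compounds")
  nrm <- sqrt(rowSums(embeddings$vectors^2))
  if (any(nrm == 0)) stop("zero vector(s): cosine geometry undefined")
  unit <- embeddings$vectors / nrm
  uniq <- unique(unit)
  if (nrow(uniq) < k)
    stop("k exceeds the number of distinct compound vectors")
  # several seeded starts from distinct rows (duplicated points would break
  # kmeans' own center sampling); keep the best by total within-ss
  km <- withr::with_seed(seed, {
    best <- NULL
    for (s in seq_len(5L)) {
      ctrs <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
      fit <- tryCatch(
        stats::kmeans(unit, centers = ctrs, iter.max = 100L),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
    if (is.null(best))
      best <- stats::kmeans(unit, centers = uniq[sample.int(nrow(uniq), k), ,
                                                 drop = FALSE],
                            iter.max = 100L, algorithm = "Lloyd")
    best
  })
  cluster_of <- as.integer(km$cluster)
  names(cluster_of) <- embeddings$ids
  structure(list(compound_ids = embeddings$ids, cluster_of = cluster_of,
                 k = k, metric = "cosine-on-descriptors", seed = as.integer(seed)),
            class = "compound_clustering")
}

#' @export
print.compound_clustering <- function(x, ...) {
  cat(sprintf("compound_clustering: %d compounds in %d clusters (%s)\n",
              length(x$compound_ids), x$k, x$metric))
  print(table(x$cluster_of))
  invisible(x)
}

#' Leave-compound-cluster-out split
#'
#' All records whose compound belongs to the held-out cluster form the test
#' set; the remaining records are split randomly into train and validation.
#' Iterating `test_cluster` over `1..k` yields a k-fold cross-validation in
#' which every record appears in exactly one test set.
#'
#' @param table an [activity_table()]; every compound must appear in
#'   `clustering`.
#' @param clustering a [cluster_compounds()] result.
#' @param test_cluster cluster index in `1..k` to hold out.
#' @param valid_fraction fraction of the remaining records used for
#'   validation (default 0.125, i.e. 1/8 of the non-test side).
#' @param seed integer seed for the train/valid carve.
#' @return a `split_assignment` with `held_out` set to the cluster index.
#' @export
split_lcco <- function(table, clustering, test_cluster,
                       valid_fraction = 0.125, seed = 1L) {
  test_cluster <- as.integer(test_cluster)
  if (test_cluster < 1L || test_cluster > clustering$k)
    stop("test_cluster must be in 1..k")
  unknown <- setdiff(unique(table$compound_id), clustering$compound_ids)
  if (length(unknown) > 0L)
    stop("compound(s) missing from clustering: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  rec_cluster <- clustering$cluster_of[table$compound_id]
  test <- which(rec_cluster == test_cluster)
  if (length(test) == 0L) stop("held-out cluster has no records")
  rest <- which(rec_cluster != test_cluster)
  if (length(rest) < 2L) stop("too few records outside the held-out cluster")
  tv <- withr::with_seed(seed, carve_valid(rest, valid_fraction))
  new_split_assignment("lcco", test_cluster, tv$train, tv$valid, test,
                       list(cluster = test_cluster), seed, nrow(table))
}

#' Leave-protein-out split
#'
#' Proteins are partitioned randomly (by `seed`) into `n_folds` groups; all
#' records of the requested fold's proteins form the test set and the rest
#' are split into train and validation.  Unioning the test sets over all
#' folds covers every record exactly once.
#'
#' @param table an [activity_table()].
#' @param n_folds number of protein folds; at most the number of distinct
#'   proteins.
#' @param fold fold index in `1..n_folds`.
#' @param valid_fraction fraction of non-test records used for validation.
#' @param seed integer seed; the protein partition depends only on
#'   (`seed`, `n_folds`), so different `fold` values index the same
#'   partition.
#' @return a `split_assignment` with `held_out` listing the test proteins.
#' @export
split_lpo <- function(table, n_folds, fold, valid_fraction = 0.125, seed = 1L) {
  n_folds <- as.integer(n_folds); fold <- as.integer(fold)
  prots <- sort(unique(table$protein_id))
  if (n_folds > length(prots)) stop("n_folds exceeds the number of proteins")
  if (fold < 1L || fold > n_folds) stop("fold must be in 1..n_folds")
  groups <- withr::with_seed(seed, {
    perm <- sample(length(prots))
    split(prots[perm], rep_len(seq_len(n_folds), length(prots)))
  })
  held <- groups[[fold]]
  test <- which(table$protein_id %in% held)
  if (length(test) == 0L) stop("held-out proteins have no records")
  rest <- which(!(table$protein_id %in% held))
  if (length(rest) < 2L) stop("too few records outside the held-out proteins")
  tv <- withr::with_seed(seed + fold, carve_valid(rest, valid_fraction))
  new_split_assignment("lpo", fold, tv$train, tv$valid, test,
                       list(proteins = sort(held)), seed, nrow(table))
}

#' Mean nearest-neighbour cosine distance from test to train
#'
#' For each test vector, computes one minus its maximum cosine similarity
#' to any training vector and returns the mean.  Larger values mean the
#' test chemistry is further from anything seen in training, i.e. a harder
#' split.  Ties are irrelevant to the value (the maximum similarity is
#' unique as a number); zero vectors are an error because cosine geometry
#' is undefined for them.
#'
#' @param test_embeddings,train_embeddings [embedding_table()]s of equal
#'   dimension.
#' @return numeric scalar, the mean nearest-neighbour cosine distance.
#' @export
nn_distance_diagnostic <- function(test_embeddings, train_embeddings) {
  if (test_embeddings$dim != train_embeddings$dim)
    stop("dimension mismatch between test and train embeddings")
  if (length(test_embeddings$ids) == 0L || length(train_embeddings$ids) == 0L)
    stop("empty embedding table")
  unit <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("zero vector(s): cosine distance undefined")
    m / nrm
  }
  sims <- unit(test_embeddings$vectors) %*% t(unit(train_embeddings$vectors))
  mean(1 - apply(sims, 1L, max))
}

#' Write / read a split assignment as a delimited table
#'
#' The on-disk format has one row per record: `record_index`,
#' `compound_id`, `protein_id`, `partition` (train/valid/test), `fold`,
#' `regime`, `seed` - enough to reproduce a run exactly.
#'
#' @param split a `split_assignment`.
#' @param table the [activity_table()] the split indexes.
#' @param path output file (tab-separated).
#' @return `path` invisibly for the writer; a `split_assignment` for the
#'   reader.
#' @export
write_split <- function(split, table, path) {
  part <- character(split$n_records)
  part[split$train] <- "train"; part[split$valid] <- "valid"; part[split$test] <- "test"
  df <- data.frame(record_index = seq_len(split$n_records),
                   compound_id = table$compound_id,
                   protein_id = table$protein_id,
                   partition = part,
                   fold = split$fold, regime = split$regime, seed = split$seed,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          showProgress = FALSE)
  need <- c("record_index", "partition", "fold", "regime", "seed")
  if (!all(need %in% names(df))) stop("not a split file: ", path)
  new_split_assignment(df$regime[1L], df$fold[1L],
                       df$record_index[df$partition == "train"],
                       df$record_index[df$partition == "valid"],
                       df$record_index[df$partition == "test"],
                       NULL, df$seed[1L], nrow(df))
}
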