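# Evaluation metrics: Matthews correlation coefficient, BEDROC early
# enrichment, per-protein top-decile overlap, and the per-split evaluation
# bundle consumed by the comparison layer.

#' Confusion counts from binary truth and prediction
#'
#' @param truth,predicted binary (0/1) vectors of equal length.
#' @return a list of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (any(!(truth %in% c(0L, 1L))) || any(!(predicted %in% c(0L, 1L))))
    stop("truth and predicted must be binary (0/1)")
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, a
#' confusion-matrix correlation in `[-1, 1]` that remains informative on
#' unbalanced data.  When any marginal is zero the score is undefined and
#' the conventional value 0 is returned with a warning.
#'
#' @param counts a [confusion_counts()] object, or a binary truth vector
#'   (in which case `predicted` must be given).
#' @param predicted optional binary prediction vector.
#' @return numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(counts, predicted = NULL) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts, predicted)
  with(counts, {
    n <- tp + fp + tn + fn
    if (n == 0L) stop("all-zero confusion counts")
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (denom == 0) {
      warning("zero marginal in confusion counts; returning MCC = 0 by convention")
      return(0)
    }
    (tp * tn - fp * fn) / denom
  })
}

#' BEDROC early-enrichment score
#'
#' Boltzmann-enhanced discrimination of ROC: actives are credited with an
#' exponential weight `exp(-alpha * rank / n)` so that early ranks dominate
#' the score, which is then rescaled to `[0, 1]` with the standard
#' closed-form normalisation (exact for the discrete geometric sum: a
#' perfect ranking scores exactly 1).  At the default `alpha = 20`, 80% of
#' the total rank weight falls in the top 8% of a long ranking.  Tied
#' scores receive the mean exponential weight of their rank block, making
#' the score invariant to input order among ties.
#'
#' @param scores numeric predicted scores (higher = ranked earlier).
#' @param labels binary (0/1) activity labels.
#' @param alpha early-recognition weighting parameter (> 0).
#' @return numeric scalar in `[0, 1]`.
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!(labels %in% c(0L, 1L)))) stop("labels must be binary (0/1)")
  if (alpha <= 0) stop("alpha must be positive")
  n <- length(scores)
  n_act <- sum(labels)
  if (n_act == 0L || n_act == n)
    stop("BEDROC needs at least one active and one inactive")
  ra <- n_act / n
  # descending-score ranks; ties get the mean weight of their block
  r <- rank(-scores, ties.method = "min")
  w_by_rank <- exp(-alpha * seq_len(n) / n)
  block_sizes <- table(r)
  block_mean <- vapply(as.integer(names(block_sizes)), function(start) {
    len <- block_sizes[[as.character(start)]]
    mean(w_by_rank[start:(start + len - 1L)])
  }, numeric(1L))
  names(block_mean) <- names(block_sizes)
  s <- sum(block_mean[as.character(r)][labels == 1L])
  rie <- s / (n_act * (1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  val <- rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  min(max(val, 0), 1)
}

#' Fraction of BEDROC rank weight in the top of a ranking
#'
#' The share of the total exponential rank weight
#' `sum_i exp(-alpha * i / n)` carried by the first `top_fraction` of
#' ranks.  As `n` grows this approaches `1 - exp(-top_fraction * alpha)`;
#' at the default `alpha = 20` the top 8% of ranks carries about 80% of
#' the weight, which is the sense in which BEDROC is an early-recognition
#' score.
#'
#' @param top_fraction fraction of the ranking counted as "top".
#' @param alpha BEDROC weighting parameter.
#' @param n ranking length (`NULL` for the large-`n` closed form).
#' @return numeric scalar in (0, 1).
#' @export
bedroc_weight_fraction <- function(top_fraction = 0.08, alpha = 20, n = NULL) {
  stopifnot(top_fraction > 0, top_fraction < 1, alpha > 0)
  if (is.null(n)) return(1 - exp(-top_fraction * alpha))
  i <- seq_len(n)
  w <- exp(-alpha * i / n)
  sum(w[i <= top_fraction * n]) / sum(w)
}

#' Per-protein overlap of true and predicted top activity deciles
#'
#' For each protein with at least `min_compounds` measured compounds,
#' computes the overlap between the top `top_fraction` of compounds ranked
#' by measured activity and the top `top_fraction` ranked by predicted
#' score, as a fraction of the decile size `ceiling(top_fraction * n)`.
#' Proteins below the compound threshold are omitted (for small panels the
#' statistic is not meaningful).  Ties are broken by input order,
#' deterministically.
#'
#' @param truth numeric measured activities.
#' @param prediction numeric predicted scores, same length.
#' @param protein_ids character protein of each measurement.
#' @param min_compounds minimum compounds per protein (default 100).
#' @param top_fraction fraction defining the decile (default 0.1).
#' @return named numeric vector (protein -> overlap fraction); empty if no
#'   protein qualifies.
#' @export
top_decile_overlap <- function(truth, prediction, protein_ids,
                               min_compounds = 100L, top_fraction = 0.1) {
  if (length(truth) != length(prediction) ||
      length(truth) != length(protein_ids)) stop("length mismatch")
  out <- c()
  for (prot in unique(protein_ids)) {
    sel <- which(protein_ids == prot)
    if (length(sel) < min_compounds) next
    k <- ceiling(top_fraction * length(sel))
    top_truth <- sel[order(-truth[sel], seq_along(sel))][seq_len(k)]
    top_pred <- sel[order(-prediction[sel], seq_along(sel))][seq_len(k)]
    out[prot] <- length(intersect(top_truth, top_pred)) / k
  }
  out
}

#' Evaluate a trained model on the test partition of a split
#'
#' Computes MCC at a probability threshold (default 0.5) and BEDROC on the
#' score-ranked test set.  If the test partition contains a single class,
#' BEDROC is undefined and reported as `NA` with a message.
#'
#' @param model a trained `pcm_model`.
#' @param split a `split_assignment` with a non-empty test partition.
#' @param table a labelled [activity_table()].
#' @param compound_embeddings,protein_embeddings [embedding_table()]s.
#' @param threshold decision threshold on the predicted probability.
#' @param alpha BEDROC weighting parameter.
#' @param compound_descriptor,protein_descriptor optional descriptor names
#'   recorded in the result for downstream aggregation.
#' @return an `evaluation_result`: list with `regime`, `fold`, `variant`,
#'   descriptor names, `mcc`, `bedroc`, `n_test`, `counts`, `seed`.
#' @export
evaluate_model <- function(model, split, table, compound_embeddings,
                           protein_embeddings, threshold = 0.5, alpha = 20,
                           compound_descriptor = NA_character_,
                           protein_descriptor = NA_character_) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (length(split$test) == 0L) stop("empty test partition")
  te <- resolve_xy(split$test, table, compound_embeddings, protein_embeddings)
  p <- model_probs(model, te$Xc, te$Xp)
  counts <- confusion_counts(te$y, as.integer(p >= threshold))
  bed <- if (sum(te$y) == 0L || sum(te$y) == length(te$y)) {
    message("single-class test partition: BEDROC omitted")
    NA_real_
  } else bedroc(p, te$y, alpha = alpha)
  structure(list(regime = split$regime, fold = split$fold,
                 variant = model$config$variant,
                 compound_descriptor = compound_descriptor,
                 protein_descriptor = protein_descriptor,
                 mcc = suppressWarnings(mcc(counts)), bedroc = bed,
                 n_test = length(split$test), counts = counts,
                 seed = split$seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result [%s fold %d, %s]: MCC %.3f, BEDROC %s, n_test %d\n",
              x$regime, x$fold, x$variant, x$mcc,
              ifelse(is.na(x$bedroc), "NA", sprintf("%.3f", x$bedroc)),
              x$n_test))
  invisible(x)
}

#' Bind evaluation results into a results matrix
#'
#' @param results a list of `evaluation_result` objects.
#' @return a `data.frame` with one row per result, the input format of the
#'   comparison layer.
#' @export
results_matrix <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(compound_descriptor = r$compound_descriptor,
               protein_descriptor = r$protein_descriptor,
               regime = r$regime, fold = r$fold, variant = r$variant,
               mcc = r$mcc, bedroc = r$bedroc, n_test = r$n_test,
               seed = r$seed, stringsAsFactors = FALSE)))
}
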