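# Analysis arithmetic over a results matrix: descriptor-marginal means,
# full-vs-no-interaction percent improvement and its per-regime averages,
# and a paired Wilcoxon signed-rank test (exact by null enumeration for
# small n, normal approximation with continuity and tie correction above).

#' Round half away from zero
#'
#' Display rounding used throughout the comparison layer (3 decimals for
#' metrics, 1 for percentages, 0 for averaged percentages).  Computations
#' keep full precision; this is applied only when matching printed tables.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Marginal performance of a descriptor
#'
#' The unweighted mean of a metric over all descriptor combinations that
#' contain the given descriptor (as compound or protein side), for one
#' split regime.  Only full-variant rows enter the marginal.
#'
#' @param results a results `data.frame` (see [results_matrix()]) with
#'   columns `compound_descriptor`, `protein_descriptor`, `regime`,
#'   `variant` and the metric.
#' @param descriptor descriptor name to marginalise over.
#' @param regime split regime to restrict to.
#' @param metric metric column name (default `"mcc"`).
#' @return numeric scalar, full precision (use [round_half_up()] with 3
#'   digits for display).
#' @export
marginal_performance <- function(results, descriptor, regime, metric = "mcc") {
  sel <- results$regime == regime &
    (results$compound_descriptor == descriptor |
       results$protein_descriptor == descriptor)
  if ("variant" %in% names(results)) sel <- sel & results$variant == "full"
  if (!any(sel)) stop("descriptor '", descriptor, "' absent from results for regime '", regime, "'")
  mean(results[[metric]][sel])
}

#' Percent improvement of the full model over the baseline
#'
#' @param full,no_int numeric metric values (vectorised).
#' @return `100 * (full - no_int) / no_int`; display to one decimal with
#'   [round_half_up()].
#' @export
percent_improvement <- function(full, no_int) {
  if (any(no_int == 0)) stop("zero baseline value")
  100 * (full - no_int) / no_int
}

#' Average percent improvement over descriptor combinations
#'
#' For each (compound, protein) descriptor combination present in the
#' regime, computes the percent improvement of the full variant over the
#' no-interaction variant, then returns the unweighted mean (display at
#' integer rounding).  Each combination must contribute both variants.
#'
#' @param results a results `data.frame` with both variants per
#'   combination.
#' @param regime split regime.
#' @param metric metric column (default `"mcc"`).
#' @return numeric scalar, full precision.
#' @export
average_improvement <- function(results, regime, metric = "mcc") {
  sub <- results[results$regime == regime, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for regime '", regime, "'")
  combos <- unique(sub[, c("compound_descriptor", "protein_descriptor")])
  imps <- apply(combos, 1L, function(cp) {
    rows <- sub[sub$compound_descriptor == cp[[1L]] &
                  sub$protein_descriptor == cp[[2L]], , drop = FALSE]
    fu <- rows[[metric]][rows$variant == "full"]
    ni <- rows[[metric]][rows$variant == "no_interaction"]
    if (length(fu) == 0L || length(ni) == 0L)
      stop("combination ", cp[[1L]], " + ", cp[[2L]], " is missing a variant")
    percent_improvement(mean(fu), mean(ni))
  })
  mean(imps)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped before ranking (standard convention); tied
#' absolute differences receive mean ranks.  For `n <= exact_limit`
#' non-zero differences the p-value is computed by exact enumeration of
#' the 2^n sign-assignment null (via the generating-function recursion,
#' which remains exact under ties); above the limit a normal approximation
#' with continuity correction and tie correction is used.  Deterministic.
#'
#' @param paired_a,paired_b numeric vectors of equal length; at least 5
#'   non-zero differences are required.
#' @param alternative `"two.sided"` or `"greater"` (`a` tends to exceed
#'   `b`).
#' @param exact_limit largest `n` for exact enumeration (default 25).
#' @return a list with `statistic` (the positive-rank sum `V`), `p_value`,
#'   `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alternative = c("two.sided", "greater"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  if (length(paired_a) != length(paired_b)) stop("length mismatch")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences are zero")
  if (length(d) < 5L) stop("need at least 5 non-zero differences")
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2*V under random signs; doubled ranks are integers
    # even when ties produce half-integer mean ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- c(1, numeric(total))        # dist[w + 1] = #assignments with 2V = w
    for (rr in r2) {
      shifted <- c(numeric(rr), dist[seq_len(total + 1L - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(dist[(v2 + 1L):(total + 1L)])
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (alternative == "greater") {
      z <- (v - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    } else {
      z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Assemble a comparison report from a results matrix
#'
#' Computes (i) the marginal mean metric of every descriptor per regime,
#' (ii) the full-vs-no-interaction percent-improvement grid per
#' (combination, regime) with its per-regime averages when both variants
#' are present, and (iii) a paired Wilcoxon signed-rank test of full vs
#' no-interaction over folds/combinations per regime.
#'
#' @param results a results `data.frame` (see [results_matrix()]).
#' @param metric metric column (default `"mcc"`).
#' @param alpha_level significance level used when printing (default
#'   0.05).
#' @return an object of class `comparison_report` with elements
#'   `marginal`, `improvement`, `avg_improvement`, `wilcoxon`.
#' @export
comparison_report <- function(results, metric = "mcc", alpha_level = 0.05) {
  regimes <- unique(results$regime)
  descriptors <- setdiff(unique(c(results$compound_descriptor,
                                  results$protein_descriptor)), NA)
  marginal <- expand.grid(descriptor = descriptors, regime = regimes,
                          stringsAsFactors = FALSE)
  marginal$value <- mapply(function(d, g)
    marginal_performance(results, d, g, metric),
    marginal$descriptor, marginal$regime)

  both <- all(c("full", "no_interaction") %in% results$variant)
  improvement <- NULL; avg_improvement <- NULL; wilcox <- NULL
  if (both) {
    improvement <- do.call(rbind, lapply(regimes, function(g) {
      sub <- results[results$regime == g, , drop = FALSE]
      combos <- unique(sub[, c("compound_descriptor", "protein_descriptor")])
      data.frame(combos, regime = g,
                 pct_improvement = apply(combos, 1L, function(cp) {
                   rows <- sub[sub$compound_descriptor == cp[[1L]] &
                                 sub$protein_descriptor == cp[[2L]], , drop = FALSE]
                   percent_improvement(mean(rows[[metric]][rows$variant == "full"]),
                                       mean(rows[[metric]][rows$variant == "no_interaction"]))
                 }),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    avg_improvement <- vapply(regimes, function(g)
      average_improvement(results, g, metric), numeric(1L))
    names(avg_improvement) <- regimes
    wilcox <- lapply(regimes, function(g) {
      sub <- results[results$regime == g, , drop = FALSE]
      fold <- if ("fold" %in% names(sub)) sub$fold else 0L
      key <- interaction(sub$compound_descriptor, sub$protein_descriptor,
                         fold, drop = TRUE)
      fu <- tapply(sub[[metric]][sub$variant == "full"],
                   droplevels(key[sub$variant == "full"]), mean)
      ni <- tapply(sub[[metric]][sub$variant == "no_interaction"],
                   droplevels(key[sub$variant == "no_interaction"]), mean)
      shared <- intersect(names(fu), names(ni))
      if (length(shared) < 5L) return(NULL)
      wilcoxon_signed_rank(fu[shared], ni[shared], alternative = "greater")
    })
    names(wilcox) <- regimes
  }
  structure(list(marginal = marginal, improvement = improvement,
                 avg_improvement = avg_improvement, wilcoxon = wilcox,
                 metric = metric, alpha_level = alpha_level),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (metric:", x$metric, ")\n\nMarginal performance:\n")
  m <- x$marginal
  m$value <- round_half_up(m$value, 3L)
  print(m, row.names = FALSE)
  if (!is.null(x$improvement)) {
    cat("\nPercent improvement (full vs no-interaction):\n")
    im <- x$improvement
    im$pct_improvement <- round_half_up(im$pct_improvement, 1L)
    print(im, row.names = FALSE)
    cat("\nAverage improvement per regime:\n")
    print(round_half_up(x$avg_improvement, 0L))
    for (g in names(x$wilcoxon)) {
      w <- x$wilcoxon[[g]]
      if (is.null(w)) next
      cat(sprintf("Wilcoxon (full > no-interaction, %s): V = %g, p = %.3g%s\n",
                  g, w$statistic, w$p_value,
                  ifelse(w$p_value < x$alpha_level, " *", "")))
    }
  }
  invisible(x)
}
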