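# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# literal transcription of the BEDROC closed form with explicit loops and
# tied-block weight averaging
bedroc_brute <- function(scores, labels, alpha = 20) {
  n <- length(scores)
  n_act <- sum(labels)
  ra <- n_act / n
  r <- rank(-scores, ties.method = "min")
  s <- 0
  for (i in which(labels == 1)) {
    block <- which(r == r[i])
    w <- 0
    for (j in seq_along(block)) w <- w + exp(-alpha * (r[i] + j - 1) / n)
    s <- s + w / length(block)
  }
  rie <- s / (n_act * (1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  rie * ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# exact signed-rank null by enumerating all 2^n sign vectors
wilcoxon_brute <- function(a, b, alternative) {
  d <- (a - b); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- grid %*% r
  p_ge <- mean(vs >= v - 1e-9)
  p_le <- mean(vs <= v + 1e-9)
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

# exhaustive double-loop nearest-neighbour cosine scan
nn_brute <- function(test_emb, train_emb) {
  nt <- length(test_emb$ids)
  mean(vapply(seq_len(nt), function(i) {
    x <- test_emb$vectors[i, ]
    1 - max(vapply(seq_along(train_emb$ids), function(j) {
      y <- train_emb$vectors[j, ]
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }, numeric(1L)))
  }, numeric(1L)))
}
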