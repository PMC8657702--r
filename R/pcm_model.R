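# Feedforward PCM classifier and its no-interaction-terms baseline.
#
# The full variant concatenates the compound and protein vectors and feeds
# them through three fully connected ReLU layers into a single sigmoid
# output.  The no-interaction variant keeps the two channels separate: one
# tower sees only the compound vector, one only the protein vector, each
# ends in its own sigmoid, and the model prediction is the arithmetic mean
# of the two tower probabilities.  Because no weight ever connects the two
# channels, the baseline can at best recover per-compound and per-protein
# bias, never a compound-protein interaction: its 2x2 prediction tables are
# exactly additive.
#
# Training minimises binary cross-entropy with Adam, halves the learning
# rate when validation loss plateaus, stops early after a patience window
# without validation improvement and restores the best-validation weights.

#' Model configuration
#'
#' @param variant `"full"` (concatenated input) or `"no_interaction"`
#'   (dual towers averaged on the probability scale).
#' @param hidden_sizes integer vector of exactly three hidden-layer widths.
#'   For the no-interaction variant each tower uses half these widths so
#'   the two variants have comparable capacity.
#' @param dropout dropout probability on hidden activations, in `[0, 1)`.
#' @param learning_rate initial Adam learning rate.
#' @param lr_halving_patience epochs without validation improvement before
#'   the learning rate is halved.
#' @param early_stop_patience epochs without validation improvement before
#'   training stops (default 10).
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param average scale on which the no-interaction towers are combined:
#'   `"probability"` (default; the mean of the two sigmoid outputs) or
#'   `"logit"` (sigmoid of the mean tower logit).
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout; fixed seed and data give bit-identical weights.
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("full", "no_interaction"),
                         hidden_sizes = c(2048L, 1024L, 512L),
                         dropout = 0.25,
                         learning_rate = 1e-3,
                         lr_halving_patience = 5L,
                         early_stop_patience = 10L,
                         max_epochs = 300L,
                         batch_size = 256L,
                         average = c("probability", "logit"),
                         seed = 1L) {
  variant <- match.arg(variant)
  average <- match.arg(average)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) != 3L || any(hidden_sizes < 1L))
    stop("hidden_sizes must be exactly three positive integers")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (lr_halving_patience < 1L || early_stop_patience < 1L)
    stop("patience values must be >= 1")
  structure(list(variant = variant, hidden_sizes = hidden_sizes,
                 dropout = dropout, learning_rate = learning_rate,
                 lr_halving_patience = as.integer(lr_halving_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 average = average, seed = as.integer(seed)),
            class = "model_config")
}

sigm <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# ---- minimal MLP engine (list of weight matrices, ReLU hidden layers) ----

net_new <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])), sizes[l])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

net_n_params <- function(net)
  sum(vapply(net$W, length, numeric(1L))) + sum(lengths(net$b))

# forward pass; with training = TRUE applies inverted dropout to hidden
# activations and records the masks for the backward pass
net_fwd <- function(net, Z, drop_p = 0, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L); Zs <- vector("list", L - 1L)
  masks <- vector("list", L - 1L)
  A[[1L]] <- Z
  for (l in seq_len(L - 1L)) {
    Zs[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    H <- pmax(Zs[[l]], 0)
    if (training && drop_p > 0) {
      masks[[l]] <- matrix(stats::runif(length(H)) >= drop_p, nrow(H)) / (1 - drop_p)
      H <- H * masks[[l]]
    }
    A[[l + 1L]] <- H
  }
  logit <- drop(A[[L]] %*% net$W[[L]]) + net$b[[L]]
  list(A = A, Zs = Zs, masks = masks, logit = logit)
}

# backward pass from d(loss)/d(logit); returns per-layer gradients
net_bwd <- function(net, fw, dlogit) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dz <- matrix(dlogit, ncol = 1L)
  gW[[L]] <- crossprod(fw$A[[L]], dz)
  gb[[L]] <- sum(dz)
  dA <- dz %*% t(net$W[[L]])
  for (l in seq(L - 1L, 1L)) {
    if (!is.null(fw$masks[[l]])) dA <- dA * fw$masks[[l]]
    dZ <- dA * (fw$Zs[[l]] > 0)
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dA <- dZ %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb)
}

adam_new <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(x) x * 0), vb = lapply(net$b, function(x) x * 0))
}

adam_step <- function(net, st, gr, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * gr$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * gr$gW[[l]]^2
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * gr$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * gr$gb[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / (1 - beta1^t)) /
      (sqrt(st$vW[[l]] / (1 - beta2^t)) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / (1 - beta1^t)) /
      (sqrt(st$vb[[l]] / (1 - beta2^t)) + eps)
  }
  list(net = net, st = st)
}

# ---- public model surface ----

#' Build an (untrained) PCM model
#'
#' @param config a [model_config()].
#' @param compound_dim,protein_dim input dimensionalities.
#' @return an object of class `pcm_model` with seeded initial weights; the
#'   same config and seed always give identical initial weights.
#' @export
build_pcm_model <- function(config, compound_dim, protein_dim) {
  stopifnot(inherits(config, "model_config"))
  compound_dim <- as.integer(compound_dim); protein_dim <- as.integer(protein_dim)
  if (compound_dim < 1L || protein_dim < 1L) stop("input dimensions must be positive")
  nets <- withr::with_seed(config$seed, {
    if (config$variant == "full") {
      list(full = net_new(c(compound_dim + protein_dim, config$hidden_sizes, 1L)))
    } else {
      tower <- pmax(1L, as.integer(ceiling(config$hidden_sizes / 2)))
      list(compound = net_new(c(compound_dim, tower, 1L)),
           protein = net_new(c(protein_dim, tower, 1L)))
    }
  })
  structure(list(config = config, compound_dim = compound_dim,
                 protein_dim = protein_dim, nets = nets,
                 n_params = sum(vapply(nets, net_n_params, numeric(1L))),
                 trained = FALSE, training_log = NULL),
            class = "pcm_model")
}

#' @export
print.pcm_model <- function(x, ...) {
  cat(sprintf("pcm_model [%s]: compound_dim %d, protein_dim %d, %d parameters, %s\n",
              x$config$variant, x$compound_dim, x$protein_dim, x$n_params,
              if (x$trained) "trained" else "untrained"))
  if (x$trained)
    cat(sprintf("  best validation loss %.5f after %d epoch(s)\n",
                min(x$training_log$valid_loss), nrow(x$training_log)))
  invisible(x)
}

# resolve the feature matrices and labels for a set of record indices
resolve_xy <- function(idx, table, compound_embeddings, protein_embeddings) {
  cid <- table$compound_id[idx]; pid <- table$protein_id[idx]
  miss_c <- setdiff(unique(cid), compound_embeddings$ids)
  miss_p <- setdiff(unique(pid), protein_embeddings$ids)
  if (length(miss_c) > 0L)
    stop("missing compound embedding(s): ", paste(utils::head(miss_c, 5L), collapse = ", "))
  if (length(miss_p) > 0L)
    stop("missing protein embedding(s): ", paste(utils::head(miss_p, 5L), collapse = ", "))
  y <- table$label[idx]
  if (anyNA(y)) stop("unlabeled record(s); run binarize() first")
  list(Xc = compound_embeddings$vectors[cid, , drop = FALSE],
       Xp = protein_embeddings$vectors[pid, , drop = FALSE],
       y = as.numeric(y))
}

model_probs <- function(model, Xc, Xp) {
  unname(model_probs_(model, Xc, Xp))
}

model_probs_ <- function(model, Xc, Xp) {
  if (model$config$variant == "full") {
    sigm(net_fwd(model$nets$full, cbind(Xc, Xp))$logit)
  } else if (model$config$average == "probability") {
    (sigm(net_fwd(model$nets$compound, Xc)$logit) +
       sigm(net_fwd(model$nets$protein, Xp)$logit)) / 2
  } else {
    sigm((net_fwd(model$nets$compound, Xc)$logit +
            net_fwd(model$nets$protein, Xp)$logit) / 2)
  }
}

#' Train a PCM model on a split
#'
#' Minimises binary cross-entropy on the training partition with Adam,
#' halves the learning rate after `lr_halving_patience` epochs without
#' validation-loss improvement, stops after `early_stop_patience` epochs
#' without improvement and restores the best-validation weights.
#'
#' @param model an untrained (or previously trained) [build_pcm_model()]
#'   object; training restarts from freshly seeded weights so that the
#'   result is a pure function of (config, split, data).
#' @param split a `split_assignment` with non-empty train and valid
#'   partitions.
#' @param table a labelled [activity_table()].
#' @param compound_embeddings,protein_embeddings [embedding_table()]s
#'   covering every compound/protein in the split.
#' @return the trained `pcm_model`, with `training_log` (one row per epoch:
#'   train loss, validation loss, learning rate) and `valid_loss` equal to
#'   the minimum validation loss.
#' @export
train_pcm_model <- function(model, split, table, compound_embeddings,
                            protein_embeddings) {
  stopifnot(inherits(model, "pcm_model"), inherits(split, "split_assignment"))
  if (length(split$train) == 0L || length(split$valid) == 0L)
    stop("empty train or valid partition")
  cfg <- model$config
  model <- build_pcm_model(cfg, model$compound_dim, model$protein_dim)
  tr <- resolve_xy(split$train, table, compound_embeddings, protein_embeddings)
  va <- resolve_xy(split$valid, table, compound_embeddings, protein_embeddings)
  nets <- model$nets
  states <- lapply(nets, adam_new)
  lr <- cfg$learning_rate
  best <- list(loss = Inf, nets = nets)
  lr_wait <- 0L; stop_wait <- 0L; tstep <- 0L
  log_rows <- vector("list", cfg$max_epochs)
  n <- length(tr$y)

  valid_loss <- function(nets) {
    m <- model; m$nets <- nets
    bce_loss(model_probs(m, va$Xc, va$Xp), va$y)
  }

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      batch_losses <- c()
      for (s in seq(1L, n, by = cfg$batch_size)) {
        ii <- ord[s:min(s + cfg$batch_size - 1L, n)]
        m <- length(ii); yb <- tr$y[ii]
        tstep <- tstep + 1L
        if (cfg$variant == "full") {
          fw <- net_fwd(nets$full, cbind(tr$Xc[ii, , drop = FALSE],
                                         tr$Xp[ii, , drop = FALSE]),
                        cfg$dropout, training = TRUE)
          p <- sigm(fw$logit)
          batch_losses <- c(batch_losses, bce_loss(p, yb))
          gr <- net_bwd(nets$full, fw, (p - yb) / m)
          up <- adam_step(nets$full, states$full, gr, lr, tstep)
          nets$full <- up$net; states$full <- up$st
        } else {
          fwc <- net_fwd(nets$compound, tr$Xc[ii, , drop = FALSE],
                         cfg$dropout, training = TRUE)
          fwp <- net_fwd(nets$protein, tr$Xp[ii, , drop = FALSE],
                         cfg$dropout, training = TRUE)
          pc <- sigm(fwc$logit); pp <- sigm(fwp$logit)
          if (cfg$average == "probability") {
            pbar <- pmin(pmax((pc + pp) / 2, 1e-12), 1 - 1e-12)
            batch_losses <- c(batch_losses, bce_loss(pbar, yb))
            dl <- (pbar - yb) / (pbar * (1 - pbar)) / m
            dc <- dl * 0.5 * pc * (1 - pc)
            dp <- dl * 0.5 * pp * (1 - pp)
          } else {
            pbar <- sigm((fwc$logit + fwp$logit) / 2)
            batch_losses <- c(batch_losses, bce_loss(pbar, yb))
            dc <- dp <- (pbar - yb) / (2 * m)
          }
          grc <- net_bwd(nets$compound, fwc, dc)
          grp <- net_bwd(nets$protein, fwp, dp)
          up <- adam_step(nets$compound, states$compound, grc, lr, tstep)
          nets$compound <- up$net; states$compound <- up$st
          up <- adam_step(nets$protein, states$protein, grp, lr, tstep)
          nets$protein <- up$net; states$protein <- up$st
        }
      }
      vl <- valid_loss(nets)
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = mean(batch_losses),
                                      valid_loss = vl, lr = lr)
      if (vl < best$loss - 1e-8) {
        best <- list(loss = vl, nets = nets)
        lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
        if (lr_wait >= cfg$lr_halving_patience) { lr <- lr / 2; lr_wait <- 0L }
        if (stop_wait >= cfg$early_stop_patience) break
      }
    }
  })
  model$nets <- best$nets
  model$trained <- TRUE
  model$training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1L))])
  model$valid_loss <- best$loss
  model
}

#' Predict binding probabilities for (compound, protein) pairs
#'
#' @param object a `pcm_model`.
#' @param pairs a data frame with columns `compound_id` and `protein_id`.
#' @param compound_embeddings,protein_embeddings [embedding_table()]s
#'   resolving every ID in `pairs`.
#' @param ... unused.
#' @return numeric vector of probabilities strictly in (0, 1), in the order
#'   of `pairs`.
#' @export
predict.pcm_model <- function(object, pairs, compound_embeddings,
                              protein_embeddings, ...) {
  miss_c <- setdiff(unique(pairs$compound_id), compound_embeddings$ids)
  miss_p <- setdiff(unique(pairs$protein_id), protein_embeddings$ids)
  if (length(miss_c) > 0L || length(miss_p) > 0L)
    stop("unknown id(s): ", paste(utils::head(c(miss_c, miss_p), 5L), collapse = ", "))
  Xc <- compound_embeddings$vectors[pairs$compound_id, , drop = FALSE]
  Xp <- protein_embeddings$vectors[pairs$protein_id, , drop = FALSE]
  model_probs(object, Xc, Xp)
}
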