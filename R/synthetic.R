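# Synthetic proteochemometric datasets with a known bias/interaction
# decomposition.  Compound embeddings are drawn around unit-sphere cluster
# centres (so leave-compound-cluster-out splits hold out real structure),
# protein embeddings are isotropic on the unit sphere, and the latent
# binding logit is the sum of an intercept, per-entity bias terms and a
# bilinear compound-protein interaction that a dual-tower model is
# structurally unable to represent.  Every quantity is a pure function of
# the seed.

#' Simulation configuration
#'
#' The latent logit of pair (c, p) is
#' `b0 + s_c * bias_c + s_p * bias_p + gamma * (x_c' M x_p)` where `M` has
#' independent standard-normal entries and all embedding vectors are unit
#' length, so the bilinear term has unit variance for any dimension pair.
#' Each entity's bias is a fixed linear functional of its own embedding
#' (`bias_c = w_c' x_c` with `w_c` standard normal), so the bias component
#' is learnable - and in principle fully recoverable - by a model that
#' sees only one side of the pair.  Labels are `logit > 0` with a
#' `label_noise` fraction flipped.
#'
#' @param n_compounds,n_proteins entity counts (defaults 2000 / 50).
#' @param n_clusters number of compound clusters (default 10).
#' @param compound_dim,protein_dim embedding dimensions (defaults 64 / 32).
#' @param cluster_spread within-cluster spread relative to the unit-sphere
#'   centres (default 0.3; per-coordinate s.d. `cluster_spread/sqrt(dim)`
#'   before re-normalisation).
#' @param bias_scale_compound,bias_scale_protein scales of the per-entity
#'   bias terms (defaults 1).
#' @param interaction_strength gamma, the scale of the bilinear
#'   compound-protein interaction (default 1).
#' @param intercept b0 (default 0, approximately balanced classes).
#' @param density fraction of the compound x protein grid measured
#'   (default 0.1).
#' @param label_noise fraction of labels flipped, in `[0, 0.5)` (default
#'   0.1).
#' @param seed integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 2000L, n_proteins = 50L,
                              n_clusters = 10L,
                              compound_dim = 64L, protein_dim = 32L,
                              cluster_spread = 0.3,
                              bias_scale_compound = 1,
                              bias_scale_protein = 1,
                              interaction_strength = 1,
                              intercept = 0,
                              density = 0.1, label_noise = 0.1, seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_proteins = as.integer(n_proteins),
              n_clusters = as.integer(n_clusters),
              compound_dim = as.integer(compound_dim),
              protein_dim = as.integer(protein_dim),
              cluster_spread = cluster_spread,
              bias_scale_compound = bias_scale_compound,
              bias_scale_protein = bias_scale_protein,
              interaction_strength = interaction_strength,
              intercept = intercept,
              density = density, label_noise = label_noise,
              seed = as.integer(seed))
  if (cfg$compound_dim < 2L || cfg$protein_dim < 2L) stop("dims must be >= 2")
  if (cfg$n_clusters > cfg$n_compounds) stop("more clusters than compounds")
  if (cfg$n_clusters < 1L) stop("n_clusters must be >= 1")
  if (cfg$density <= 0 || cfg$density > 1) stop("density must be in (0, 1]")
  if (cfg$label_noise < 0 || cfg$label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)")
  if (cfg$bias_scale_compound < 0 || cfg$bias_scale_protein < 0 ||
      cfg$interaction_strength < 0) stop("scales must be non-negative")
  structure(cfg, class = "simulation_config")
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Simulate a synthetic PCM dataset
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_dataset`: list with `activity` (an
#'   [activity_table()] whose `activity` column is the latent logit and
#'   whose labels carry the flip noise), `compound_embeddings`,
#'   `protein_embeddings`, `truth` (latent logits, per-entity biases, the
#'   mixing matrix and bias functionals) and `config`.  Identical seeds
#'   give bit-identical datasets.
#' @export
simulate_pcm_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    centers <- unit_rows(matrix(rnorm(cfg$n_clusters * cfg$compound_dim),
                                cfg$n_clusters))
    cluster <- sample(cfg$n_clusters, cfg$n_compounds, replace = TRUE)
    X <- centers[cluster, , drop = FALSE] +
      (cfg$cluster_spread / sqrt(cfg$compound_dim)) *
      matrix(rnorm(cfg$n_compounds * cfg$compound_dim), cfg$n_compounds)
    X <- unit_rows(X)
    P <- unit_rows(matrix(rnorm(cfg$n_proteins * cfg$protein_dim),
                          cfg$n_proteins))
    w_c <- rnorm(cfg$compound_dim)
    w_p <- rnorm(cfg$protein_dim)
    bias_c <- drop(X %*% w_c)
    bias_p <- drop(P %*% w_p)
    M <- matrix(rnorm(cfg$compound_dim * cfg$protein_dim), cfg$compound_dim)
    n_pairs <- max(1L, round(cfg$density * cfg$n_compounds * cfg$n_proteins))
    pair_idx <- sample(cfg$n_compounds * cfg$n_proteins, n_pairs)
    ci <- ((pair_idx - 1L) %% cfg$n_compounds) + 1L
    pi_ <- ((pair_idx - 1L) %/% cfg$n_compounds) + 1L
    interaction <- rowSums((X[ci, , drop = FALSE] %*% M) * P[pi_, , drop = FALSE])
    logit <- cfg$intercept +
      cfg$bias_scale_compound * bias_c[ci] +
      cfg$bias_scale_protein * bias_p[pi_] +
      cfg$interaction_strength * interaction
    label <- as.integer(logit > 0)
    flip <- runif(n_pairs) < cfg$label_noise
    label[flip] <- 1L - label[flip]
  })
  compound_ids <- sprintf("C%05d", seq_len(cfg$n_compounds))
  protein_ids <- sprintf("P%03d", seq_len(cfg$n_proteins))
  tab <- activity_table(compound_ids[ci], protein_ids[pi_],
                        activity = logit, label = label)
  structure(list(
    activity = tab,
    compound_embeddings = embedding_table(compound_ids, X),
    protein_embeddings = embedding_table(protein_ids, P),
    truth = list(logit = logit, bias_compound = bias_c, bias_protein = bias_p,
                 cluster = cluster, mixing_matrix = M,
                 bias_functional_compound = w_c, bias_functional_protein = w_p,
                 flipped = flip),
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d pairs (%d compounds x %d proteins, density %.2f)\n",
              nrow(x$activity), x$config$n_compounds, x$config$n_proteins,
              x$config$density))
  cat(sprintf("  gamma %.2f, bias scales (%.2f, %.2f), label noise %.2f, seed %d\n",
              x$config$interaction_strength, x$config$bias_scale_compound,
              x$config$bias_scale_protein, x$config$label_noise, x$config$seed))
  invisible(x)
}

#' Bayes-ceiling MCC of a synthetic dataset
#'
#' The MCC of the noiseless-logit classifier (`logit > 0`) against the
#' observed noisy labels - the ceiling any trained model can reach on this
#' dataset.  With no label noise it is 1; with noise 0.5 the labels are
#' independent of the logit and it is approximately 0.
#'
#' @param dataset a [simulate_pcm_data()] result.
#' @return numeric scalar.
#' @export
truth_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  suppressWarnings(mcc(dataset$activity$label,
                       as.integer(dataset$truth$logit > 0)))
}

#' Write a synthetic dataset in the package's interchange formats
#'
#' Writes `activity.csv`, `compound_embeddings.csv` and
#' `protein_embeddings.csv` into a directory.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_activity_table(dataset$activity, file.path(dir, "activity.csv"))
  write_embedding_table(dataset$compound_embeddings,
                        file.path(dir, "compound_embeddings.csv"))
  write_embedding_table(dataset$protein_embeddings,
                        file.path(dir, "protein_embeddings.csv"))
  invisible(dir)
}
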