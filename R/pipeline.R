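# End-to-end orchestration: a declarative run configuration is resolved
# into data, splits, trained model variants and a results matrix, with
# every artifact written to the output directory so any row can be
# replayed.  One global seed fans out deterministically to per-stage
# seeds.

#' Derive a per-stage seed from a global seed
#'
#' A small deterministic string hash mixed with the global seed, kept
#' below 2^31 so it is always a valid integer seed.
#'
#' @param global_seed integer.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(global_seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full PCM pipeline from a declarative configuration
#'
#' The configuration is a nested list (typically parsed from a YAML file)
#' with blocks:
#' \describe{
#'   \item{simulation}{arguments for [simulation_config()] (synthetic
#'     data), or}
#'   \item{data}{paths `activity`, `compound_embeddings`,
#'     `protein_embeddings` plus an optional `binarize_threshold`.}
#'   \item{split}{`regime` (`random`/`lcco`/`lpo`) and its parameters:
#'     `fractions` for random; `k` and optionally `folds` for lcco;
#'     `n_folds` and optionally `folds` for lpo; `valid_fraction`.}
#'   \item{model}{arguments for [model_config()] minus `variant`/`seed`;
#'     `variants` selects which of `full`/`no_interaction` to train
#'     (default both).}
#'   \item{output_dir}{where artifacts are written (optional).}
#'   \item{seed}{global seed (default 1).}
#' }
#'
#' @param config nested list or path to a YAML file.
#' @return a results `data.frame` (one row per fold x variant) with the
#'   comparison report attached as attribute `"report"` when both
#'   variants were trained.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$output_dir

  # ---- data stage ----
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, "simulate")
    dataset <- simulate_pcm_data(do.call(simulation_config, sim_args))
    table <- dataset$activity
    comp_emb <- dataset$compound_embeddings
    prot_emb <- dataset$protein_embeddings
  } else {
    table <- read_activity_table(config$data$activity)
    if (!is.null(config$data$binarize_threshold))
      table <- binarize(table, config$data$binarize_threshold)
    comp_emb <- read_embedding_table(config$data$compound_embeddings)
    prot_emb <- read_embedding_table(config$data$protein_embeddings)
  }
  if (anyNA(table$label)) stop("activity table is not binarized")

  # ---- split stage ----
  sp_cfg <- config$split
  vf <- if (is.null(sp_cfg$valid_fraction)) 0.125 else sp_cfg$valid_fraction
  split_seed <- derive_seed(seed, "split")
  splits <- switch(sp_cfg$regime,
    random = list(split_random(table,
                               fractions = if (is.null(sp_cfg$fractions))
                                 c(0.7, 0.1, 0.2) else unlist(sp_cfg$fractions),
                               seed = split_seed)),
    lcco = {
      k <- if (is.null(sp_cfg$k)) 10L else as.integer(sp_cfg$k)
      used <- comp_emb$ids[comp_emb$ids %in% table$compound_id]
      clust <- cluster_compounds(
        embedding_table(used, comp_emb$vectors[used, , drop = FALSE]),
        k = k, seed = derive_seed(seed, "cluster"))
      folds <- if (is.null(sp_cfg$folds)) seq_len(k) else as.integer(sp_cfg$folds)
      lapply(folds, function(f)
        split_lcco(table, clust, f, valid_fraction = vf, seed = split_seed + f))
    },
    lpo = {
      nf <- if (is.null(sp_cfg$n_folds)) 5L else as.integer(sp_cfg$n_folds)
      folds <- if (is.null(sp_cfg$folds)) seq_len(nf) else as.integer(sp_cfg$folds)
      lapply(folds, function(f)
        split_lpo(table, nf, f, valid_fraction = vf, seed = split_seed))
    },
    stop("unknown split regime: ", sp_cfg$regime))

  # ---- model stage ----
  variants <- if (is.null(config$model$variants)) c("full", "no_interaction")
              else unlist(config$model$variants)
  model_args <- config$model
  model_args$variants <- NULL
  results <- list()
  for (split in splits) {
    for (variant in variants) {
      args <- model_args
      args$variant <- variant
      args$seed <- derive_seed(seed, paste0("model/", variant, "/", split$fold))
      if (!is.null(args$hidden_sizes)) args$hidden_sizes <- unlist(args$hidden_sizes)
      cfg <- do.call(model_config, args)
      model <- build_pcm_model(cfg, comp_emb$dim, prot_emb$dim)
      model <- train_pcm_model(model, split, table, comp_emb, prot_emb)
      res <- evaluate_model(model, split, table, comp_emb, prot_emb,
                            compound_descriptor = config$compound_descriptor %||% "compound",
                            protein_descriptor = config$protein_descriptor %||% "protein")
      results <- c(results, list(res))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_split(split, table,
                    file.path(out_dir, sprintf("split_%s_fold%d.tsv",
                                               split$regime, split$fold)))
      }
    }
  }
  mat <- results_matrix(results)
  report <- if (all(c("full", "no_interaction") %in% mat$variant))
    tryCatch(comparison_report(mat), error = function(e) NULL) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    data.table::fwrite(mat, file.path(out_dir, "results.tsv"), sep = "\t")
  }
  attr(mat, "report") <- report
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# schema validation before any computation
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$simulation) && is.null(config$data))
    stop("config needs a 'simulation' or 'data' block")
  if (!is.null(config$data)) {
    for (f in c("activity", "compound_embeddings", "protein_embeddings"))
      if (is.null(config$data[[f]]))
        stop("config$data is missing '", f, "'")
  }
  if (is.null(config$split) || is.null(config$split$regime))
    stop("config needs a 'split' block with a 'regime'")
  if (!config$split$regime %in% c("random", "lcco", "lpo"))
    stop("unknown split regime: ", config$split$regime)
  invisible(TRUE)
}
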