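# Shared fixtures, all generated in code.

toy_activity <- function() {
  activity_table(
    compound_id = c("c1", "c2", "c3", "c1", "c2", "c3"),
    protein_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    activity = c(5.0, 6.5, 8.0, 4.0, 7.0, 6.4)
  )
}

toy_embeddings <- function(ids, dim, seed = 1L) {
  withr::with_seed(seed,
    embedding_table(ids, matrix(rnorm(length(ids) * dim), length(ids))))
}

# a small simulated dataset reused across split/model tests
small_sim <- function(seed = 11L, gamma = 2, ...) {
  simulate_pcm_data(simulation_config(
    n_compounds = 150L, n_proteins = 12L, n_clusters = 4L,
    compound_dim = 12L, protein_dim = 6L, density = 0.5,
    interaction_strength = gamma, seed = seed, ...))
}

tiny_model_config <- function(variant, seed = 1L, ...) {
  model_config(variant = variant, hidden_sizes = c(24L, 16L, 8L),
               max_epochs = 20L, early_stop_patience = 5L,
               batch_size = 64L, seed = seed, ...)
}

# train both variants on one split of a simulated dataset and return their
# test MCCs; used by the interaction-recovery experiments
fit_both_variants <- function(dataset, seed, hidden = c(128L, 64L, 32L),
                              max_epochs = 60L) {
  sp <- split_random(dataset$activity, seed = seed)
  out <- vapply(c("full", "no_interaction"), function(v) {
    cfg <- model_config(variant = v, hidden_sizes = hidden,
                        max_epochs = max_epochs, seed = seed)
    m <- build_pcm_model(cfg, dataset$compound_embeddings$dim,
                         dataset$protein_embeddings$dim)
    m <- train_pcm_model(m, sp, dataset$activity,
                         dataset$compound_embeddings,
                         dataset$protein_embeddings)
    evaluate_model(m, sp, dataset$activity, dataset$compound_embeddings,
                   dataset$protein_embeddings)$mcc
  }, numeric(1L))
  names(out) <- c("full", "no_interaction")
  out
}
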