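#' Published benchmark reference results
#'
#' Per-combination test-set results reported for the large ChEMBL-derived
#' bioactivity benchmark: MCC and BEDROC of the full PCM model for every
#' compound x protein descriptor combination under the three split
#' regimes, together with the no-interaction-terms baseline MCCs.  These
#' reference values ship with the package so the comparison-layer
#' arithmetic (descriptor marginals, percent improvement and its
#' per-regime averages) can be exercised and checked against the published
#' summary numbers without any external download.
#'
#' @return a results `data.frame` with columns `compound_descriptor`,
#'   `protein_descriptor`, `regime`, `variant`, `mcc`, `bedroc`.
#' @export
benchmark_results <- function() {
  path <- system.file("extdata", "benchmark_results.csv",
                      package = "pcmbench", mustWork = TRUE)
  data.table::fread(path, data.table = FALSE, showProgress = FALSE)
}
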