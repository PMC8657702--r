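# Descriptor backends: a uniform interface over precomputed embedding tables
# and built-in handcrafted baselines, plus a registry of descriptor metadata
# for the five pretrained embedding families consumed as tables.

#' Registry of pretrained descriptor metadata
#'
#' pcmbench never runs the embedding generators themselves; pretrained
#' descriptors are consumed as precomputed vector tables.  The registry
#' records each family's representation size, originating-model parameter
#' count (metadata only) and model type, so pipelines can validate the
#' tables they are given.
#'
#' @return a `data.frame` with columns `name`, `entity_kind`, `repr_size`,
#'   `n_params`, `model_type`.
#' @export
descriptor_registry <- function() {
  data.frame(
    name = c("cddd", "molbert", "unirep", "seqvec", "esm"),
    entity_kind = c("compound", "compound", "protein", "protein", "protein"),
    repr_size = c(512L, 768L, 256L, 1024L, 1280L),
    n_params = c(26e6, 85e6, 1.8e6, 93e6, 650e6),
    model_type = c("GRU-Autoencoder", "Transformer", "m-LSTM",
                   "Stacked LSTM", "Transformer"),
    stringsAsFactors = FALSE
  )
}

#' Obtain a descriptor backend
#'
#' A backend produces fixed-length numeric vectors for compound or protein
#' IDs.  Three sources are supported:
#' \describe{
#'   \item{precomputed table}{`name` is one of the registry entries
#'     (`"cddd"`, `"molbert"`, `"unirep"`, `"seqvec"`, `"esm"`) with `table`
#'     supplied, in which case the table width must match the registry's
#'     representation size; or `name = "table"` for an ad-hoc table of any
#'     width.}
#'   \item{handcrafted compound}{`name = "handcrafted_compound"` with
#'     `smiles` (named character vector, see [read_smiles()]); hashed
#'     circular substructure fingerprints.}
#'   \item{handcrafted protein}{`name = "handcrafted_protein"` with
#'     `sequences` (named character vector, see [read_sequences()]);
#'     composition plus physicochemical-scale aggregation.}
#' }
#'
#' @param name backend name (see Details).
#' @param table an [embedding_table()] or a path to one, for table-backed
#'   backends.
#' @param smiles named character vector of SMILES for the handcrafted
#'   compound backend.
#' @param sequences named character vector of amino-acid sequences for the
#'   handcrafted protein backend.
#' @param entity_kind `"compound"` or `"protein"`; required only for
#'   ad-hoc tables (`name = "table"`).
#' @param n_bits,radius fingerprint fold size and circular radius for the
#'   handcrafted compound backend.
#' @param scales property-scale matrix for the handcrafted protein backend
#'   (default [aa_property_scales()]).
#' @param strict if `TRUE` (default), unknown IDs passed to [embed_ids()]
#'   are an error; otherwise they are dropped with a message.
#' @return an object of class `descriptor_backend`.
#' @export
get_backend <- function(name, table = NULL, smiles = NULL, sequences = NULL,
                        entity_kind = NULL, n_bits = 1024L, radius = 2L,
                        scales = aa_property_scales(), strict = TRUE) {
  reg <- descriptor_registry()
  if (is.character(table)) table <- read_embedding_table(table)
  if (name %in% reg$name) {
    if (is.null(table)) stop("backend '", name, "' needs a precomputed embedding table")
    want <- reg$repr_size[reg$name == name]
    if (table$dim != want)
      stop(sprintf("table dimension %d conflicts with registry dimension %d for '%s'",
                   table$dim, want, name))
    backend <- list(name = name, entity_kind = reg$entity_kind[reg$name == name],
                    dim = table$dim, source = "precomputed-table",
                    table = table, strict = strict)
  } else if (name == "table") {
    if (is.null(table)) stop("backend 'table' needs an embedding table")
    if (is.null(entity_kind)) stop("entity_kind required for ad-hoc tables")
    backend <- list(name = name, entity_kind = match.arg(entity_kind, c("compound", "protein")),
                    dim = table$dim, source = "precomputed-table",
                    table = table, strict = strict)
  } else if (name == "handcrafted_compound") {
    if (is.null(smiles)) stop("handcrafted_compound backend needs smiles")
    backend <- list(name = name, entity_kind = "compound", dim = as.integer(n_bits),
                    source = "handcrafted", smiles = smiles,
                    n_bits = as.integer(n_bits), radius = as.integer(radius),
                    strict = strict)
  } else if (name == "handcrafted_protein") {
    if (is.null(sequences)) stop("handcrafted_protein backend needs sequences")
    backend <- list(name = name, entity_kind = "protein",
                    dim = 20L + 2L * nrow(scales), source = "handcrafted",
                    sequences = sequences, scales = scales, strict = strict)
  } else {
    stop("unknown backend name: ", name)
  }
  class(backend) <- "descriptor_backend"
  backend
}

#' @export
print.descriptor_backend <- function(x, ...) {
  cat(sprintf("descriptor_backend '%s' (%s, %s), dim %d\n",
              x$name, x$entity_kind, x$source, x$dim))
  invisible(x)
}

#' Embed a list of IDs through a backend
#'
#' @param backend a [get_backend()] object.
#' @param ids character vector of IDs to embed.
#' @return an [embedding_table()] with rows in request order.  In strict
#'   mode an unknown ID is an error naming the ID; otherwise unknown IDs
#'   are dropped with a message.
#' @export
embed_ids <- function(backend, ids) {
  ids <- as.character(ids)
  known <- switch(backend$source,
    "precomputed-table" = backend$table$ids,
    "handcrafted" = names(if (backend$entity_kind == "compound") backend$smiles else backend$sequences)
  )
  missing_ids <- setdiff(ids, known)
  if (length(missing_ids) > 0L) {
    if (isTRUE(backend$strict))
      stop("unknown id(s) for backend '", backend$name, "': ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    message(sprintf("dropped %d id(s) unknown to backend '%s'",
                    length(missing_ids), backend$name))
    ids <- ids[ids %in% known]
  }
  if (length(ids) == 0L) stop("no embeddable ids")
  if (backend$source == "precomputed-table")
    return(embedding_table(ids, backend$table$vectors[ids, , drop = FALSE]))
  if (backend$entity_kind == "compound") {
    vecs <- t(vapply(backend$smiles[ids], handcrafted_compound,
                     numeric(backend$n_bits),
                     n_bits = backend$n_bits, radius = backend$radius))
  } else {
    vecs <- t(vapply(backend$sequences[ids], handcrafted_protein,
                     numeric(backend$dim), scales = backend$scales))
  }
  embedding_table(ids, vecs)
}

#' Handcrafted compound descriptor: hashed circular fingerprint
#'
#' Circular (extended-connectivity) substructure fingerprints enumerate
#' atom-centred environments up to a bond radius, hash them into a sparse
#' bit space and fold the result to a compact fixed length at the expense
#' of bit collisions.  Perception and hashing are delegated to Open Babel's
#' ECFP implementation; the 4096-bit native fingerprint is folded to
#' `n_bits` by OR-ing blocks.  The result depends only on the molecular
#' graph, so equivalent SMILES spellings of the same molecule map to
#' identical vectors.
#'
#' @param smiles a single SMILES string.
#' @param n_bits fold size (default 1024); must divide 4096.
#' @param radius circular radius in bonds (default 2, i.e. ECFP4).
#' @return numeric 0/1 vector of length `n_bits`.
#' @export
handcrafted_compound <- function(smiles, n_bits = 1024L, radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  n_bits <- as.integer(n_bits)
  fp_name <- paste0("ECFP", 2L * as.integer(radius))
  mol <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) m),
    error = function(e) stop("unparseable SMILES: ", smiles))
  if (length(mol) == 0L) stop("unparseable SMILES: ", smiles)
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::fingerprint_OB(mol, fp_name)),
    error = function(e) stop("unparseable SMILES: ", smiles))
  raw <- as.numeric(raw)
  if (length(raw) %% n_bits != 0L)
    stop("n_bits must divide the native fingerprint length ", length(raw))
  folded <- matrix(raw, nrow = n_bits)
  as.numeric(rowSums(folded) > 0)
}

#' Amino-acid physicochemical property scales
#'
#' Five standard z-scale-like property scales (derived from principal
#' components of a large panel of measured physicochemical properties)
#' covering lipophilicity, steric bulk/polarisability, polarity and
#' electronic character, for the 20 canonical amino acids.
#'
#' @return a 5 x 20 numeric matrix; rows are scales `z1..z5`, columns the
#'   one-letter amino-acid codes.
#' @export
aa_property_scales <- function() {
  m <- matrix(c(
    # z1      z2     z3     z4     z5
    0.24, -2.32,  0.60, -0.14,  1.30,  # A
    3.52,  2.50, -3.50,  1.99, -0.17,  # R
    3.05,  1.62,  1.04, -1.15,  1.61,  # N
    3.98,  0.93,  1.93, -2.46,  0.75,  # D
    0.84, -1.67,  3.71,  0.18, -2.65,  # C
    1.75,  0.50, -1.44, -1.34,  0.66,  # Q
    3.11,  0.26, -0.11, -3.04, -0.25,  # E
    2.05, -4.06,  0.36, -0.82, -0.38,  # G
    2.47,  1.95,  0.26,  3.90,  0.09,  # H
   -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   -4.28, -1.30, -1.49, -0.72,  0.84,  # L
    2.29,  0.89, -2.49,  1.49,  0.31,  # K
   -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   -1.66,  0.27,  1.84,  0.70,  2.00,  # P
    2.39, -1.07,  1.15, -1.39,  0.67,  # S
    0.75, -2.18, -1.12, -1.46, -0.40,  # T
   -4.36,  3.94,  0.59,  3.44, -1.59,  # W
   -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
   -2.59, -2.64, -1.54, -0.85, -0.02   # V
  ), nrow = 5L)
  colnames(m) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  rownames(m) <- paste0("z", 1:5)
  m
}

#' Handcrafted protein descriptor: composition and scale aggregation
#'
#' An alignment-free sequence descriptor: the 20 amino-acid composition
#' fractions followed by the mean and (population) standard deviation of
#' each property scale over the sequence, giving a fixed dimension of
#' `20 + 2 * nrow(scales)`.  Unknown residues (`X`) contribute zero to
#' composition and are skipped in the scale aggregation.  Because every
#' component is a per-residue aggregate, permuting a sequence leaves the
#' descriptor unchanged.
#'
#' @param sequence a single amino-acid string over the 20-letter alphabet
#'   (plus `X`).
#' @param scales numeric matrix of property scales with the 20 one-letter
#'   codes as column names (default [aa_property_scales()]).
#' @param strict if `TRUE` (default), characters outside the alphabet are
#'   an error; otherwise they are treated like `X`.
#' @return numeric vector of length `20 + 2 * nrow(scales)`.
#' @export
handcrafted_protein <- function(sequence, scales = aa_property_scales(),
                                strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  alphabet <- colnames(scales)
  illegal <- !(aa %in% c(alphabet, "X"))
  if (any(illegal)) {
    if (strict) stop("illegal residue(s): ",
                     paste(unique(aa[illegal]), collapse = ", "))
    aa[illegal] <- "X"
  }
  comp <- table(factor(aa, levels = alphabet))
  comp <- as.numeric(comp) / length(aa)
  known <- aa[aa %in% alphabet]
  if (length(known) == 0L) stop("sequence contains no known residues")
  vals <- scales[, known, drop = FALSE]
  mu <- rowMeans(vals)
  sdev <- sqrt(rowMeans((vals - mu)^2))
  out <- c(comp, mu, sdev)
  names(out) <- c(paste0("comp_", alphabet),
                  paste0("mean_", rownames(scales)),
                  paste0("sd_", rownames(scales)))
  out
}
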