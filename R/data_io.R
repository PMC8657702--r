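# Activity tables and embedding tables: construction, validation, delimited
# text input/output.  All IDs are case-sensitive opaque strings.

#' Construct an activity table
#'
#' An activity table holds one row per (compound, protein) measurement with
#' an optional continuous activity value (log-activity units, e.g. pChEMBL)
#' and an optional binary label (1 = active, 0 = inactive).
#'
#' @param compound_id,protein_id character vectors of equal length; must be
#'   non-empty strings.
#' @param activity numeric vector of continuous activities, or `NULL`.
#'   `NA` entries mean "no continuous measurement".
#' @param label integer/logical vector of binary labels, or `NULL`.
#' @param dedup how to resolve duplicated (compound, protein) pairs:
#'   `"highest"` keeps the record with the highest activity value
#'   (conservative toward activity), `"error"` fails.
#' @return A `data.frame` of class `activity_table` with columns
#'   `compound_id`, `protein_id`, `activity`, `label`.
#' @export
activity_table <- function(compound_id, protein_id, activity = NULL,
                           label = NULL, dedup = c("highest", "error")) {
  dedup <- match.arg(dedup)
  compound_id <- as.character(compound_id)
  protein_id <- as.character(protein_id)
  n <- length(compound_id)
  if (length(protein_id) != n)
    stop("compound_id and protein_id must have equal length")
  if (n == 0L) stop("activity table is empty")
  if (any(!nzchar(compound_id)) || any(is.na(compound_id)))
    stop("compound_id entries must be non-empty strings")
  if (any(!nzchar(protein_id)) || any(is.na(protein_id)))
    stop("protein_id entries must be non-empty strings")
  activity <- if (is.null(activity)) rep(NA_real_, n) else as.numeric(activity)
  label <- if (is.null(label)) rep(NA_integer_, n) else as.integer(label)
  if (length(activity) != n || length(label) != n)
    stop("activity and label must match the number of records")
  if (any(!is.na(label) & !(label %in% c(0L, 1L))))
    stop("labels must be binary (0/1)")
  tab <- data.frame(compound_id = compound_id, protein_id = protein_id,
                    activity = activity, label = label,
                    stringsAsFactors = FALSE)
  key <- paste(tab$compound_id, tab$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (dedup == "error") stop("duplicated (compound, protein) pairs present")
    # keep highest activity within each duplicated pair (NA sorts last)
    ord <- order(key, -xtfrm(tab$activity), method = "radix")
    tab <- tab[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    n_drop <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    tab <- tab[order(as.integer(rownames(tab))), , drop = FALSE]
    message(sprintf("dropped %d duplicated (compound, protein) record(s), keeping highest activity", n_drop))
  }
  rownames(tab) <- NULL
  class(tab) <- c("activity_table", "data.frame")
  tab
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d records, %d compounds, %d proteins\n",
              nrow(x), n_compounds(x), n_proteins(x)))
  if (all(is.na(x$label))) cat("labels: none (run binarize())\n")
  else if (!anyNA(x$label))
    cat(sprintf("labels: %d active / %d inactive\n",
                sum(x$label == 1L), sum(x$label == 0L)))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Number of distinct compounds / proteins in an activity table
#' @param table an [activity_table()].
#' @return integer count.
#' @export
n_compounds <- function(table) length(unique(table$compound_id))

#' @rdname n_compounds
#' @export
n_proteins <- function(table) length(unique(table$protein_id))

#' Read an activity table from delimited text
#'
#' The field separator (comma or tab) is auto-detected.  Rows whose mapped
#' activity column cannot be parsed as a number are dropped with a message.
#' Duplicated (compound, protein) pairs are resolved by keeping the record
#' with the highest activity value.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema named character vector mapping the internal column names
#'   `compound_id`, `protein_id`, `activity`, `label` to the file's column
#'   names.  `activity` and `label` entries may be omitted if absent from
#'   the file.
#' @return an [activity_table()].
#' @export
read_activity_table <- function(path,
                                schema = c(compound_id = "compound_id",
                                           protein_id = "protein_id",
                                           activity = "activity",
                                           label = "label")) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  cols <- strsplit(header, if (grepl("\t", header, fixed = TRUE)) "\t" else ",",
                   fixed = TRUE)[[1L]]
  for (col in c("compound_id", "protein_id")) {
    if (!schema[[col]] %in% cols)
      stop("mapped column not found in header: ", schema[[col]])
  }
  raw <- data.table::fread(path, header = TRUE, sep = "auto",
                           colClasses = list(character = unname(schema[c("compound_id", "protein_id")])),
                           data.table = FALSE, showProgress = FALSE)
  has_act <- "activity" %in% names(schema) && schema[["activity"]] %in% names(raw)
  has_lab <- "label" %in% names(schema) && schema[["label"]] %in% names(raw)
  activity <- if (has_act) suppressWarnings(as.numeric(raw[[schema[["activity"]]]])) else NULL
  label <- if (has_lab) as.integer(raw[[schema[["label"]]]]) else NULL
  keep <- rep(TRUE, nrow(raw))
  if (has_act) {
    raw_act <- raw[[schema[["activity"]]]]
    bad <- is.na(activity) & !is.na(raw_act) & nzchar(trimws(as.character(raw_act)))
    if (any(bad)) {
      message(sprintf("dropped %d row(s) with unparseable activity", sum(bad)))
      keep <- !bad
    }
  }
  if (!any(keep)) stop("no parseable records in ", path)
  activity_table(raw[[schema[["compound_id"]]]][keep],
                 raw[[schema[["protein_id"]]]][keep],
                 activity = if (has_act) activity[keep],
                 label = if (has_lab) label[keep])
}

#' Write an activity table as delimited text
#'
#' @param table an [activity_table()].
#' @param path output file; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(as.data.frame(table), path, sep = sep)
  invisible(path)
}

#' Binarize continuous activities at a threshold
#'
#' Labels each record active (1) iff `activity >= threshold`.  Continuous
#' values are preserved.  The default threshold of 6.5 log-activity units is
#' a common convention for binary bioactivity benchmarks and is exposed as a
#' parameter, not a constant.
#'
#' @param table an [activity_table()]; every record must carry an activity
#'   value.
#' @param threshold numeric scalar in log-activity units.
#' @return the table with the `label` column filled in.
#' @export
binarize <- function(table, threshold = 6.5) {
  if (anyNA(table$activity))
    stop("binarize() requires an activity value on every record")
  table$label <- as.integer(table$activity >= threshold)
  table
}

#' Construct an embedding table
#'
#' An embedding table maps unique string IDs to fixed-length real vectors.
#'
#' @param ids character vector of unique IDs.
#' @param vectors numeric matrix with one row per ID; all entries finite.
#' @return an object of class `embedding_table` with fields `ids`,
#'   `vectors` (rownames set to ids) and `dim`.
#' @export
embedding_table <- function(ids, vectors) {
  ids <- as.character(ids)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(ids) != nrow(vectors))
    stop("one vector row per id required")
  if (anyDuplicated(ids)) stop("duplicate ids in embedding table")
  if (any(!is.finite(vectors))) stop("non-finite entries in embedding table")
  rownames(vectors) <- ids
  colnames(vectors) <- paste0("dim_", seq_len(ncol(vectors)) - 1L)
  structure(list(ids = ids, vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d ids x %d dims\n", length(x$ids), x$dim))
  invisible(x)
}

#' Read an embedding table from delimited text
#'
#' Expects a header `id,dim_0,...,dim_{d-1}` (any numeric column names are
#' accepted); the separator (comma or tab) is auto-detected.  The
#' dimensionality is inferred from the first row and every row is validated
#' against it; ragged rows, duplicate IDs and non-numeric cells are errors.
#'
#' @param path path to the file.
#' @return an [embedding_table()].
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("ragged rows: found lines with ", paste(unique(nf), collapse = " and "),
         " fields")
  raw <- data.table::fread(path, header = TRUE, sep = sep,
                           colClasses = list(character = 1L),
                           data.table = FALSE, showProgress = FALSE)
  if (ncol(raw) < 2L) stop("embedding table needs an id column plus numeric columns")
  ids <- raw[[1L]]
  vec <- raw[, -1L, drop = FALSE]
  num <- vapply(vec, is.numeric, logical(1L))
  if (!all(num)) {
    # a non-numeric cell forces a character column
    bad <- names(vec)[!num]
    stop("non-numeric cell(s) in embedding column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(vec)) stop("missing/non-numeric entries in embedding table")
  embedding_table(ids, as.matrix(vec))
}

#' Write an embedding table as delimited text
#'
#' Values are written with full double precision so that a read/write
#' round-trip reproduces the vectors bit-identically.
#'
#' @param x an [embedding_table()].
#' @param path output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(id = x$ids, x$vectors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(x$vectors))
  # fwrite's default 15 significant digits does not always round-trip; force
  # shortest-exact decimal via format with 17 digits
  for (j in seq_along(df)[-1L]) df[[j]] <- sprintf("%.17g", df[[j]])
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.  Record IDs are the first whitespace-delimited
#'   token of each header.  Duplicate IDs and empty sequences are errors;
#'   lowercase residues are uppercased.
#' @return named character vector of amino-acid strings.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicate FASTA headers: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aas))
  if (any(!nzchar(seqs))) stop("empty sequence record(s) in ", path)
  names(seqs) <- ids
  seqs
}

#' Read a SMILES list
#'
#' One `SMILES<tab>ID` record per line; blank lines are skipped.
#'
#' @param path path to the file.
#' @return named character vector mapping compound ID to SMILES.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no SMILES records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1L)) < 2L))
    stop("every line must be SMILES<tab>ID")
  smiles <- vapply(parts, `[[`, character(1L), 1L)
  ids <- vapply(parts, `[[`, character(1L), 2L)
  if (anyDuplicated(ids)) stop("duplicate compound ids in ", path)
  names(smiles) <- ids
  smiles
}
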