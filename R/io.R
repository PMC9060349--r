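#' Read a labeled numeric matrix from TSV
#'
#' Expects a tab-separated file with a header row of condition/column
#' labels and a first column of module identifiers. Validation is strict:
#' ragged rows, duplicate identifiers and non-numeric cells are reported
#' with their line number.
#'
#' @param path file path.
#' @return numeric matrix with identifier rownames and header colnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(sprintf("%s: missing header or data rows", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol_expected <- length(header)
  if (ncol_expected < 2L)
    stop(sprintf("%s: line 1: header must name an identifier column and at least one data column", path))
  ids <- character(length(lines) - 1L)
  M <- matrix(NA_real_, length(lines) - 1L, ncol_expected - 1L)
  for (i in seq_along(ids)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncol_expected)
      stop(sprintf("%s: line %d: expected %d fields, found %d",
                   path, i + 1L, ncol_expected, length(row)))
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals))
      stop(sprintf("%s: line %d: non-numeric value '%s'",
                   path, i + 1L, row[-1L][which(is.na(vals))[1L]]))
    M[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1L]
    stop(sprintf("%s: line %d: duplicate identifier '%s'", path, d + 1L, ids[d]))
  }
  dimnames(M) <- list(ids, header[-1L])
  M
}

#' Write a labeled numeric matrix as TSV
#'
#' @param M matrix with rownames and colnames.
#' @param path output file path.
#' @param id_header header label of the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path, id_header = "id") {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(M)), collapse = "\t"), con)
  body <- apply(M, 1L, function(x)
    paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Read a perturbation dataset from TSV
#'
#' Two dialects are accepted. Wide: a matrix TSV (see [read_matrix_tsv()])
#' whose columns are the basal condition (named by `basal_label`) plus one
#' column per perturbed module, named by that module's identifier. Long:
#' three tab-separated columns `module`, `perturbation`, `value`, where
#' `perturbation` is `basal_label` or a module identifier.
#'
#' @param path file path.
#' @param basal_label column/condition label of the basal profile.
#' @param value_scale passed to [perturbation_dataset()].
#' @param format `"wide"`, `"long"`, or `"auto"` (detect from the header).
#' @return a [perturbation_dataset()].
#' @export
read_perturbation_tsv <- function(path, basal_label = "basal",
                                  value_scale = "positive_abundance",
                                  format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (format == "auto") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    format <- if (identical(header[-1L], c("perturbation", "value")) ||
                  identical(header, c("module", "perturbation", "value")))
      "long" else "wide"
  }
  if (format == "long") {
    tab <- utils::read.delim(path, colClasses = c("character", "character", "numeric"))
    names(tab) <- c("module", "perturbation", "value")
    ids <- unique(tab$module)
    wide <- matrix(NA_real_, length(ids), length(ids) + 1L,
                   dimnames = list(ids, c(basal_label, ids)))
    idx <- cbind(match(tab$module, ids),
                 match(tab$perturbation, c(basal_label, ids)))
    if (anyNA(idx[, 2L]))
      stop("long format: 'perturbation' labels must be the basal label or module identifiers")
    wide[idx] <- tab$value
    if (anyNA(wide)) stop("long format: incomplete module x perturbation grid")
    M <- wide
  } else {
    M <- read_matrix_tsv(path)
  }
  if (!basal_label %in% colnames(M))
    stop(sprintf("no '%s' column found", basal_label))
  ids <- rownames(M)
  pert_cols <- setdiff(colnames(M), basal_label)
  if (!setequal(pert_cols, ids))
    stop("perturbed column names must match the module identifiers exactly")
  perturbation_dataset(ids, basal = M[, basal_label],
                       perturbed = M[ids, ids], value_scale = value_scale)
}

#' Write a perturbation dataset as wide TSV
#'
#' @param data a [perturbation_dataset()].
#' @param path output file path.
#' @param basal_label column label of the basal profile.
#' @return `path`, invisibly.
#' @export
write_perturbation_tsv <- function(data, path, basal_label = "basal") {
  stopifnot(inherits(data, "perturbation_dataset"))
  write_matrix_tsv(condition_matrix(data, basal_label), path, id_header = "module")
}

#' Read / write edge lists
#'
#' Edge-list TSV with header `a`, `b`, `score` and optionally `sign`
#' (inferred edges) — the (node1, node2, score) dialect of interaction
#' databases is accepted for references via [reference_network()].
#'
#' @param path file path.
#' @return data.frame with the file's columns.
#' @export
read_edges_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop(sprintf("%s: an edge list needs at least two columns", path))
  names(tab)[1:2] <- c("a", "b")
  if (!"score" %in% names(tab)) {
    cand <- which(tolower(names(tab)) %in% c("combined_score", "confidence", "v3"))
    if (length(cand)) names(tab)[cand[1L]] <- "score"
  }
  tab
}

#' @rdname read_edges_tsv
#' @param edges data.frame of edges (e.g. an edge set).
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
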