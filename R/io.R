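# Readers and writers for the plain-text formats the package exchanges:
# genes x samples matrices (TSV/CSV, header row of sample ids, first
# column of gene ids), two-column group-label tables, ranked result
# tables and JSON run summaries.

.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genes x samples expression matrix
#'
#' Expects a delimited text file with a header row of sample ids and a
#' first column of gene ids. Ragged rows and non-numeric cells are hard
#' errors that name the offending line and column; duplicated gene ids
#' are suffixed (`id.1`, `id.2`, ...) with a warning.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated unless `sep` is given.
#' @param sep Optional field separator override.
#' @return Numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("read_expression_matrix: no such file: ", path)
  }
  sep <- .sep_for(path, sep)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_expression_matrix: need a header and at least one gene row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  samples <- header[-1L]
  if (length(samples) < 2L) stop("read_expression_matrix: need at least 2 sample columns")

  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf("read_expression_matrix: line %d has %d fields, expected %d",
                 bad + 1L, widths[bad], n_col))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
           nrow = length(body), byrow = TRUE)
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "read_expression_matrix: non-numeric value at line %d, column '%s'",
      bad[1L] + 1L, samples[bad[2L]]
    ))
  }
  if (anyDuplicated(ids)) {
    warning("read_expression_matrix: duplicate gene ids suffixed")
    ids <- make.unique(ids, sep = ".")
  }
  rownames(vals) <- ids
  colnames(vals) <- samples
  vals
}

#' Read a two-column sample-group label table
#'
#' Expects a delimited file with header `sample_id`, `group` (order of
#' columns detected by name) and group values `normal` or `cancer`.
#' Labels are matched to matrix columns by sample id, not by position.
#'
#' @param path File path (`.csv` comma-separated, otherwise tabs).
#' @param sample_ids Optional character vector the labels must cover
#'   exactly (the matrix column names); unlabelled or unknown samples
#'   are errors.
#' @param sep Optional separator override.
#' @return List with integer-index vectors `normal` and `cancer`
#'   relative to `sample_ids` (or a factor of groups named by sample id
#'   when `sample_ids` is `NULL`).
#' @export
read_group_labels <- function(path, sample_ids = NULL, sep = NULL) {
  sep <- .sep_for(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("read_group_labels: need columns 'sample_id' and 'group'")
  }
  bad <- setdiff(unique(df$group), c("normal", "cancer"))
  if (length(bad) > 0L) {
    stop("read_group_labels: unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(sample_ids)) {
    return(stats::setNames(factor(df$group, c("normal", "cancer")), df$sample_id))
  }
  pos <- match(sample_ids, df$sample_id)
  if (anyNA(pos)) {
    stop("read_group_labels: unlabelled sample(s): ",
         paste(sample_ids[is.na(pos)], collapse = ", "))
  }
  grp <- df$group[pos]
  list(normal = which(grp == "normal"), cancer = which(grp == "cancer"))
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (`gene_id` header), sample ids in the header row.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path (`.csv` comma-separated, otherwise tabs).
#' @param sep Optional separator override.
#' @export
write_expression_matrix <- function(x, path, sep = NULL) {
  sep <- .sep_for(path, sep)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write a result table as delimited text
#'
#' @param res Data frame (e.g. from [npcps_matrix()] or
#'   [comparator_matrix()]).
#' @param path Output path (`.csv` comma-separated, otherwise tabs).
#' @param sep Optional separator override.
#' @export
write_result_table <- function(res, path, sep = NULL) {
  sep <- .sep_for(path, sep)
  utils::write.table(res, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write a JSON run summary
#'
#' Serializes the echoed run configuration and result counts, so every
#' run is reproducible from its summary and seed.
#'
#' @param summary Named list.
#' @param path Output path.
#' @export
write_run_summary <- function(summary, path) {
  summary$package_version <- as.character(utils::packageVersion("npcps"))
  summary$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}
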