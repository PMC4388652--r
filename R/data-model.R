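#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression matrix with one header row and one id column
#' into a numeric matrix oriented subjects x features, whatever the file
#' orientation. Missing values are the literal token `NA` (case-sensitive) or
#' an empty cell; any other non-numeric cell is a parse error naming the
#' offending row and column.
#'
#' @param path Path to a delimited text file. The field separator is taken
#'   from the header line (tab if present, else comma).
#' @param orientation `"subjects"` if rows are subjects (default),
#'   `"features"` if rows are features; the returned matrix is always
#'   subjects x features.
#' @return A numeric matrix with subject ids as rownames and feature ids as
#'   colnames, in file order.
#' @seealso [write_expression_matrix()], [paired_expression_set()]
#' @export
read_expression_matrix <- function(path, orientation = c("subjects", "features")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2L) {
    stop("expression file '", path, "' needs a header row and at least one data row")
  }
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops a trailing empty field; restore it (empty cell = missing)
  trailing <- endsWith(lines, sep)
  fields[trailing] <- lapply(fields[trailing], c, "")
  header <- fields[[1L]]
  n_col <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad) > 0L) {
    stop(
      "ragged row in '", path, "': line ", bad[[1L]] + 1L, " has ",
      widths[[bad[[1L]]]], " fields, header has ", n_col
    )
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  col_ids <- header[-1L]
  cells <- vapply(body, function(x) x[-1L], character(n_col - 1L))
  cells <- if (is.matrix(cells)) t(cells) else matrix(cells, nrow = length(body))
  is_missing <- cells == "NA" | cells == ""
  values <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(values) & !is_missing)
  if (length(bad_cell) > 0L) {
    idx <- arrayInd(bad_cell[[1L]], dim(cells))
    stop(
      "non-numeric cell '", cells[bad_cell[[1L]]], "' in '", path,
      "' at row '", row_ids[idx[1L]], "', column '", col_ids[idx[2L]], "'"
    )
  }
  mat <- matrix(values, nrow = length(body), dimnames = list(row_ids, col_ids))
  if (orientation == "features") mat <- t(mat)
  mat
}

#' Write an expression matrix as delimited text
#'
#' Values are written with up to 15 significant digits so that any value whose
#' decimal representation has at most 12 significant digits round-trips
#' bit-identically through [read_expression_matrix()]. Missing values are
#' written as `NA`.
#'
#' @param mat Numeric matrix, subjects x features, with dimnames.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @param id_name Name of the id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t", id_name = "subject_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- "NA"
    out
  }
  header <- paste(c(id_name, colnames(mat)), collapse = sep)
  rows <- vapply(
    seq_len(nrow(mat)),
    function(i) paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = sep),
    character(1)
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Bundle paired normal/tumor expression matrices
#'
#' Container for a paired design where the tumor matrix is fully observed and
#' some subjects' normal samples are entirely missing (whole-sample
#' missingness: no tissue was available, so every feature of that subject's
#' normal row is `NA`). Partially missing normal rows are rejected: the
#' imputation model is defined only for whole missing samples.
#'
#' @param normal Numeric matrix, subjects x features; rows of missing subjects
#'   are all-`NA`.
#' @param tumor Numeric matrix, subjects x features, fully observed, with the
#'   same subject and feature ordering as `normal`.
#' @return An object of class `paired_expression_set`: a list with elements
#'   `normal`, `tumor`, `subject_ids`, `feature_ids`, and `missing_mask`
#'   (logical per subject, `TRUE` = normal sample missing).
#' @export
paired_expression_set <- function(normal, tumor) {
  stopifnot(is.matrix(normal), is.matrix(tumor))
  if (is.null(rownames(normal))) rownames(normal) <- paste0("s", seq_len(nrow(normal)))
  if (is.null(colnames(normal))) colnames(normal) <- paste0("f", seq_len(ncol(normal)))
  if (is.null(rownames(tumor))) rownames(tumor) <- rownames(normal)
  if (is.null(colnames(tumor))) colnames(tumor) <- colnames(normal)
  if (!identical(dim(normal), dim(tumor))) {
    stop("normal and tumor matrices must have identical dimensions")
  }
  if (!identical(rownames(normal), rownames(tumor))) {
    stop("normal and tumor matrices must share subject ordering")
  }
  if (!identical(colnames(normal), colnames(tumor))) {
    stop("normal and tumor matrices must share feature ordering")
  }
  if (anyNA(tumor)) stop("tumor matrix must be fully observed")
  n_miss <- rowSums(is.na(normal))
  partial <- which(n_miss > 0L & n_miss < ncol(normal))
  if (length(partial) > 0L) {
    stop(
      "partial row: subject(s) ", paste(rownames(normal)[partial], collapse = ", "),
      " have some but not all features missing; whole-sample missingness is required"
    )
  }
  mask <- n_miss == ncol(normal)
  if (all(mask)) stop("every normal sample is missing; nothing to impute from")
  structure(
    list(
      normal = normal,
      tumor = tumor,
      subject_ids = rownames(normal),
      feature_ids = colnames(normal),
      missing_mask = setNames(mask, rownames(normal))
    ),
    class = "paired_expression_set"
  )
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat(
    "<paired_expression_set> ", length(x$subject_ids), " subjects x ",
    length(x$feature_ids), " features; ", sum(x$missing_mask),
    " normal sample(s) missing\n",
    sep = ""
  )
  invisible(x)
}

#' Per-subject covariate table for neighbor finding
#'
#' Splits a per-subject data frame of fully observed covariates into a
#' continuous block (used with Euclidean distance) and a binary 0/1 block
#' (used with Manhattan distance). Covariates are used only to find nearest
#' neighbors; they never enter the expression model.
#'
#' @param data A data frame, one row per subject: an id column plus numeric
#'   covariate columns.
#' @param binary_cols Character vector naming the 0/1 indicator columns; all
#'   other covariate columns are treated as continuous.
#' @param id_col Name of the subject id column (default `"subject_id"`).
#' @return An object of class `covariate_table`: a list with `continuous` and
#'   `binary` matrices (subjects x covariates) and `subject_ids`.
#' @export
covariate_table <- function(data, binary_cols = character(), id_col = "subject_id") {
  stopifnot(is.data.frame(data))
  if (!id_col %in% names(data)) stop("id column '", id_col, "' not found")
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate subject ids in covariate table")
  cov_cols <- setdiff(names(data), id_col)
  missing_bin <- setdiff(binary_cols, cov_cols)
  if (length(missing_bin) > 0L) {
    stop("binary column(s) not present: ", paste(missing_bin, collapse = ", "))
  }
  cont_cols <- setdiff(cov_cols, binary_cols)
  as_block <- function(cols) {
    m <- as.matrix(data[cols])
    if (length(cols) > 0L && !is.numeric(m)) stop("covariate columns must be numeric")
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  continuous <- as_block(cont_cols)
  binary <- as_block(binary_cols)
  if (anyNA(continuous) || anyNA(binary)) {
    stop("covariates must be fully observed (no missing values)")
  }
  if (length(binary_cols) > 0L && !all(binary %in% c(0, 1))) {
    bad <- which(!(binary %in% c(0, 1)))[[1L]]
    idx <- arrayInd(bad, dim(binary))
    stop(
      "non-binary entry ", binary[bad], " in column '", colnames(binary)[idx[2L]],
      "', subject '", ids[idx[1L]], "'"
    )
  }
  structure(
    list(continuous = continuous, binary = binary, subject_ids = ids),
    class = "covariate_table"
  )
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(
    "<covariate_table> ", length(x$subject_ids), " subjects; ",
    ncol(x$continuous), " continuous + ", ncol(x$binary), " binary covariates\n",
    sep = ""
  )
  invisible(x)
}

#' Validate a paired expression set against its covariates
#'
#' Checks the whole bundle before imputation: matching subject ids between
#' expression and covariates, whole-sample missingness, and (optionally) that
#' at least `k` fully observed subjects remain as potential neighbors.
#'
#' @param pes A [paired_expression_set()].
#' @param cov A [covariate_table()] over the same subjects.
#' @param k Optional neighbor count a later imputation will use.
#' @return The validated `pes`, invisibly.
#' @export
validate_paired_set <- function(pes, cov, k = NULL) {
  stopifnot(inherits(pes, "paired_expression_set"), inherits(cov, "covariate_table"))
  extra <- setdiff(cov$subject_ids, pes$subject_ids)
  absent <- setdiff(pes$subject_ids, cov$subject_ids)
  if (length(extra) > 0L || length(absent) > 0L) {
    stop(
      "subject-id mismatch between expression and covariates; ",
      if (length(extra) > 0L) paste0("unknown in expression: ", paste(extra, collapse = ", "), "; ") else "",
      if (length(absent) > 0L) paste0("missing from covariates: ", paste(absent, collapse = ", ")) else ""
    )
  }
  if (!identical(cov$subject_ids, pes$subject_ids)) {
    stop("covariate subjects must be ordered as in the expression set")
  }
  n_obs <- sum(!pes$missing_mask)
  if (!is.null(k) && k > n_obs) {
    stop("k = ", k, " exceeds the ", n_obs, " fully observed subjects")
  }
  invisible(pes)
}
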