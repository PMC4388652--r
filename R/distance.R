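#' Pairwise Euclidean distance over continuous covariates
#'
#' @param cont Numeric matrix, subjects x covariates.
#' @param standardize Center and scale each column to unit variance first
#'   (default `TRUE`), so covariates on large scales (calories) do not swamp
#'   covariates on small ones (BMI). Zero-variance columns are dropped with a
#'   warning; they carry no between-subject information.
#' @return Symmetric N x N matrix of Euclidean distances.
#' @export
continuous_distance <- function(cont, standardize = TRUE) {
  stopifnot(is.matrix(cont), ncol(cont) >= 1L)
  if (standardize) {
    sds <- apply(cont, 2L, sd)
    flat <- sds == 0 | is.na(sds)
    if (any(flat)) {
      warning(
        "dropping zero-variance covariate column(s): ",
        paste(colnames(cont)[flat], collapse = ", ")
      )
      cont <- cont[, !flat, drop = FALSE]
      if (ncol(cont) == 0L) {
        d <- matrix(0, nrow(cont), nrow(cont), dimnames = list(rownames(cont), rownames(cont)))
        return(d)
      }
    }
    cont <- scale(cont)
  }
  as.matrix(dist(cont, method = "euclidean"))
}

#' Pairwise Manhattan distance over binary covariates
#'
#' For 0/1 indicators the Manhattan distance is the number of disagreeing
#' indicators (the Hamming count).
#'
#' @param bin Numeric matrix of 0/1 indicators, subjects x covariates.
#' @return Symmetric N x N matrix of disagreement counts.
#' @export
binary_distance <- function(bin) {
  stopifnot(is.matrix(bin), ncol(bin) >= 1L)
  if (!all(bin %in% c(0, 1))) {
    bad <- which(!(bin %in% c(0, 1)))[[1L]]
    idx <- arrayInd(bad, dim(bin))
    stop("non-binary entry at row ", idx[1L], ", column ", idx[2L])
  }
  as.matrix(dist(bin, method = "manhattan"))
}

minmax_offdiag <- function(D) {
  off <- D[row(D) != col(D)]
  rng <- range(off)
  if (diff(rng) == 0) {
    return(matrix(0, nrow(D), ncol(D), dimnames = dimnames(D)))
  }
  out <- (D - rng[1L]) / diff(rng)
  diag(out) <- 0
  out
}

#' Aggregate per-type distance matrices into one dissimilarity
#'
#' Each block is min-max scaled to \[0, 1\] over its off-diagonal entries
#' (a constant block maps to all zeros), then the blocks are combined as a
#' weighted average. The result is symmetric with zero diagonal but need not
#' satisfy the triangle inequality.
#'
#' @param d_cont,d_bin Symmetric nonnegative N x N distance matrices.
#' @param block_weights Numeric pair `(continuous, binary)` summing to 1.
#' @return An object of class `aggregated_distance`: the N x N matrix with a
#'   `block_weights` attribute.
#' @export
aggregate_distance <- function(d_cont, d_bin, block_weights = c(0.5, 0.5)) {
  stopifnot(is.matrix(d_cont), is.matrix(d_bin), identical(dim(d_cont), dim(d_bin)))
  if (abs(sum(block_weights) - 1) > 1e-9) {
    stop("block weights must sum to 1, got ", sum(block_weights))
  }
  D <- block_weights[[1L]] * minmax_offdiag(d_cont) +
    block_weights[[2L]] * minmax_offdiag(d_bin)
  structure(D, block_weights = block_weights, class = c("aggregated_distance", "matrix", "array"))
}

#' Between-subject distance from mixed-type covariates
#'
#' Builds the single dissimilarity used for neighbor finding: Euclidean
#' distance over the continuous block, Manhattan distance over the binary
#' block, each min-max scaled to \[0, 1\], then averaged with `block_weights`.
#' If one block is empty its weight is reassigned to the other.
#'
#' @param cov A [covariate_table()].
#' @param block_weights Numeric pair `(continuous, binary)` summing to 1.
#' @param standardize Passed to [continuous_distance()].
#' @return An `aggregated_distance` matrix with subject ids as dimnames.
#' @export
covariate_distance <- function(cov, block_weights = c(0.5, 0.5), standardize = TRUE) {
  stopifnot(inherits(cov, "covariate_table"))
  has_cont <- ncol(cov$continuous) > 0L
  has_bin <- ncol(cov$binary) > 0L
  if (!has_cont && !has_bin) stop("covariate table has no covariates")
  n <- length(cov$subject_ids)
  zero <- matrix(0, n, n, dimnames = list(cov$subject_ids, cov$subject_ids))
  if (!has_bin) block_weights <- c(1, 0)
  if (!has_cont) block_weights <- c(0, 1)
  d_cont <- if (has_cont) continuous_distance(cov$continuous, standardize) else zero
  d_bin <- if (has_bin) binary_distance(cov$binary) else zero
  aggregate_distance(d_cont, d_bin, block_weights)
}
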