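#' Neighbor sets and imputation weights for missing subjects
#'
#' For each subject whose normal sample is missing, finds the k nearest fully
#' observed subjects in the aggregated covariate distance and converts their
#' distances into convex weights. With sorted neighbor distances
#' `D_i1 <= ... <= D_ik` and `D_imax` the maximum distance from subject i over
#' ALL fully observed subjects (not just the k chosen), the raw weight of
#' neighbor l is `w_il = 1 - D_il / D_imax`, normalized to `a_il = w_il / sum(w)`.
#' A neighbor sitting exactly at `D_imax` therefore gets weight 0 and is
#' retained with zero contribution.
#'
#' Ties at the k-th distance are broken by stable subject order, so reruns are
#' deterministic; tied neighbors receive equal weights regardless of which is
#' kept. If a missing subject is at distance 0 from every observed subject
#' (or every selected neighbor sits at `D_imax`, so all raw weights vanish),
#' uniform weights `1/k` are used and a warning is logged.
#'
#' @param D An [aggregate_distance()] (or plain symmetric) N x N matrix with
#'   subject ids as dimnames.
#' @param missing_mask Logical vector over subjects, `TRUE` = normal missing.
#' @param k Number of neighbors (default 10), or `"auto"` for the square root
#'   of the number of fully observed subjects rounded to the nearest odd
#'   integer.
#' @return An object of class `neighbor_weights`: per missing subject, the
#'   neighbor ids (sorted by distance), distances, raw and normalized weights;
#'   plus `k`, `observed_ids`, `missing_ids`.
#' @export
neighbor_weights <- function(D, missing_mask, k = 10) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), length(missing_mask) == nrow(D))
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(D)))
  observed <- which(!missing_mask)
  missing <- which(missing_mask)
  n_obs <- length(observed)
  if (identical(k, "auto")) {
    k <- round(sqrt(n_obs))
    if (k %% 2L == 0L) k <- k + if (sqrt(n_obs) >= k) 1L else -1L
    k <- max(1L, k)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n_obs) {
    stop("k = ", k, " exceeds the ", n_obs, " fully observed subjects")
  }
  per_subject <- lapply(missing, function(i) {
    d <- D[i, observed]
    d_max <- max(d)
    ord <- order(d)[seq_len(k)]
    d_sel <- d[ord]
    if (d_max == 0) {
      warning("subject '", ids[i], "' is at distance 0 from every observed subject; using uniform weights")
      w <- rep(1, k)
    } else {
      w <- 1 - d_sel / d_max
      if (sum(w) == 0) {
        warning("all selected neighbors of subject '", ids[i], "' sit at the maximum distance; using uniform weights")
        w <- rep(1, k)
      }
    }
    list(
      neighbors = ids[observed[ord]],
      distances = unname(d_sel),
      w = unname(w),
      a = unname(w / sum(w))
    )
  })
  names(per_subject) <- ids[missing]
  structure(
    list(
      weights = per_subject,
      k = k,
      observed_ids = ids[observed],
      missing_ids = ids[missing],
      subject_ids = ids
    ),
    class = "neighbor_weights"
  )
}

#' @export
print.neighbor_weights <- function(x, ...) {
  cat(
    "<neighbor_weights> k = ", x$k, "; ", length(x$missing_ids),
    " missing subject(s), ", length(x$observed_ids), " donors\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn neighbor_weights One row per (missing subject, neighbor):
#'   `subject`, `neighbor`, `rank`, `distance`, `weight_raw`, `weight`.
#' @param x A `neighbor_weights` object.
#' @param ... Unused.
#' @export
tidy.neighbor_weights <- function(x, ...) {
  purrr::imap(x$weights, function(w, subj) {
    tibble::tibble(
      subject = subj,
      neighbor = w$neighbors,
      rank = seq_along(w$neighbors),
      distance = w$distances,
      weight_raw = w$w,
      weight = w$a
    )
  }) |>
    purrr::list_rbind()
}

# (N-S) x S weight matrix: column i holds missing subject i's normalized
# weights at its neighbors' rows, zeros elsewhere.
weight_matrix <- function(nw) {
  A <- matrix(
    0, length(nw$observed_ids), length(nw$missing_ids),
    dimnames = list(nw$observed_ids, nw$missing_ids)
  )
  for (subj in nw$missing_ids) {
    w <- nw$weights[[subj]]
    A[w$neighbors, subj] <- w$a
  }
  A
}

#' Induced covariance structure of observed plus imputed samples
#'
#' Imputed rows are linear combinations `A' X` of observed rows, so observed
#' and imputed samples covary. At unit feature variance the joint covariance,
#' with subjects ordered observed-first then missing, is the block matrix
#' `[[I, A], [A', A'A]]`: identity among observed subjects, the weight matrix
#' as the cross block, and the Gram matrix `A'A` among imputed subjects. The
#' per-feature variance scaling is applied later by the GLS test.
#'
#' @param nw A [neighbor_weights()] object.
#' @return A list with `sigma` (N x N symmetric matrix, observed-first order)
#'   and `order` (the permutation of original subject positions it uses).
#' @export
induced_sigma <- function(nw) {
  stopifnot(inherits(nw, "neighbor_weights"))
  A <- weight_matrix(nw)
  n_obs <- nrow(A)
  sigma <- rbind(
    cbind(diag(n_obs), A),
    cbind(t(A), crossprod(A))
  )
  ids <- c(nw$observed_ids, nw$missing_ids)
  dimnames(sigma) <- list(ids, ids)
  list(sigma = sigma, order = match(ids, nw$subject_ids))
}

#' Impute missing normal samples by weighted KNN
#'
#' Fills each missing normal row with the convex combination of its neighbors'
#' rows, `xhat_ij = a_i1 x_i1j + ... + a_ik x_ikj` (equivalently, the imputed
#' block is the matrix product `A' X` of the weight matrix with the observed
#' normal matrix). Observed rows are returned untouched, and every imputed
#' value lies within the range of its neighbors' values for that feature.
#'
#' @param pes A [paired_expression_set()].
#' @param nw A [neighbor_weights()] computed on the same subjects.
#' @return An object of class `imputation_result`: `completed_normal` (N x G,
#'   original subject order), `A` (the (N-S) x S weight matrix), `sigma` and
#'   `order` from [induced_sigma()], plus `k` and the id vectors.
#' @export
knn_impute <- function(pes, nw) {
  stopifnot(inherits(pes, "paired_expression_set"), inherits(nw, "neighbor_weights"))
  if (!identical(nw$subject_ids, pes$subject_ids)) {
    stop("neighbor weights were computed on a different subject set")
  }
  A <- weight_matrix(nw)
  completed <- pes$normal
  if (length(nw$missing_ids) > 0L) {
    completed[nw$missing_ids, ] <- t(A) %*% pes$normal[nw$observed_ids, , drop = FALSE]
  }
  is_ <- induced_sigma(nw)
  structure(
    list(
      completed_normal = completed,
      A = A,
      sigma = is_$sigma,
      order = is_$order,
      k = nw$k,
      observed_ids = nw$observed_ids,
      missing_ids = nw$missing_ids
    ),
    class = "imputation_result"
  )
}

#' Column-mean imputation baseline
#'
#' Replaces each missing normal row with the per-feature mean of the observed
#' rows. This is the degenerate case of weighted KNN with every observed
#' subject as a neighbor at uniform weight, and is represented that way so the
#' induced covariance is available for it too.
#'
#' @param pes A [paired_expression_set()].
#' @return An `imputation_result`, as for [knn_impute()].
#' @export
mean_impute <- function(pes) {
  stopifnot(inherits(pes, "paired_expression_set"))
  observed <- pes$subject_ids[!pes$missing_mask]
  missing <- pes$subject_ids[pes$missing_mask]
  A <- matrix(
    1 / length(observed), length(observed), length(missing),
    dimnames = list(observed, missing)
  )
  completed <- pes$normal
  if (length(missing) > 0L) {
    completed[missing, ] <- t(A) %*% pes$normal[observed, , drop = FALSE]
  }
  n_obs <- length(observed)
  sigma <- rbind(cbind(diag(n_obs), A), cbind(t(A), crossprod(A)))
  ids <- c(observed, missing)
  dimnames(sigma) <- list(ids, ids)
  structure(
    list(
      completed_normal = completed,
      A = A,
      sigma = sigma,
      order = match(ids, pes$subject_ids),
      k = n_obs,
      observed_ids = observed,
      missing_ids = missing
    ),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(
    "<imputation_result> ", length(x$missing_ids), " subject(s) imputed from ",
    length(x$observed_ids), " donors (k = ", x$k, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn knn_impute One row per imputed (subject, feature) with the
#'   imputed value.
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @export
tidy.imputation_result <- function(x, ...) {
  imp <- x$completed_normal[x$missing_ids, , drop = FALSE]
  tibble::as_tibble(imp, rownames = "subject") |>
    tidyr::pivot_longer(-"subject", names_to = "feature", values_to = "imputed")
}
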