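#' Error covariance of paired differences under imputation
#'
#' The tumor-minus-normal difference vector for any feature has covariance
#' proportional to `V = I + Sigma`, where `Sigma` is the unit-variance induced
#' covariance of the (observed + imputed) normal samples and the leading `I`
#' carries the fully observed tumor arm. `V` is feature-independent, so it is
#' built and factorized once and reused across all features.
#'
#' @param sigma N x N induced covariance from [induced_sigma()] (or a zero
#'   matrix / `NULL` with `n` given, for the independence working model).
#' @param n Number of subjects, required when `sigma` is `NULL`.
#' @return `V`, verified symmetric positive definite, with its upper Cholesky
#'   factor attached as attribute `"chol"`.
#' @export
build_v <- function(sigma = NULL, n = NULL) {
  if (is.null(sigma)) {
    stopifnot(!is.null(n))
    sigma <- matrix(0, n, n)
  }
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  V <- diag(nrow(sigma)) + sigma
  dimnames(V) <- dimnames(sigma)
  U <- tryCatch(
    chol(V),
    error = function(e) {
      stop(
        "V = I + Sigma is not positive definite; reduce the number of ",
        "missing subjects or increase k",
        call. = FALSE
      )
    }
  )
  attr(V, "chol") <- U
  V
}

#' GLS paired t-test for one feature
#'
#' Fits the single-mean model `d = 1 mu + eps`, `Var(eps) = sigma2 V`, by
#' generalized least squares: `mu_hat = (1' V^-1 1)^-1 1' V^-1 d`, residual
#' variance `sigma2_hat = r' V^-1 r / (N - 1)` with `r = d - 1 mu_hat`,
#' `Var(mu_hat) = sigma2_hat (1' V^-1 1)^-1`, and `t = mu_hat / sqrt(Var(mu_hat))`
#' referred to a Student t with `N - 1` degrees of freedom (two-sided). With
#' `V = I` this reduces exactly to the classical one-sample t-test.
#'
#' @param differences Numeric vector of per-subject paired differences, in the
#'   subject order `V` was built for.
#' @param V Covariance from [build_v()] (Cholesky factor reused if attached).
#' @param df Degrees of freedom; defaults to `length(differences) - 1`.
#' @return A one-row tibble: `mu_hat`, `sigma2_hat`, `var_mu_hat`, `t_stat`,
#'   `df`, `p_value`. When the GLS residuals vanish, `t_stat` is `+/-Inf` and
#'   `p_value` 0, with a message.
#' @export
gls_paired_t <- function(differences, V, df = length(differences) - 1L) {
  n <- length(differences)
  stopifnot(n >= 3L, nrow(V) == n)
  fit <- gls_fit(matrix(differences, ncol = 1L), V, df = df)
  if (fit$sigma2_hat == 0) {
    message("zero residual variance: all differences fit the mean exactly; t is infinite")
  }
  tibble::as_tibble(fit)
}

# Vectorized GLS across feature columns; diffs is N x G.
gls_fit <- function(diffs, V, df) {
  U <- attr(V, "chol")
  if (is.null(U)) U <- chol(V)
  Lt <- t(U)
  z1 <- forwardsolve(Lt, rep(1, nrow(diffs)))
  W <- forwardsolve(Lt, diffs)
  c11 <- sum(z1^2)
  c1d <- as.vector(crossprod(z1, W))
  cdd <- colSums(W^2)
  mu_hat <- c1d / c11
  rss <- pmax(cdd - c1d^2 / c11, 0)
  sigma2_hat <- rss / df
  var_mu_hat <- sigma2_hat / c11
  t_stat <- ifelse(var_mu_hat > 0, mu_hat / sqrt(var_mu_hat), sign(mu_hat) * Inf)
  p_value <- ifelse(
    is.finite(t_stat),
    2 * pt(-abs(t_stat), df = df),
    0
  )
  list(
    mu_hat = mu_hat, sigma2_hat = sigma2_hat, var_mu_hat = var_mu_hat,
    t_stat = t_stat, df = df, p_value = p_value
  )
}

#' Per-feature differential expression analysis of paired samples
#'
#' Computes tumor-minus-normal differences for every feature and tests each
#' for a nonzero mean, with Benjamini-Hochberg FDR adjustment across features.
#' Three working models are available:
#'
#' * `"dependent"` — the dependence-aware test: subjects are reordered
#'   observed-first to match the imputation's covariance, and the GLS test
#'   uses `V = I + Sigma` from the imputation. This is the analysis that keeps
#'   FDR control after KNN imputation.
#' * `"independent"` — imputed values are treated as fully observed
#'   independent samples (`V = I`); the classical paired t-test on the
#'   completed data.
#' * `"case_deletion"` — missing subjects are dropped and the classical test
#'   is run on the complete pairs, with degrees of freedom reduced to the
#'   number of complete pairs minus one.
#'
#' With no missing subjects all three modes coincide exactly.
#'
#' @param pes A [paired_expression_set()].
#' @param imputation An [knn_impute()] / [mean_impute()] result; required for
#'   the dependent mode and, when any subject is missing, for the independent
#'   mode. Ignored by case deletion.
#' @param mode One of `"dependent"`, `"independent"`, `"case_deletion"`.
#' @param alpha FDR level used to flag significant features (default 0.05).
#' @return An object of class `de_result`; `tidy()` returns the per-feature
#'   table (`feature_id`, `mu_hat`, `sigma2_hat`, `t_stat`, `df`, `p_value`,
#'   `q_value`, `significant`), `glance()` a one-row summary.
#' @export
run_de_analysis <- function(pes, imputation = NULL,
                            mode = c("dependent", "independent", "case_deletion"),
                            alpha = 0.05) {
  stopifnot(inherits(pes, "paired_expression_set"))
  mode <- match.arg(mode)
  n <- length(pes$subject_ids)
  s <- sum(pes$missing_mask)

  if (mode == "case_deletion") {
    keep <- !pes$missing_mask
    if (sum(keep) < 3L) stop("case deletion needs at least 3 complete pairs")
    diffs <- pes$tumor[keep, , drop = FALSE] - pes$normal[keep, , drop = FALSE]
    V <- build_v(n = sum(keep))
    df <- sum(keep) - 1L
  } else {
    if (s == 0L) {
      completed <- pes$normal
      V <- build_v(n = n)
    } else {
      if (is.null(imputation) || !inherits(imputation, "imputation_result")) {
        stop("mode '", mode, "' with missing subjects requires an imputation result")
      }
      completed <- imputation$completed_normal
      V <- if (mode == "dependent") build_v(imputation$sigma) else build_v(n = n)
    }
    diffs <- pes$tumor - completed
    if (mode == "dependent" && s > 0L) {
      diffs <- diffs[imputation$order, , drop = FALSE]
    }
    if (n < 3L) stop("at least 3 subjects are required")
    df <- n - 1L
  }

  fit <- gls_fit(diffs, V, df = df)
  q_value <- p.adjust(fit$p_value, method = "BH")
  table <- tibble::tibble(
    feature_id = pes$feature_ids,
    mu_hat = fit$mu_hat,
    sigma2_hat = fit$sigma2_hat,
    var_mu_hat = fit$var_mu_hat,
    t_stat = fit$t_stat,
    df = fit$df,
    p_value = fit$p_value,
    q_value = q_value,
    significant = q_value <= alpha
  )
  structure(
    list(table = table, mode = mode, alpha = alpha, n_subjects = n,
         n_missing = s, df = df),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(
    "<de_result> mode = ", x$mode, "; ", nrow(x$table), " features, ",
    sum(x$table$significant), " significant at BH ", x$alpha, "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn run_de_analysis Per-feature test table as a tibble.
#' @param x A `de_result`.
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @describeIn run_de_analysis One-row summary: mode, alpha, subjects,
#'   missing, df, features, significant calls.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    alpha = x$alpha,
    n_subjects = x$n_subjects,
    n_missing = x$n_missing,
    df = x$df,
    n_features = nrow(x$table),
    n_significant = sum(x$table$significant)
  )
}

#' @describeIn run_de_analysis Histogram of the per-feature p-values with the
#'   uniform reference density.
#' @param object A `de_result`.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      breaks = seq(0, 1, by = 0.05), fill = "grey35"
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "p-value",
      y = "density",
      title = paste0("Paired DE test p-values (", object$mode, " mode)")
    ) +
    ggplot2::theme_minimal()
}
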