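#' Run a simulation study over a grid of conditions
#'
#' For every `(N, missing_fraction)` cell of `grid` and every replicate:
#' simulate a dataset, impute the masked normal rows, run the requested
#' differential-expression analyses at BH level `alpha`, and score TPR, FPR,
#' empirical FDR, and imputation RMSE against the simulation truth.
#'
#' Replicates are independently seeded by a stable scheme,
#' `rep_seed = seed + 100000 * (cell - 1) + rep`, so any cell or replicate
#' can be reproduced in isolation and the whole study is bit-reproducible.
#'
#' @param grid Data frame with columns `N` and `missing_fraction`, one row per
#'   study cell.
#' @param methods Any of `"knn_dependent"` (covariate-KNN imputation + GLS
#'   test with the induced covariance), `"knn_independent"` (same imputation,
#'   identity covariance), `"mean_impute"` (column-mean imputation, identity
#'   covariance), `"case_deletion"` (complete pairs only), `"full"` (the
#'   unmasked data; upper reference).
#' @param n_reps Replicates per cell.
#' @param k Neighbor count for the KNN methods.
#' @param alpha BH FDR level for calling features significant.
#' @param seed Base seed for the replicate seed scheme.
#' @param ... Further [sim_config()] overrides (`G`, `de_fraction`, `mu_de`, ...).
#' @return A `study_report` tibble: `N`, `missing_fraction`, `method`, `rep`,
#'   `seed`, `tpr`, `fpr`, `fdr`, `rmse` (RMSE is `NA` for methods that do not
#'   impute).
#' @export
run_study <- function(grid,
                      methods = c("knn_dependent", "knn_independent",
                                  "case_deletion", "full"),
                      n_reps = 3, k = 10, alpha = 0.05, seed = 1, ...) {
  stopifnot(is.data.frame(grid), all(c("N", "missing_fraction") %in% names(grid)))
  known <- c("knn_dependent", "knn_independent", "mean_impute", "case_deletion", "full")
  methods <- match.arg(methods, known, several.ok = TRUE)
  cells <- seq_len(nrow(grid))
  out <- purrr::map(cells, function(ci) {
    purrr::map(seq_len(n_reps), function(rep) {
      rep_seed <- seed + 100000 * (ci - 1L) + rep
      cfg <- sim_config(
        N = grid$N[[ci]], missing_fraction = grid$missing_fraction[[ci]],
        k = k, seed = rep_seed, ...
      )
      one_rep(cfg, methods, alpha) |>
        dplyr::mutate(
          N = cfg$N, missing_fraction = cfg$missing_fraction,
          rep = rep, seed = rep_seed,
          .before = 1L
        )
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  class(out) <- c("study_report", class(out))
  out
}

one_rep <- function(cfg, methods, alpha) {
  ds <- simulate_dataset(cfg)
  truth <- ds$truth
  imp <- NULL
  if (any(c("knn_dependent", "knn_independent") %in% methods)) {
    D <- covariate_distance(ds$cov)
    nw <- neighbor_weights(D, ds$pes$missing_mask, k = cfg$k)
    imp <- knn_impute(ds$pes, nw)
  }
  score <- function(de, imputation) {
    m <- confusion_metrics(tidy(de)$significant, truth$de_indicator)
    m$rmse <- if (is.null(imputation)) {
      NA_real_
    } else {
      miss <- imputation$missing_ids
      rmse(truth$true_normal[miss, , drop = FALSE],
           imputation$completed_normal[miss, , drop = FALSE])
    }
    m
  }
  purrr::map(methods, function(method) {
    res <- switch(
      method,
      knn_dependent = score(run_de_analysis(ds$pes, imp, "dependent", alpha), imp),
      knn_independent = score(run_de_analysis(ds$pes, imp, "independent", alpha), imp),
      mean_impute = {
        mi <- mean_impute(ds$pes)
        score(run_de_analysis(ds$pes, mi, "independent", alpha), mi)
      },
      case_deletion = score(run_de_analysis(ds$pes, NULL, "case_deletion", alpha), NULL),
      full = {
        full_pes <- paired_expression_set(truth$true_normal, ds$pes$tumor)
        score(run_de_analysis(full_pes, NULL, "independent", alpha), NULL)
      }
    )
    dplyr::mutate(res, method = method, .before = 1L)
  }) |>
    purrr::list_rbind()
}

#' Aggregate a study report over replicates
#'
#' @param report A `study_report` from [run_study()].
#' @return A tibble with one row per (cell, method): replicate count and the
#'   mean and SD of TPR, FPR, FDR, RMSE.
#' @export
summarize_study <- function(report) {
  report |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$N, .data$missing_fraction, .data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      dplyr::across(
        c("tpr", "fpr", "fdr", "rmse"),
        list(mean = ~ mean(.x), sd = ~ sd(.x))
      ),
      .groups = "drop"
    )
}

#' @describeIn run_study Mean TPR and empirical FDR per method across missing
#'   fractions, faceted by sample size, with the nominal FDR level marked.
#' @param object A `study_report`.
#' @param nominal_fdr Reference level drawn on the FDR panel.
#' @export
autoplot.study_report <- function(object, nominal_fdr = 0.05, ...) {
  long <- summarize_study(object) |>
    tidyr::pivot_longer(
      c("tpr_mean", "fdr_mean"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      tpr_mean = "TPR", fdr_mean = "empirical FDR"
    ))
  ref <- tibble::tibble(metric = "empirical FDR", yintercept = nominal_fdr)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$missing_fraction, y = .data$value, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = ref, ggplot2::aes(yintercept = .data$yintercept),
      linetype = "dotted", colour = "red"
    ) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$metric), ggplot2::vars(.data$N),
      scales = "free_y",
      labeller = ggplot2::labeller(.cols = function(x) paste0("N = ", x))
    ) +
    ggplot2::labs(x = "missing fraction", y = NULL, colour = "method") +
    ggplot2::theme_minimal()
}

#' Sweep the neighbor count and score imputation RMSE
#'
#' For each replicate, simulates one dataset and imputes its masked rows at
#' every candidate `k`, so the RMSE curve across `k` is computed on identical
#' data within a replicate. Used to choose `k`: the curve drops steeply for
#' small `k` and flattens past about 10 neighbors.
#'
#' @param N Subjects.
#' @param missing_fraction Fraction of masked normal rows.
#' @param k_values Candidate neighbor counts.
#' @param n_reps Replicates.
#' @param seed Base seed (`rep_seed = seed + rep`).
#' @param ... Further [sim_config()] overrides.
#' @return A `k_sweep` tibble: `k`, `rep`, `rmse`.
#' @export
sweep_k <- function(N, missing_fraction = 0.3,
                    k_values = c(1, 2, 5, 10, 15, 20, 25),
                    n_reps = 3, seed = 1, ...) {
  out <- purrr::map(seq_len(n_reps), function(rep) {
    cfg <- sim_config(
      N = N, missing_fraction = missing_fraction,
      k = max(k_values), seed = seed + rep, ...
    )
    ds <- simulate_dataset(cfg)
    D <- covariate_distance(ds$cov)
    miss <- ds$pes$subject_ids[ds$pes$missing_mask]
    purrr::map(k_values, function(k) {
      nw <- neighbor_weights(D, ds$pes$missing_mask, k = k)
      imp <- knn_impute(ds$pes, nw)
      tibble::tibble(
        k = k, rep = rep,
        rmse = rmse(ds$truth$true_normal[miss, , drop = FALSE],
                    imp$completed_normal[miss, , drop = FALSE])
      )
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  class(out) <- c("k_sweep", class(out))
  out
}

#' @describeIn sweep_k Mean RMSE (with per-replicate points) against `k`.
#' @param object A `k_sweep`.
#' @param ... Unused.
#' @export
autoplot.k_sweep <- function(object, ...) {
  means <- object |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$k, y = .data$rmse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      alpha = 0.4, colour = "steelblue"
    ) +
    ggplot2::labs(x = "number of neighbors k", y = "imputation RMSE") +
    ggplot2::theme_minimal()
}
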