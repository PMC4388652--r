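#' Simulation configuration
#'
#' Parameters of the synthetic paired miRNA study used throughout the
#' benchmarking framework. Defaults reproduce the study conditions the method
#' was developed under: G = 2000 features, 20% truly differentially expressed,
#' null mean 2 and DE tumor mean 2.5 at common standard deviation 1.25
#' (i.e. a mean tumor-normal shift of 0.5), z = 20 DE tumor features driving
#' the simulated covariates, continuous-covariate slopes uniform over 2% of
#' the covariate's min/max, covariate noise variance 10% of the covariate's
#' variance, and 25 replicate simulations.
#'
#' @param N Number of subjects.
#' @param G Number of features (default 2000).
#' @param de_fraction Fraction of features truly differentially expressed in
#'   tumor (default 0.20).
#' @param mu_null Mean of all normal-sample features and of non-DE tumor
#'   features (default 2).
#' @param mu_de Mean of DE tumor features (default 2.5).
#' @param sigma Common standard deviation (default 1.25).
#' @param missing_fraction Fraction of subjects whose normal sample is masked
#'   (default 0.5).
#' @param z Number of randomly chosen truly-DE tumor features driving every
#'   simulated covariate (default 20).
#' @param cont_beta_frac Continuous-covariate slopes are drawn uniformly from
#'   `[cont_beta_frac * min, cont_beta_frac * max]` of the covariate's base
#'   range (default 0.02).
#' @param eps_var_frac Continuous-covariate noise variance as a fraction of
#'   the covariate's base variance (default 0.10).
#' @param k Neighbor count the study will use (default 10).
#' @param n_reps Replicate simulations per condition (default 25).
#' @param seed Optional RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(N, G = 2000, de_fraction = 0.20, mu_null = 2,
                       mu_de = 2.5, sigma = 1.25, missing_fraction = 0.5,
                       z = 20, cont_beta_frac = 0.02, eps_var_frac = 0.10,
                       k = 10, n_reps = 25, seed = NULL) {
  stopifnot(
    N >= 3, G >= 1,
    de_fraction >= 0, de_fraction < 1,
    missing_fraction > 0, missing_fraction < 1,
    sigma > 0, z >= 0, z <= round(de_fraction * G)
  )
  structure(
    list(
      N = as.integer(N), G = as.integer(G), de_fraction = de_fraction,
      mu_null = mu_null, mu_de = mu_de, sigma = sigma,
      missing_fraction = missing_fraction, z = as.integer(z),
      cont_beta_frac = cont_beta_frac, eps_var_frac = eps_var_frac,
      k = k, n_reps = as.integer(n_reps), seed = seed
    ),
    class = "sim_config"
  )
}

#' Base characteristics of the simulated covariates
#'
#' Synthetic stand-in profiles for the five continuous (age, cigarettes/day,
#' calories, BMI, lutein + zeaxanthin concentration) and five binary (gender,
#' recent aspirin/NSAID use, recent smoker, menopause, HRT use) demographic
#' and lifestyle variables a colorectal-cancer cohort would record. The
#' cohort's real summary statistics are not public, so these are plausible
#' values (age in years, calories in kcal/day, BMI in kg/m^2, concentration in
#' umol/L); nothing downstream depends on their specific magnitudes, and each
#' can be overridden. Variance defaults to `((max - min) / 4)^2`.
#'
#' @return A list with tibbles `continuous` (`name`, `mean`, `min`, `max`,
#'   `var`) and `binary` (`name`, `mode`).
#' @export
default_covariate_profiles <- function() {
  continuous <- tibble::tibble(
    name = c("age", "cigarettes_per_day", "calories", "bmi", "lutein_zeaxanthin"),
    mean = c(65, 5, 2000, 27, 1.5),
    min = c(30, 0, 800, 17, 0.1),
    max = c(79, 60, 4500, 45, 6)
  )
  continuous$var <- ((continuous$max - continuous$min) / 4)^2
  binary <- tibble::tibble(
    name = c("female", "aspirin_nsaid", "recent_smoker", "menopause", "hrt_use"),
    mode = c(1, 0, 0, 1, 0)
  )
  list(continuous = continuous, binary = binary)
}

#' Simulate paired normal/tumor expression with known truth
#'
#' Every normal-sample feature and every non-DE tumor feature is drawn from
#' `Normal(mu_null, sigma^2)`; the `round(de_fraction * G)` DE tumor features
#' (chosen uniformly at random) are drawn from `Normal(mu_de, sigma^2)`.
#' Uses the current RNG stream; seed it (or via [simulate_dataset()]) for
#' reproducibility.
#'
#' @param cfg A [sim_config()].
#' @return A list with `pes` (an unmasked [paired_expression_set()]) and
#'   `truth` (class `simulation_truth`: `true_normal`, logical `de_indicator`
#'   named by feature, and `params = cfg`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  subject_ids <- sprintf("s%03d", seq_len(cfg$N))
  feature_ids <- sprintf("mir%04d", seq_len(cfg$G))
  n_de <- round(cfg$de_fraction * cfg$G)
  de <- setNames(logical(cfg$G), feature_ids)
  de[sample.int(cfg$G, n_de)] <- TRUE
  normal <- matrix(
    rnorm(cfg$N * cfg$G, cfg$mu_null, cfg$sigma), cfg$N, cfg$G,
    dimnames = list(subject_ids, feature_ids)
  )
  tumor <- matrix(
    rnorm(cfg$N * cfg$G, cfg$mu_null, cfg$sigma), cfg$N, cfg$G,
    dimnames = list(subject_ids, feature_ids)
  )
  if (n_de > 0L) {
    tumor[, de] <- tumor[, de] + (cfg$mu_de - cfg$mu_null)
  }
  truth <- structure(
    list(true_normal = normal, de_indicator = de, params = cfg),
    class = "simulation_truth"
  )
  list(pes = paired_expression_set(normal, tumor), truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(
    "<simulation_truth> ", nrow(x$true_normal), " subjects x ",
    ncol(x$true_normal), " features; ", sum(x$de_indicator), " truly DE\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate one continuous covariate from DE tumor expression
#'
#' `C = beta0 + sum_j beta_j x_j + eps`, where `beta0` is the covariate's base
#' mean, the `x_j` are the z driver features' tumor expression values,
#' `beta_j ~ U[beta_frac * base_min, beta_frac * base_max]` (drawn once,
#' shared across subjects), and `eps ~ Normal(0, eps_var_frac * base_var)`.
#' Because the drivers are truly DE tumor features, the covariate carries
#' expression signal by construction. `C` is not truncated to the base range.
#'
#' @param de_expr N x z matrix of tumor expression at the driver features.
#' @param base_mean,base_min,base_max,base_var Base characteristics of the
#'   covariate being emulated.
#' @param beta_frac,eps_var_frac See [sim_config()].
#' @return Numeric N-vector.
#' @export
simulate_continuous_covariate <- function(de_expr, base_mean, base_min, base_max,
                                          base_var, beta_frac = 0.02,
                                          eps_var_frac = 0.10) {
  stopifnot(is.matrix(de_expr))
  beta <- runif(ncol(de_expr), beta_frac * base_min, beta_frac * base_max)
  eps <- rnorm(nrow(de_expr), 0, sqrt(eps_var_frac * base_var))
  as.vector(base_mean + de_expr %*% beta + eps)
}

#' Simulate one binary covariate from DE tumor expression
#'
#' A logistic model: `logit(p) = beta0 + sum_j beta_j x_j` with `beta0` the
#' covariate's base mode and `beta_j ~ U[-0.5, 0.5]`. The fitted probabilities
#' are min-max rescaled to `[0, 1]` to guarantee variability, and a subject is
#' assigned 1 when the rescaled probability exceeds 0.5. If all probabilities
#' coincide (e.g. all slopes zero) every subject is assigned 0, with a
#' warning.
#'
#' @param de_expr N x z matrix of tumor expression at the driver features.
#' @param base_mode Base mode (0 or 1) of the emulated indicator, used as the
#'   logistic intercept.
#' @return Numeric N-vector of 0/1.
#' @export
simulate_binary_covariate <- function(de_expr, base_mode) {
  stopifnot(is.matrix(de_expr), nrow(de_expr) >= 2L)
  beta <- runif(ncol(de_expr), -0.5, 0.5)
  p_hat <- plogis(as.vector(base_mode + de_expr %*% beta))
  rng <- range(p_hat)
  if (diff(rng) == 0) {
    warning("degenerate binary covariate: all probabilities equal; assigning 0 to every subject")
    return(rep(0, nrow(de_expr)))
  }
  p_scaled <- (p_hat - rng[1L]) / diff(rng)
  as.numeric(p_scaled > 0.5)
}

#' Simulate the full covariate table from DE tumor expression
#'
#' Draws z driver features uniformly from the truly DE set and builds every
#' continuous and binary covariate from their TUMOR expression (tumor samples
#' are fully observed, so covariates remain computable for normal-missing
#' subjects).
#'
#' @param tumor N x G tumor matrix.
#' @param de_indicator Logical G-vector of true DE status.
#' @param cfg A [sim_config()].
#' @param profiles Covariate base characteristics, see
#'   [default_covariate_profiles()].
#' @return A [covariate_table()] over the same subjects.
#' @export
simulate_covariates <- function(tumor, de_indicator, cfg,
                                profiles = default_covariate_profiles()) {
  stopifnot(inherits(cfg, "sim_config"), sum(de_indicator) >= cfg$z)
  drivers <- sample(which(de_indicator), cfg$z)
  de_expr <- tumor[, drivers, drop = FALSE]
  cont <- purrr::pmap(profiles$continuous, function(name, mean, min, max, var) {
    simulate_continuous_covariate(
      de_expr, mean, min, max, var,
      beta_frac = cfg$cont_beta_frac, eps_var_frac = cfg$eps_var_frac
    )
  })
  names(cont) <- profiles$continuous$name
  bin <- purrr::pmap(profiles$binary, function(name, mode) {
    simulate_binary_covariate(de_expr, mode)
  })
  names(bin) <- profiles$binary$name
  data <- tibble::tibble(subject_id = rownames(tumor), !!!cont, !!!bin)
  covariate_table(data, binary_cols = profiles$binary$name)
}

#' Mask whole normal rows completely at random
#'
#' Chooses `round(missing_fraction * N)` subjects uniformly at random and
#' replaces their entire normal rows with `NA` (whole-sample missingness,
#' MCAR by construction). Tumor rows are untouched; the pre-masking values
#' stay available in the simulation truth for RMSE scoring.
#'
#' @param pes An unmasked [paired_expression_set()].
#' @param missing_fraction Fraction of subjects to mask, in (0, 1).
#' @param k Optional neighbor count; errors early if fewer than `k` observed
#'   subjects would remain.
#' @return The masked `paired_expression_set`.
#' @export
apply_missingness <- function(pes, missing_fraction, k = NULL) {
  stopifnot(
    inherits(pes, "paired_expression_set"),
    missing_fraction > 0, missing_fraction < 1
  )
  n <- length(pes$subject_ids)
  s <- round(missing_fraction * n)
  if (!is.null(k) && n - s < k) {
    stop("masking ", s, " of ", n, " subjects leaves fewer than k = ", k, " donors")
  }
  masked <- pes$normal
  masked[sample.int(n, s), ] <- NA_real_
  paired_expression_set(masked, pes$tumor)
}

#' Simulate a complete study dataset
#'
#' One-shot generator: expression with known truth, covariates driven by DE
#' tumor features, and MCAR whole-row masking of the normal matrix.
#'
#' @param cfg A [sim_config()]; if `cfg$seed` is non-`NULL` the RNG is seeded
#'   first, making the dataset fully reproducible.
#' @return A list: `pes` (masked), `cov`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  expr <- simulate_expression(cfg)
  cov <- simulate_covariates(expr$pes$tumor, expr$truth$de_indicator, cfg)
  pes <- apply_missingness(expr$pes, cfg$missing_fraction, k = cfg$k)
  list(pes = pes, cov = cov, truth = expr$truth)
}
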