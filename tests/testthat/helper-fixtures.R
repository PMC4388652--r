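# Shared fixtures and independent oracles, all built in code.

make_toy_pes <- function(n = 6, g = 4, s = 2, seed = 42, mu = 2, sigma = 1.25) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  feats <- sprintf("f%02d", seq_len(g))
  normal <- matrix(rnorm(n * g, mu, sigma), n, g, dimnames = list(ids, feats))
  tumor <- matrix(rnorm(n * g, mu, sigma), n, g, dimnames = list(ids, feats))
  masked <- normal
  if (s > 0) masked[sample.int(n, s), ] <- NA_real_
  list(pes = paired_expression_set(masked, tumor), true_normal = normal)
}

make_toy_cov <- function(ids, p_c = 2, p_b = 1, seed = 7) {
  set.seed(seed)
  df <- data.frame(subject_id = ids)
  for (j in seq_len(p_c)) df[[paste0("c", j)]] <- rnorm(length(ids))
  for (j in seq_len(p_b)) df[[paste0("b", j)]] <- rbinom(length(ids), 1, 0.5)
  covariate_table(df, binary_cols = paste0("b", seq_len(p_b)))
}

# distance oracles: explicit double loops over subject pairs
euclid_oracle <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  D
}

hamming_oracle <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- sum(X[i, ] != X[j, ])
  }
  D
}

# imputation oracle: the per-cell weighted sum, no matrix algebra
impute_loop_oracle <- function(pes, nw) {
  out <- pes$normal
  for (subj in nw$missing_ids) {
    w <- nw$weights[[subj]]
    for (j in seq_along(pes$feature_ids)) {
      acc <- 0
      for (l in seq_along(w$neighbors)) {
        acc <- acc + w$a[[l]] * pes$normal[w$neighbors[[l]], j]
      }
      out[subj, j] <- acc
    }
  }
  out
}

# GLS oracle: whiten by the Cholesky factor of V, then ordinary least squares
whiten_gls_oracle <- function(d, V, df = length(d) - 1) {
  L <- t(chol(V))
  dw <- solve(L, d)
  onew <- solve(L, rep(1, length(d)))
  mu <- sum(onew * dw) / sum(onew^2)
  r <- dw - onew * mu
  sigma2 <- sum(r^2) / df
  var_mu <- sigma2 / sum(onew^2)
  list(
    mu_hat = mu, sigma2_hat = sigma2, var_mu_hat = var_mu,
    t_stat = mu / sqrt(var_mu),
    p_value = 2 * stats::pt(-abs(mu / sqrt(var_mu)), df)
  )
}

# a distance matrix with prescribed distances from one missing subject
# (subject "m") to observed subjects "o1".."oK"; other pairs arbitrary
dist_fixture <- function(obs_dists, fill = 10) {
  n <- length(obs_dists) + 1L
  ids <- c(paste0("o", seq_along(obs_dists)), "m")
  D <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  D[n, seq_along(obs_dists)] <- obs_dists
  D[seq_along(obs_dists), n] <- obs_dists
  D
}
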