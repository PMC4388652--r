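test_that("neighbor weights follow the 1 - D/Dmax rule with sum-to-one normalization", {
  # sorted neighbor distances (1, 3) with Dmax = 4: w = (0.75, 0.25), already normalized
  D <- dist_fixture(c(1, 3, 4))
  mask <- c(o1 = FALSE, o2 = FALSE, o3 = FALSE, m = TRUE)
  nw <- neighbor_weights(D, mask, k = 2)
  expect_equal(nw$weights$m$neighbors, c("o1", "o2"))
  expect_equal(nw$weights$m$w, c(0.75, 0.25))
  expect_equal(nw$weights$m$a, c(0.75, 0.25))

  # k = 1: normalization forces weight 1 whatever the distances
  nw1 <- neighbor_weights(D, mask, k = 1)
  expect_equal(nw1$weights$m$a, 1)

  # equidistant neighbors split evenly
  nw_eq <- neighbor_weights(dist_fixture(c(2, 2, 5)), mask, k = 2)
  expect_equal(nw_eq$weights$m$a, c(0.5, 0.5))

  # k spanning all donors: the farthest sits at Dmax and gets weight 0, kept
  nw_all <- neighbor_weights(D, mask, k = 3)
  expect_equal(nw_all$weights$m$a, c(0.75, 0.25, 0) / 1)
  expect_length(nw_all$weights$m$neighbors, 3L)

  expect_error(neighbor_weights(D, mask, k = 4), "exceeds the 3 fully observed")
})

test_that("boundary ties are broken by stable subject order; zero Dmax falls back to uniform", {
  D <- dist_fixture(c(1, 2, 2, 2))
  mask <- c(rep(FALSE, 4), TRUE)
  names(mask) <- rownames(D)
  nw <- neighbor_weights(D, mask, k = 2)
  expect_equal(nw$weights$m$neighbors, c("o1", "o2"))

  D0 <- dist_fixture(c(0, 0, 0))
  mask0 <- c(o1 = FALSE, o2 = FALSE, o3 = FALSE, m = TRUE)
  expect_warning(nw0 <- neighbor_weights(D0, mask0, k = 2), "uniform")
  expect_equal(nw0$weights$m$a, c(0.5, 0.5))
})

test_that("k = 'auto' is the square root of the donor count rounded to odd", {
  for (n_obs in c(25, 50, 144)) {
    D <- matrix(runif((n_obs + 1)^2), n_obs + 1, n_obs + 1)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    rownames(D) <- colnames(D) <- paste0("s", seq_len(n_obs + 1))
    mask <- c(rep(FALSE, n_obs), TRUE)
    k <- neighbor_weights(D, mask, k = "auto")$k
    expect_true(k %% 2 == 1)
    expect_lte(abs(k - sqrt(n_obs)), 1)
  }
})

test_that("imputed rows are the stated convex combinations of neighbor rows", {
  D <- dist_fixture(c(1, 3, 4))
  toy <- make_toy_pes(n = 4, g = 2, s = 0, seed = 5)
  normal <- toy$true_normal
  rownames(normal) <- rownames(D)
  normal["m", ] <- NA_real_
  tumor <- toy$pes$tumor
  rownames(tumor) <- rownames(D)
  pes <- paired_expression_set(normal, tumor)
  nw <- neighbor_weights(D, pes$missing_mask, k = 2)

  # hand arithmetic at weights (0.75, 0.25)
  pes$normal["o1", 1] <- 10
  pes$normal["o2", 1] <- 20
  imp <- knn_impute(pes, nw)
  expect_equal(imp$completed_normal["m", 1], 0.75 * 10 + 0.25 * 20)

  # neighbors sharing a value pass it through unchanged
  pes$normal[c("o1", "o2"), 2] <- 7.25
  imp2 <- knn_impute(pes, nw)
  expect_equal(imp2$completed_normal["m", 2], 7.25)
  # observed rows untouched
  expect_identical(
    imp2$completed_normal[c("o1", "o2", "o3"), ],
    pes$normal[c("o1", "o2", "o3"), ]
  )
})

test_that("per-cell loop and matrix forms of the imputation agree", {
  for (seed in 1:3) {
    toy <- make_toy_pes(n = 8, g = 5, s = 3, seed = seed)
    cov <- make_toy_cov(toy$pes$subject_ids, p_c = 3, p_b = 2, seed = seed + 50)
    D <- covariate_distance(cov)
    nw <- neighbor_weights(D, toy$pes$missing_mask, k = 3)
    imp <- knn_impute(toy$pes, nw)
    expect_equal(imp$completed_normal, impute_loop_oracle(toy$pes, nw), tolerance = 1e-10)

    # convexity: every imputed value within its neighbors' range
    for (subj in nw$missing_ids) {
      nb <- toy$pes$normal[nw$weights[[subj]]$neighbors, , drop = FALSE]
      expect_true(all(imp$completed_normal[subj, ] >= apply(nb, 2, min) - 1e-12))
      expect_true(all(imp$completed_normal[subj, ] <= apply(nb, 2, max) + 1e-12))
    }

    # weight-matrix columns are convex weights
    expect_equal(unname(colSums(imp$A)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(imp$A >= 0))
  }
})

test_that("imputation preserves a constant feature exactly", {
  toy <- make_toy_pes(n = 7, g = 3, s = 2, seed = 9)
  toy$pes$normal[!toy$pes$missing_mask, 2] <- 4.5
  cov <- make_toy_cov(toy$pes$subject_ids, seed = 10)
  nw <- neighbor_weights(covariate_distance(cov), toy$pes$missing_mask, k = 3)
  imp <- knn_impute(toy$pes, nw)
  expect_equal(unname(imp$completed_normal[, 2]), rep(4.5, 7))
})

test_that("the induced covariance has the documented block structure", {
  # weights (0.6, 0.4) at donors o1, o2 of 3: bottom-right block = 0.52
  D <- dist_fixture(c(1, 2, 4))
  mask <- c(o1 = FALSE, o2 = FALSE, o3 = FALSE, m = TRUE)
  nw <- neighbor_weights(D, mask, k = 2)
  expect_equal(nw$weights$m$a, c(0.6, 0.4))
  is_ <- induced_sigma(nw)
  expect_equal(unname(is_$sigma[4, 4]), 0.36 + 0.16)
  expect_equal(unname(is_$sigma[1:3, 4]), c(0.6, 0.4, 0))
  expect_equal(unname(is_$sigma[1:3, 1:3]), diag(3))
  expect_equal(is_$order, c(1L, 2L, 3L, 4L))

  # no missing subjects: identity, no induced dependence
  nw0 <- neighbor_weights(D, setNames(rep(FALSE, 4), rownames(D)), k = 2)
  expect_equal(unname(induced_sigma(nw0)$sigma), diag(4))
})

test_that("the imputed-block Gram matrix is symmetric PSD with diagonal at most 1", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:15, 1)
    s <- sample(1:3, 1)
    toy <- make_toy_pes(n = n, g = 2, s = s, seed = seed + 200)
    cov <- make_toy_cov(toy$pes$subject_ids, p_c = 3, p_b = 2, seed = seed + 300)
    nw <- neighbor_weights(covariate_distance(cov), toy$pes$missing_mask,
                           k = min(3, n - s))
    sig <- induced_sigma(nw)$sigma
    expect_equal(sig, t(sig))
    gram <- sig[(n - s + 1):n, (n - s + 1):n, drop = FALSE]
    expect_true(all(diag(gram) <= 1 + 1e-12))
    expect_gte(min(eigen(gram, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("imputation is equivariant to subject permutation", {
  toy <- make_toy_pes(n = 9, g = 4, s = 3, seed = 33)
  cov_df <- data.frame(
    subject_id = toy$pes$subject_ids,
    c1 = rnorm(9), c2 = rnorm(9), b1 = rbinom(9, 1, 0.5)
  )
  run <- function(df, normal, tumor) {
    cov <- covariate_table(df, binary_cols = "b1")
    pes <- paired_expression_set(normal, tumor)
    nw <- neighbor_weights(covariate_distance(cov), pes$missing_mask, k = 3)
    knn_impute(pes, nw)$completed_normal
  }
  base <- run(cov_df, toy$pes$normal, toy$pes$tumor)
  set.seed(1)
  perm <- sample(9)
  permuted <- run(cov_df[perm, ], toy$pes$normal[perm, ], toy$pes$tumor[perm, ])
  expect_equal(permuted[toy$pes$subject_ids, ], base)
})

test_that("mean imputation is the uniform-weight, all-donor special case", {
  toy <- make_toy_pes(n = 6, g = 3, s = 2, seed = 44)
  mi <- mean_impute(toy$pes)
  obs <- toy$pes$subject_ids[!toy$pes$missing_mask]
  expect_equal(
    mi$completed_normal[mi$missing_ids[1], ],
    colMeans(toy$pes$normal[obs, ])
  )
  expect_equal(unname(colSums(mi$A)), rep(1, 2))
  expect_equal(unname(mi$sigma[1:4, 1:4]), diag(4))
})

test_that("tidied neighbor weights expose one row per (subject, neighbor)", {
  D <- dist_fixture(c(1, 3, 4))
  mask <- c(o1 = FALSE, o2 = FALSE, o3 = FALSE, m = TRUE)
  td <- tidy(neighbor_weights(D, mask, k = 2))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  expect_equal(td$weight, c(0.75, 0.25))
  expect_equal(td$rank, 1:2)
})
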