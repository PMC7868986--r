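test_that("restricted log-likelihood matches the closed form for an i.i.d. sample", {
  set.seed(21)
  n <- 30
  y <- rnorm(n, mean = 3, sd = 1.4)
  null_K <- kernel_set(list(null = matrix(0, n, n)))
  sse <- sum((y - mean(y))^2)
  # closed form: V = s2*I, X = intercept =>
  # L = -1/2 [ n log s2 + log(n/s2) + SSE/s2 ]
  for (s2 in c(0.5, 1, sse / (n - 1), 4)) {
    expected <- -0.5 * (n * log(s2) + log(n / s2) + sse / s2)
    got <- restricted_loglik(y, NULL, null_K,
                             variance_components(c(null = 0), s2))
    expect_equal(got, expected, tolerance = 1e-10)
  }
  # the closed-form REML maximizer is SSE/(n-1)
  s2_hat <- sse / (n - 1)
  ll_hat <- restricted_loglik(y, NULL, null_K, variance_components(c(null = 0), s2_hat))
  for (s2 in c(0.8, 1.2) * s2_hat) {
    expect_gt(ll_hat, restricted_loglik(y, NULL, null_K,
                                        variance_components(c(null = 0), s2)))
  }
})

test_that("REML estimates transform correctly under shifting and scaling of y", {
  ds <- make_tiny_dataset(n_parents = 30, n_hybrids = 70, seed = 5)
  ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
  fit <- reml_fit(ds$y, NULL, ks)

  fit_shift <- reml_fit(ds$y + 7, NULL, ks)
  expect_equal(fit_shift$vc$by_kernel, fit$vc$by_kernel, tolerance = 1e-3)
  expect_equal(fit_shift$vc$residual, fit$vc$residual, tolerance = 1e-3)
  expect_equal(unname(fit_shift$beta[1]), unname(fit$beta[1]) + 7, tolerance = 1e-6)

  c2 <- 2.5
  fit_scale <- reml_fit(ds$y * c2, NULL, ks)
  expect_equal(fit_scale$vc$by_kernel, fit$vc$by_kernel * c2^2, tolerance = 5e-3)
  expect_equal(fit_scale$vc$residual, fit$vc$residual * c2^2, tolerance = 5e-3)
})

test_that("the REML optimum dominates random perturbations of the components", {
  ds <- make_tiny_dataset(n_parents = 30, n_hybrids = 60, seed = 13)
  ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
  fit <- reml_fit(ds$y, NULL, ks)
  ll_opt <- fit$loglik
  set.seed(99)
  for (i in 1:40) {
    fac <- exp(rnorm(3, sd = 0.4))
    vc_p <- variance_components(fit$vc$by_kernel * fac[1:2],
                                max(fit$vc$residual * fac[3], 1e-10))
    expect_gte(ll_opt + 1e-7, restricted_loglik(ds$y, NULL, ks, vc_p))
  }
})

test_that("a duplicated kernel splits the variance its single copy would get", {
  ds <- make_tiny_dataset(n_parents = 30, n_hybrids = 70, seed = 23,
                          var_dominance = 0)
  K <- kinship_from_design(ds$design, "additive")
  single <- reml_fit(ds$y, NULL, kernel_set(list(Ka = K), check = FALSE))
  dup <- reml_fit(ds$y, NULL, kernel_set(list(Ka = K, Kb = K), check = FALSE))
  expect_equal(sum(dup$vc$by_kernel), sum(single$vc$by_kernel),
               tolerance = 0.02 * var(ds$y))
  expect_equal(dup$vc$residual, single$vc$residual, tolerance = 0.02 * var(ds$y))
})

test_that("zero genetic signal drives the kernel variance toward its floor", {
  set.seed(31)
  ds <- make_tiny_dataset(n_parents = 40, n_hybrids = 90, seed = 31)
  K <- kinship_from_design(ds$design, "additive")
  y_null <- rnorm(90)
  fit <- reml_fit(y_null, NULL, kernel_set(list(Ka = K), check = FALSE))
  expect_lt(fit$vc$by_kernel[["Ka"]], 0.15 * fit$vc$residual)
  expect_error(reml_fit(c(y_null[-1], NA), NULL,
                        kernel_set(list(Ka = K), check = FALSE)), "NA")
})

test_that("BLUP prediction reduces to the fixed part with zero covariance and beats the intercept otherwise", {
  ds <- make_tiny_dataset(n_parents = 50, n_hybrids = 150, seed = 41)
  n <- length(ds$y)
  tr <- 1:110
  te <- 111:150
  d_tr <- hyblup:::new_hybrid_design(
    ds$design$Z[tr, , drop = FALSE], ds$design$W[tr, , drop = FALSE],
    ds$design$cross_ids[tr], ds$design$feature_ids, "G", standardized = TRUE)
  ks_tr <- build_kernels(list(G = d_tr), "A+D", check = FALSE)
  fit <- reml_fit(ds$y[tr], NULL, ks_tr)

  zero21 <- lapply(ks_tr, function(K) {
    B <- matrix(0, length(te), length(tr))
    colnames(B) <- fit$train_ids
    B
  })
  expect_equal(unname(blup_predict(fit, zero21, allow_unconverged = TRUE)),
               rep(unname(fit$beta[1]), length(te)))

  m <- ncol(ds$design$Z)
  k21 <- list(
    G_add = tcrossprod(ds$design$Z[te, ], ds$design$Z[tr, ]) / m,
    G_dom = tcrossprod(ds$design$W[te, ], ds$design$W[tr, ]) / m)
  k21 <- lapply(k21, function(B) { colnames(B) <- fit$train_ids; B })
  pred <- blup_predict(fit, k21, allow_unconverged = TRUE)
  genetic_truth <- (ds$truth$TR1$additive_values + ds$truth$TR1$dominance_values)[te]
  expect_gt(cor(pred, genetic_truth)^2, 0.05)
  expect_gt(cor(pred, ds$y[te])^2, 0)

  # id-order guard
  bad <- k21
  colnames(bad$G_add) <- rev(colnames(bad$G_add))
  expect_error(blup_predict(fit, bad, allow_unconverged = TRUE), "order")
})

test_that("REML single-kernel simulation recovery has small mean bias", {
  ests <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    ds <- make_tiny_dataset(n_parents = 60, n_hybrids = 200, seed = 400 + r,
                            var_additive = 2, var_dominance = 0, var_residual = 1)
    K <- kinship_from_design(ds$design, "additive")
    fit <- reml_fit(ds$y, NULL, kernel_set(list(Ka = K), check = FALSE))
    ests[r, ] <- c(fit$vc$by_kernel[["Ka"]], fit$vc$residual)
  }
  m <- colMeans(ests)
  expect_lt(abs(m[1] - 2) / 2, 0.10)
  expect_lt(abs(m[2] - 1) / 1, 0.10)
})
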