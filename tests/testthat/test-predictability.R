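test_that("HAT matrix limits: zero genetic variance gives H = 0, vanishing residual gives H -> I", {
  ks <- random_kernels(10, 1, seed = 2)
  H0 <- hat_matrix_random(ks, variance_components(c(K1 = 0), 1))
  expect_equal(unname(H0), matrix(0, 10, 10))
  H1 <- hat_matrix_random(ks, variance_components(c(K1 = 1), 1e-12))
  expect_equal(unname(H1), diag(10), tolerance = 1e-8)
})

test_that("H xi reproduces the BLUP genetic prediction from the mixed-model solution", {
  ds <- make_tiny_dataset(n_parents = 15, n_hybrids = 20, seed = 6)
  ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
  fit <- reml_fit(ds$y, NULL, ks)
  H <- hat_matrix_random(ks, fit$vc)
  xi <- ds$y - fit$beta[1]
  # oracle: BLUP of the total genetic value, xi_hat = C V^-1 xi, computed
  # from first principles
  V <- assemble_covariance(ks, fit$vc)
  C <- fit$vc$by_kernel[["G_add"]] * ks$G_add + fit$vc$by_kernel[["G_dom"]] * ks$G_dom
  expect_equal(drop(H %*% xi), drop(C %*% solve(V, xi)), tolerance = 1e-10)
})

test_that("with no genetic signal in the model PRESS equals SS and r2 is zero", {
  set.seed(77)
  y <- rnorm(25)
  ks <- random_kernels(25, 1, seed = 3)
  vc0 <- variance_components(c(K1 = 0), 1)
  rep_n <- nfold_hat_press(y, NULL, ks, vc0)
  # H = 0 and an intercept-only GLS (= OLS mean) make PRESS the plain SS
  expect_equal(rep_n$press, sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(rep_n$r2, 0, tolerance = 1e-10)
  expect_equal(rep_n$press, brute_loocv_press(y, intercept_X(25), ks, vc0),
               tolerance = 1e-10)
})

test_that("n-fold HAT PRESS equals brute-force LOOCV PRESS at fixed components", {
  set.seed(52)
  cases <- expand.grid(n = c(50, 100, 150), k = 1:4)
  cases <- cases[rep(seq_len(nrow(cases)), length.out = 25), ]
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; k <- cases$k[i]
    ks <- random_kernels(n, k, seed = 1000 + i)
    vc <- variance_components(
      setNames(runif(k, 0.2, 2), names(ks)), runif(1, 0.3, 1.5))
    y <- rnorm(n)
    X <- intercept_X(n)
    hat <- nfold_hat_press(y, X, ks, vc)
    brute <- brute_loocv_press(y, X, ks, vc)
    expect_equal(hat$press, brute, tolerance = 1e-8)
    expect_lte(hat$r2, 1)
    expect_true(all(hat$leverages < 1))
  }
})

test_that("K-fold HAT PRESS equals brute-force leave-group-out PRESS and size-1 folds recover n-fold", {
  set.seed(53)
  for (i in 1:8) {
    n <- 60
    k_kern <- sample(1:3, 1)
    ks <- random_kernels(n, k_kern, seed = 2000 + i)
    vc <- variance_components(
      setNames(runif(k_kern, 0.2, 2), names(ks)), runif(1, 0.3, 1.5))
    y <- rnorm(n)
    X <- intercept_X(n)
    folds <- make_folds(n, sample(2:10, 1), seed = i)
    hat <- kfold_hat_press(y, X, ks, vc, folds)
    expect_equal(hat$press, brute_lgo_press(y, X, ks, vc, folds), tolerance = 1e-8)
  }
  # every fold of size one is exactly the n-fold formula
  n <- 40
  ks <- random_kernels(n, 2, seed = 3000)
  vc <- variance_components(c(K1 = 0.8, K2 = 0.5), 1)
  y <- rnorm(n)
  expect_equal(kfold_hat_press(y, NULL, ks, vc, seq_len(n))$press,
               nfold_hat_press(y, NULL, ks, vc)$press, tolerance = 1e-12)
})

test_that("cross-validation of pure noise has near-zero predictability and is seed-deterministic", {
  set.seed(71)
  n <- 500
  ks <- random_kernels(n, 1, seed = 4000)
  y <- rnorm(n)
  vc <- variance_components(c(K1 = 0.3), 1)
  cv1 <- cross_validate(y, NULL, ks, folds = 10, vc = vc, seed = 7)
  cv2 <- cross_validate(y, NULL, ks, folds = 10, vc = vc, seed = 7)
  expect_lt(cv1$r2_cor, 0.02)
  expect_identical(cv1$r2_cor, cv2$r2_cor)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
})

test_that("per-fold and full-sample variance component modes give similar predictability", {
  ds <- make_tiny_dataset(n_parents = 70, n_hybrids = 200, seed = 61)
  ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
  full <- cross_validate(ds$y, NULL, ks, folds = 5, vc_mode = "full_sample", seed = 3)
  per <- cross_validate(ds$y, NULL, ks, folds = 5, vc_mode = "per_fold", seed = 3)
  expect_lt(abs(full$r2_cor - per$r2_cor), 0.03)
})

test_that("HAT and brute CV coincide exactly under the PRESS definition with frozen parameters", {
  ds <- make_tiny_dataset(n_parents = 40, n_hybrids = 80, seed = 81)
  ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
  cmp <- compare_hat_cv(ds$y, NULL, ks, folds = "n",
                        beta_mode = "full_sample", definition = "press")
  expect_lt(abs(cmp$difference), 1e-8)
})

test_that("HAT and CV predictabilities agree in rank across datasets of varying heritability", {
  h_levels <- seq(0.2, 3, length.out = 10)
  r2_hat <- r2_cv <- numeric(length(h_levels))
  for (i in seq_along(h_levels)) {
    ds <- make_tiny_dataset(n_parents = 50, n_hybrids = 120, seed = 700 + i,
                            var_additive = h_levels[i],
                            var_dominance = h_levels[i] / 2, var_residual = 1)
    ks <- build_kernels(list(G = ds$design), "A+D", check = FALSE)
    fit <- reml_fit(ds$y, NULL, ks)
    r2_hat[i] <- nfold_hat_press(ds$y, NULL, ks, fit$vc)$r2
    r2_cv[i] <- cross_validate(ds$y, NULL, ks, folds = 10, vc = fit$vc, seed = i)$r2_cor
  }
  expect_gte(cor(r2_hat, r2_cv, method = "spearman"), 0.9)
})

test_that("adding a near-floor noise kernel barely changes the HAT predictability", {
  ds <- make_tiny_dataset(n_parents = 40, n_hybrids = 100, seed = 91)
  K <- kinship_from_design(ds$design, "additive")
  ks1 <- kernel_set(list(Ka = K), check = FALSE)
  fit <- reml_fit(ds$y, NULL, ks1)
  r2_base <- nfold_hat_press(ds$y, NULL, ks1, fit$vc)$r2
  Kn <- random_kernels(100, 1, seed = 5000)$K1
  dimnames(Kn) <- dimnames(K)
  ks2 <- kernel_set(list(Ka = K, Kn = Kn), check = FALSE)
  vc2 <- variance_components(c(Ka = fit$vc$by_kernel[["Ka"]],
                               Kn = 1e-8 * var(ds$y)), fit$vc$residual)
  r2_pert <- nfold_hat_press(ds$y, NULL, ks2, vc2)$r2
  expect_lt(abs(r2_pert - r2_base), 1e-4)
})
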