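# Shared fixtures (built in code) and independent brute-force oracles.

# Small simulated dataset: genotypes, a training plan, phenotypes and the
# standardized G design, all driven by one seed.
make_tiny_dataset <- function(n_parents = 40, n_hybrids = 80, seed = 1,
                              var_additive = 2, var_dominance = 1,
                              var_residual = 1, parental_trait_noise = 1,
                              n_traits = 1, markers_per_chromosome = 30,
                              n_chromosomes = 3) {
  cfg <- sim_config(n_parents = n_parents, n_hybrids = n_hybrids,
                    n_chromosomes = n_chromosomes,
                    markers_per_chromosome = markers_per_chromosome,
                    var_additive = var_additive,
                    var_dominance = var_dominance,
                    var_residual = var_residual,
                    parental_trait_noise = parental_trait_noise,
                    n_traits = n_traits, seed = seed)
  g <- simulate_parents(cfg)
  all_plan <- enumerate_crosses(g$parent_ids)
  set.seed(seed + 17)
  keep <- sort(sample.int(nrow(all_plan), min(n_hybrids, nrow(all_plan))))
  plan <- cross_plan(all_plan$female[keep], all_plan$male[keep])
  hyb <- suppressWarnings(simulate_hybrids(g, plan, cfg))
  list(config = cfg, genotypes = g, plan = plan, design = hyb$designs,
       y = hyb$phenotypes$TR1, phenotypes = hyb$phenotypes,
       parental = hyb$parental, truth = hyb$truth)
}

# A random synthetic kernel set (PSD by construction) for algebra tests.
random_kernels <- function(n, k, seed = 1) {
  set.seed(seed)
  mats <- lapply(seq_len(k), function(i) {
    D <- matrix(rnorm(n * (n + 5)), n)
    K <- tcrossprod(D) / ncol(D)
    rownames(K) <- colnames(K) <- sprintf("id%03d", seq_len(n))
    K
  })
  names(mats) <- paste0("K", seq_len(k))
  kernel_set(mats)
}

# GLS fixed-effect solution under V (independent of reml_core).
gls_beta <- function(y, X, V) {
  Vi_X <- solve(V, X)
  drop(solve(crossprod(X, Vi_X), crossprod(Vi_X, y)))
}

# Brute-force leave-one-out PRESS of the BLUP smoother at fixed variance
# components and full-sample fixed effects: predict xi_j from xi_{-j} by
# direct matrix partitioning (never calls the HAT code path).
brute_loocv_press <- function(y, X, kernels, vc) {
  V <- assemble_covariance(kernels, vc)
  n <- length(y)
  C <- V - diag(vc$residual, n)
  beta <- gls_beta(y, X, V)
  xi <- y - drop(X %*% beta)
  press <- 0
  for (j in seq_len(n)) {
    pred <- drop(C[j, -j, drop = FALSE] %*% solve(V[-j, -j], xi[-j]))
    press <- press + (xi[j] - pred)^2
  }
  unname(press)
}

# Brute-force leave-group-out PRESS, same conventions.
brute_lgo_press <- function(y, X, kernels, vc, fold_assignment) {
  V <- assemble_covariance(kernels, vc)
  n <- length(y)
  C <- V - diag(vc$residual, n)
  beta <- gls_beta(y, X, V)
  xi <- y - drop(X %*% beta)
  press <- 0
  for (k in unique(fold_assignment)) {
    te <- which(fold_assignment == k)
    tr <- setdiff(seq_len(n), te)
    pred <- drop(C[te, tr, drop = FALSE] %*% solve(V[tr, tr], xi[tr]))
    press <- press + sum((xi[te] - pred)^2)
  }
  unname(press)
}

intercept_X <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
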