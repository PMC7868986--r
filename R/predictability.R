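#' HAT matrix of the random effects
#'
#' With `C = sum_i K_i phi2_i` and `V = C + I sigma2`, the matrix
#' `H = C V^-1` maps the adjusted phenotypes `xi = y - X b` to their
#' fitted total genetic predictions `xi_hat = H xi`. Its diagonal (blocks)
#' yield exact leave-out prediction errors at fixed variance components
#' without refitting.
#'
#' @param kernels a `kernel_set`.
#' @param vc [variance_components()] estimated on the full sample.
#' @return the (generally non-symmetric) n x n HAT matrix.
#' @export
hat_matrix_random <- function(kernels, vc) {
  vc <- as_vc(vc, names(kernels))
  n <- nrow(kernels[[1L]])
  C <- matrix(0, n, n)
  for (nm in names(kernels)) {
    phi2 <- vc$by_kernel[[nm]]
    if (phi2 != 0) C <- C + kernels[[nm]] * phi2
  }
  V <- C + diag(vc$residual, n)
  # H = C V^-1 = (V^-1 C)' since both V and C are symmetric
  H <- t(solve(V, C))
  dimnames(H) <- dimnames(kernels[[1L]])
  H
}

new_predictability_report <- function(method, folds, press, ss, r2,
                                      r2_cor = NA_real_, leverages = NULL,
                                      fold_assignment = NULL,
                                      vc_mode = NA_character_, xi = NULL,
                                      extra = list()) {
  structure(
    c(list(method = method, folds = folds, press = press, ss = ss, r2 = r2,
           r2_cor = r2_cor, leverages = leverages,
           fold_assignment = fold_assignment, vc_mode = vc_mode, xi = xi,
           ss_convention = "mean_adjusted"),
      extra),
    class = "predictability_report")
}

#' @export
print.predictability_report <- function(x, ...) {
  cat(sprintf("<predictability_report> method %s, folds %s\n", x$method,
              as.character(x$folds)))
  cat(sprintf("  PRESS = %.6g  SS = %.6g  r2 (1 - PRESS/SS) = %.4f\n",
              x$press, x$ss, x$r2))
  if (is.finite(x$r2_cor)) {
    cat(sprintf("  r2 (squared correlation) = %.4f\n", x$r2_cor))
  }
  invisible(x)
}

# Shared preamble for the HAT-based evaluations: full-sample GLS beta and
# adjusted phenotypes under the supplied variance components.
hat_preamble <- function(y, X, kernels, vc) {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  vc <- as_vc(vc, names(kernels))
  V <- assemble_covariance(kernels, vc)
  core <- reml_core(y, X, V)
  xi <- y - drop(X %*% core$beta)
  H <- hat_matrix_random(kernels, vc)
  ehat <- xi - drop(H %*% xi)
  list(y = y, X = X, vc = vc, xi = xi, H = H, ehat = ehat, beta = core$beta)
}

press_ss <- function(y, X, ss_convention) {
  if (ss_convention == "mean_adjusted") {
    sum((y - mean(y))^2)
  } else {
    # adjust for the full fixed design by ordinary least squares
    sum(stats::lm.fit(X, y)$residuals^2)
  }
}

#' Leave-one-out (n-fold) predictability via the HAT method
#'
#' Computes the exact leave-one-out predicted residual error sum of
#' squares `PRESS = sum_j ehat_j^2 / (1 - H_jj)^2` at variance components
#' (and fixed effects) estimated once on the full sample, and the
#' predictability `r2 = 1 - PRESS / SS` with `SS` the total sum of squares
#' of `y` adjusted for the mean.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design (default intercept).
#' @param kernels a `kernel_set`.
#' @param vc full-sample [variance_components()], e.g. from [reml_fit()].
#' @param ss_convention `"mean_adjusted"` (default) or `"fixed_adjusted"`
#'   (SS from the residuals of an ordinary least-squares fit of `X`).
#' @return a `predictability_report` with per-observation leverages.
#' @export
nfold_hat_press <- function(y, X = NULL, kernels, vc,
                            ss_convention = c("mean_adjusted", "fixed_adjusted")) {
  ss_convention <- match.arg(ss_convention)
  p <- hat_preamble(y, X, kernels, vc)
  hjj <- diag(p$H)
  bad <- which(hjj >= 1 - 1e-10)
  if (length(bad)) {
    stop2("nfold_hat_press: leverage at 1 for observation(s) ",
          paste(bad, collapse = ", "), " (perfectly leveraged point)")
  }
  press <- sum((p$ehat / (1 - hjj))^2)
  ss <- press_ss(p$y, p$X, ss_convention)
  rep <- new_predictability_report(
    method = "hat", folds = length(p$y), press = press, ss = ss,
    r2 = 1 - press / ss, leverages = hjj, vc_mode = "full_sample", xi = p$xi)
  rep$ss_convention <- ss_convention
  rep
}

#' K-fold predictability via the HAT method
#'
#' Block version of [nfold_hat_press()]: for each fold `k` the predicted
#' residual is `e_k = (I - H_kk)^-1 ehat_k` with `H_kk` the fold's
#' diagonal block of the HAT matrix, and `PRESS = sum_k e_k' e_k`. At
#' fixed variance components this equals brute-force leave-group-out
#' prediction error exactly.
#'
#' @inheritParams nfold_hat_press
#' @param fold_assignment integer vector assigning each observation to a
#'   fold (a partition; see [make_folds()]).
#' @return a `predictability_report`.
#' @export
kfold_hat_press <- function(y, X = NULL, kernels, vc, fold_assignment,
                            ss_convention = c("mean_adjusted", "fixed_adjusted")) {
  ss_convention <- match.arg(ss_convention)
  p <- hat_preamble(y, X, kernels, vc)
  n <- length(p$y)
  fold_assignment <- as.integer(fold_assignment)
  if (length(fold_assignment) != n) {
    stop2("kfold_hat_press: fold_assignment must cover every observation")
  }
  press <- 0
  for (k in sort(unique(fold_assignment))) {
    idx <- which(fold_assignment == k)
    Hkk <- p$H[idx, idx, drop = FALSE]
    A <- diag(length(idx)) - Hkk
    ek <- tryCatch(solve(A, p$ehat[idx]), error = function(e) NULL)
    if (is.null(ek)) {
      stop2("kfold_hat_press: (I - H_kk) singular for fold ", k,
            "; try smaller folds or check for duplicated observations")
    }
    press <- press + sum(ek^2)
  }
  ss <- press_ss(p$y, p$X, ss_convention)
  rep <- new_predictability_report(
    method = "hat", folds = length(unique(fold_assignment)), press = press,
    ss = ss, r2 = 1 - press / ss, leverages = diag(p$H),
    fold_assignment = fold_assignment, vc_mode = "full_sample", xi = p$xi)
  rep$ss_convention <- ss_convention
  rep
}

#' Random fold assignment with balanced sizes
#'
#' @param n number of observations.
#' @param k number of folds (fold sizes differ by at most one).
#' @param seed integer seed (recorded by callers).
#' @return integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k, seed = NULL) {
  if (k < 2L || k > n) stop2("make_folds: need 2 <= k <= n")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Brute-force cross-validated predictability
#'
#' Splits the sample into folds, predicts each fold from the remaining
#' folds via the conditional-expectation BLUP formula, and reports the
#' predictability both as the squared Pearson correlation between the
#' pooled out-of-fold predictions and the observed phenotypes (the primary
#' definition) and as `1 - PRESS/SS`.
#'
#' @param y,X,kernels as in [nfold_hat_press()].
#' @param folds number of folds, or `"n"` / `length(y)` for leave-one-out.
#' @param vc_mode `"full_sample"`: variance components estimated once on
#'   the whole sample (supply `vc` or they are estimated internally);
#'   `"per_fold"`: REML is re-run on every training fold.
#' @param beta_mode `"per_fold"` (default): fixed effects re-estimated by
#'   GLS within each training fold; `"full_sample"`: fixed effects frozen
#'   at their full-sample estimates (the convention under which the HAT
#'   leave-out identity is exact).
#' @param n_repeats number of independent random partitions to average
#'   over (ignored for leave-one-out, which has a single partition).
#' @param seed integer seed controlling the partitions.
#' @param vc optional full-sample [variance_components()] to reuse.
#' @return a `predictability_report`; `r2_cor` holds the mean squared
#'   correlation across repeats, `r2` the mean PRESS-based value, and
#'   `repeats` the per-repeat values.
#' @export
cross_validate <- function(y, X = NULL, kernels, folds = 10,
                           vc_mode = c("full_sample", "per_fold"),
                           beta_mode = c("per_fold", "full_sample"),
                           n_repeats = 1, seed = 1, vc = NULL) {
  vc_mode <- match.arg(vc_mode)
  beta_mode <- match.arg(beta_mode)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  loo <- identical(folds, "n") || (is.numeric(folds) && folds == n)
  k <- if (loo) n else as.integer(folds)
  if (k < 2L) stop2("cross_validate: need at least 2 folds")

  full_vc <- NULL
  full_beta <- NULL
  if (vc_mode == "full_sample" || beta_mode == "full_sample") {
    if (is.null(vc)) {
      full_fit <- reml_fit(y, X, kernels)
      full_vc <- full_fit$vc
      full_beta <- full_fit$beta
    } else {
      full_vc <- as_vc(vc, names(kernels))
      full_beta <- reml_core(y, X, assemble_covariance(kernels, full_vc))$beta
    }
  }

  n_rep <- if (loo) 1L else as.integer(n_repeats)
  r2_cor_rep <- numeric(n_rep)
  r2_press_rep <- numeric(n_rep)
  last_assignment <- NULL
  for (rep_i in seq_len(n_rep)) {
    assignment <- if (loo) seq_len(n) else
      make_folds(n, k, seed = derive_seed(seed, rep_i))
    pred <- numeric(n)
    for (fk in sort(unique(assignment))) {
      te <- which(assignment == fk)
      tr <- setdiff(seq_len(n), te)
      if (length(tr) < 2L) stop2("cross_validate: fold with < 2 training observations")
      K11 <- lapply(kernels, function(K) K[tr, tr, drop = FALSE])
      K21 <- lapply(kernels, function(K) K[te, tr, drop = FALSE])
      if (vc_mode == "per_fold") {
        fit_k <- reml_fit(y[tr], X[tr, , drop = FALSE], kernel_set(K11, check = FALSE))
        vck <- fit_k$vc
        betak <- fit_k$beta
      } else {
        vck <- full_vc
        if (beta_mode == "full_sample") {
          betak <- full_beta
        } else {
          V11 <- assemble_covariance(K11, vck)
          betak <- reml_core(y[tr], X[tr, , drop = FALSE], V11)$beta
        }
      }
      V11 <- assemble_covariance(K11, vck)
      C21 <- matrix(0, length(te), length(tr))
      for (nm in names(kernels)) {
        phi2 <- vck$by_kernel[[nm]]
        if (phi2 != 0) C21 <- C21 + K21[[nm]] * phi2
      }
      xi1 <- y[tr] - drop(X[tr, , drop = FALSE] %*% betak)
      pred[te] <- drop(X[te, , drop = FALSE] %*% betak) +
        drop(C21 %*% solve(V11, xi1))
    }
    r2_cor_rep[rep_i] <- if (sd(pred) < 1e-12) 0 else cor(pred, y)^2
    r2_press_rep[rep_i] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    last_assignment <- assignment
  }
  ss <- sum((y - mean(y))^2)
  new_predictability_report(
    method = "cv", folds = if (loo) n else k,
    press = mean((1 - r2_press_rep)) * ss, ss = ss,
    r2 = mean(r2_press_rep), r2_cor = mean(r2_cor_rep),
    fold_assignment = last_assignment, vc_mode = vc_mode,
    extra = list(beta_mode = beta_mode, n_repeats = n_rep, seed = seed,
                 repeats = data.frame(r2_cor = r2_cor_rep,
                                      r2_press = r2_press_rep)))
}

#' Side-by-side HAT and cross-validation predictabilities
#'
#' Runs the K-fold (or leave-one-out) HAT evaluation and brute-force
#' cross-validation on the same data and fold scheme. For K-fold runs both
#' methods are averaged over the same `n_repeats` random partitions.
#'
#' @inheritParams cross_validate
#' @param definition `"native"`: HAT uses `1 - PRESS/SS`, CV uses the
#'   squared correlation (each method's primary definition);
#'   `"press"`: both sides use `1 - PRESS/SS`.
#' @return a list with `r2_hat`, `r2_cv`, `difference`
#'   (`r2_hat - r2_cv`), the definition used, and the two full reports.
#' @export
compare_hat_cv <- function(y, X = NULL, kernels, folds = 10, n_repeats = 1,
                           seed = 1, vc = NULL,
                           vc_mode = c("full_sample", "per_fold"),
                           beta_mode = c("per_fold", "full_sample"),
                           definition = c("native", "press")) {
  vc_mode <- match.arg(vc_mode)
  beta_mode <- match.arg(beta_mode)
  definition <- match.arg(definition)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(vc)) vc <- reml_fit(y, X, kernels)$vc
  loo <- identical(folds, "n") || (is.numeric(folds) && folds == n)

  if (loo) {
    hat_rep <- nfold_hat_press(y, X, kernels, vc)
    r2_hat <- hat_rep$r2
  } else {
    r2s <- vapply(seq_len(n_repeats), function(i) {
      fa <- make_folds(n, as.integer(folds), seed = derive_seed(seed, i))
      kfold_hat_press(y, X, kernels, vc, fa)$r2
    }, 0)
    r2_hat <- mean(r2s)
    hat_rep <- kfold_hat_press(y, X, kernels, vc,
                               make_folds(n, as.integer(folds),
                                          seed = derive_seed(seed, 1L)))
  }
  cv_rep <- cross_validate(y, X, kernels, folds = folds, vc_mode = vc_mode,
                           beta_mode = beta_mode, n_repeats = n_repeats,
                           seed = seed, vc = vc)
  r2_cv <- if (definition == "press") cv_rep$r2 else cv_rep$r2_cor
  list(r2_hat = r2_hat, r2_cv = r2_cv, difference = r2_hat - r2_cv,
       definition = definition, folds = if (loo) n else folds,
       hat_report = hat_rep, cv_report = cv_rep)
}
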