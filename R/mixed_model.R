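# Cholesky with escalating diagonal jitter; V must be symmetric.
# Returns the upper-triangular factor R with V = R'R.
chol_jitter <- function(V, jitters = c(0, 1e-10, 1e-8, 1e-6)) {
  scale <- mean(diag(V))
  for (j in jitters) {
    R <- tryCatch(chol(V + diag(j * scale, nrow(V))), error = function(e) NULL)
    if (!is.null(R)) {
      if (j > 0) {
        message(sprintf("covariance factorization needed diagonal jitter %.1e", j))
      }
      return(R)
    }
  }
  stop2("covariance matrix is numerically singular even after jittering")
}

# Core REML computations under a given V. Returns the restricted
# log-likelihood together with the GLS fixed-effect solution.
reml_core <- function(y, X, V) {
  R <- chol_jitter(V)
  logdetV <- 2 * sum(log(diag(R)))
  # half-solves: t(R) %*% a = rhs
  a_y <- forwardsolve(t(R), y)
  a_X <- forwardsolve(t(R), X)
  XtViX <- crossprod(a_X)
  XtViy <- crossprod(a_X, a_y)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) {
    stop2("restricted_loglik: X'V^-1 X is singular; check for collinear fixed-effect columns")
  }
  beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), XtViy))
  r <- y - X %*% beta
  a_r <- forwardsolve(t(R), r)
  quad <- sum(a_r^2)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cXtViX))) + quad)
  list(loglik = as.numeric(ll), beta = drop(beta), chol_V = R,
       resid = drop(r), quad = quad)
}

#' Restricted log-likelihood of a multi-kernel mixed model
#'
#' Evaluates `L = -1/2 log|V| - 1/2 log|X'V^-1 X| - 1/2 (y - X b)' V^-1
#' (y - X b)` with `b` the generalized least-squares solution under
#' `V = sum_i K_i phi2_i + I sigma2`.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full column rank); defaults to an
#'   intercept.
#' @param kernels a `kernel_set`.
#' @param vc [variance_components()] matched to the kernels.
#' @return the restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, X = NULL, kernels, vc) {
  y <- as.numeric(y)
  if (anyNA(y)) stop2("restricted_loglik: NA in y")
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  V <- assemble_covariance(kernels, vc)
  reml_core(y, X, V)$loglik
}

#' Fit a multi-kernel mixed model by REML
#'
#' Maximizes the restricted likelihood over log-reparameterized variance
#' components (one per kernel plus a residual) with a quasi-Newton
#' optimizer and numerical gradients. Non-negativity is enforced by the
#' log parameterization with a small floor (`1e-8 * var(y)`). Three
#' deterministic starting points are tried (equal split, residual-heavy
#' and genetic-heavy) and the best optimum is kept.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param X fixed-effect design; defaults to an intercept-only column.
#' @param kernels a `kernel_set` aligned to `y`.
#' @param max_iter maximum optimizer iterations per start (default 200).
#' @param reltol relative log-likelihood convergence tolerance (default
#'   1e-8).
#' @return an object of class `blup_fit` with elements `vc`
#'   ([variance_components()]), `beta`, `X_spec` (column labels),
#'   `loglik`, `converged`, `n_iter`, `train_ids`, plus the training data
#'   (`y`, `X`, `kernels`) needed for downstream prediction.
#' @export
reml_fit <- function(y, X = NULL, kernels, max_iter = 200, reltol = 1e-8) {
  y <- as.numeric(y)
  if (anyNA(y)) stop2("reml_fit: NA in y")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  q <- ncol(X)
  if (n < q + 2L) stop2("reml_fit: need at least q + 2 observations")
  if (qr(X)$rank < q) stop2("reml_fit: fixed-effect design is rank deficient")
  if (nrow(kernels[[1L]]) != n) stop2("reml_fit: kernels not aligned to y")

  k <- length(kernels)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop2("reml_fit: y has no variance")
  floor_vc <- 1e-8 * vy

  theta_of <- function(lambda) floor_vc + exp(lambda)
  nll <- function(lambda) {
    th <- theta_of(lambda)
    vc <- variance_components(setNames(th[seq_len(k)], names(kernels)), th[k + 1L])
    V <- assemble_covariance(kernels, vc)
    ll <- tryCatch(reml_core(y, X, V)$loglik, error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- list(
    equal = rep(vy / (k + 1), k + 1L),
    residual_heavy = c(rep(0.1 * vy / max(k, 1), k), 0.9 * vy),
    genetic_heavy = c(rep(0.9 * vy / max(k, 1), k), 0.1 * vy)
  )
  best <- NULL
  n_iter_total <- 0L
  for (s in starts) {
    lam0 <- log(pmax(s - floor_vc, floor_vc))
    res <- tryCatch(
      optim(lam0, nll, method = "BFGS",
            control = list(maxit = max_iter, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_iter_total <- n_iter_total + as.integer(res$counts[["function"]])
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop2("reml_fit: optimization failed from all starting points")
  converged <- best$convergence == 0L
  if (!converged) {
    warn2("reml_fit: optimizer did not report convergence; returning best iterate")
  }

  th <- theta_of(best$par)
  vc <- variance_components(setNames(th[seq_len(k)], names(kernels)), th[k + 1L])
  V <- assemble_covariance(kernels, vc)
  core <- reml_core(y, X, V)
  structure(
    list(vc = vc,
         beta = setNames(core$beta, colnames(X)),
         X_spec = colnames(X),
         loglik = core$loglik,
         converged = converged,
         n_iter = n_iter_total,
         train_ids = rownames(kernels[[1L]]) %||% as.character(seq_len(n)),
         y = y, X = X, kernels = kernels),
    class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit> n = %d, %d kernel(s), logLik = %.4f (%s, %d evals)\n",
              length(x$y), length(x$kernels), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  variance components:\n")
  for (nm in names(x$vc$by_kernel)) {
    cat(sprintf("    %-12s %.6g\n", nm, x$vc$by_kernel[[nm]]))
  }
  cat(sprintf("    %-12s %.6g\n", "residual", x$vc$residual))
  invisible(x)
}

#' BLUP prediction of unobserved crosses
#'
#' Predicts test-set phenotypes as the conditional expectation given the
#' training phenotypes: `y2_hat = X2 b + (sum_i K21_i phi2_i) V11^-1 (y1 -
#' X1 b)`, with all parameters taken from the fitted model.
#'
#' @param fit a `blup_fit`.
#' @param kernels21 named list of test x train kernel blocks (names and
#'   column order must match the fit's kernels / training ids).
#' @param X2 fixed-effect design for the test set; defaults to an
#'   intercept column.
#' @param allow_unconverged predict from a non-converged fit (otherwise an
#'   error).
#' @return numeric vector of predicted phenotypes (named by test row ids
#'   when available).
#' @export
blup_predict <- function(fit, kernels21, X2 = NULL, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "blup_fit"))
  if (!fit$converged && !allow_unconverged) {
    stop2("blup_predict: fit did not converge (set allow_unconverged = TRUE to override)")
  }
  if (!setequal(names(kernels21), names(fit$kernels))) {
    stop2("blup_predict: kernel block names do not match the fitted kernels")
  }
  n1 <- length(fit$y)
  n2 <- nrow(kernels21[[1L]])
  for (nm in names(kernels21)) {
    B <- kernels21[[nm]]
    if (ncol(B) != n1) stop2("blup_predict: block ", nm, " has wrong training dimension")
    cn <- colnames(B)
    if (!is.null(cn) && !identical(cn, fit$train_ids)) {
      stop2("blup_predict: block ", nm, " columns are not in training-id order")
    }
  }
  if (is.null(X2)) X2 <- matrix(1, n2, 1)
  X2 <- as.matrix(X2)
  if (ncol(X2) != length(fit$beta)) {
    stop2("blup_predict: X2 has ", ncol(X2), " column(s) but the fit has ",
          length(fit$beta), " fixed effect(s)")
  }
  C21 <- matrix(0, n2, n1)
  for (nm in names(kernels21)) {
    phi2 <- fit$vc$by_kernel[[nm]]
    if (phi2 != 0) C21 <- C21 + kernels21[[nm]] * phi2
  }
  V11 <- assemble_covariance(fit$kernels, fit$vc)
  xi <- fit$y - drop(fit$X %*% fit$beta)
  pred <- drop(X2 %*% fit$beta) + drop(C21 %*% solve(V11, xi))
  names(pred) <- rownames(kernels21[[1L]])
  pred
}
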