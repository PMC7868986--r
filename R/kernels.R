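#' Kinship matrix from a standardized hybrid design
#'
#' Builds the additive kernel `K = Z Z' / m` or the dominance kernel
#' `K = W W' / m`, where `m` is the number of features in the layer. With
#' column-standardized designs (population variance convention) the
#' diagonal of each kernel averages one.
#'
#' @param design a standardized `hybrid_design`.
#' @param part `"additive"` (use `Z`) or `"dominance"` (use `W`).
#' @param trace_normalize if `TRUE`, rescale the kernel so its mean
#'   diagonal is exactly one (off by default; the canonical scaling is
#'   1/m).
#' @return a symmetric crosses x crosses matrix with attributes `layer`,
#'   `part` and `m`.
#' @export
kinship_from_design <- function(design, part = c("additive", "dominance"),
                                trace_normalize = FALSE) {
  stopifnot(inherits(design, "hybrid_design"))
  part <- match.arg(part)
  if (!isTRUE(design$standardized)) {
    stop2("kinship_from_design: standardize the design first (standardize_columns)")
  }
  D <- if (part == "additive") design$Z else design$W
  m <- ncol(D)
  if (m == 0L) stop2("kinship_from_design: design has zero features")
  K <- tcrossprod(D) / m
  if (trace_normalize) {
    md <- mean(diag(K))
    if (md > 0) K <- K / md
  }
  attr(K, "layer") <- design$layer
  attr(K, "part") <- part
  attr(K, "m") <- m
  K
}

#' Bundle named kinship matrices into a kernel set
#'
#' Validates that all kernels are symmetric, positive semi-definite (up to
#' a small numerical tolerance) and share one row ordering.
#'
#' @param matrices named list of square matrices (same dimension and row
#'   ids).
#' @param check run the symmetry / PSD validation (eigendecomposition;
#'   skip for very large candidate sets where the kernels are products of
#'   real designs by construction).
#' @return an object of class `kernel_set` (a named list of matrices with
#'   attribute `m` holding per-kernel feature counts when available).
#' @export
kernel_set <- function(matrices, check = TRUE) {
  if (!length(matrices)) stop2("kernel_set: empty kernel list")
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))) ||
      anyDuplicated(names(matrices))) {
    stop2("kernel_set: kernels must have unique non-empty names")
  }
  n <- nrow(matrices[[1L]])
  ids <- rownames(matrices[[1L]])
  for (nm in names(matrices)) {
    K <- matrices[[nm]]
    if (!is.matrix(K) || nrow(K) != ncol(K)) {
      stop2("kernel_set: kernel ", nm, " is not square")
    }
    if (nrow(K) != n) stop2("kernel_set: kernel ", nm, " has mismatched dimension")
    if (!is.null(ids) && !is.null(rownames(K)) && !identical(rownames(K), ids)) {
      stop2("kernel_set: kernel ", nm, " rows are ordered differently")
    }
    if (check) {
      if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K)))) {
        stop2("kernel_set: kernel ", nm, " is not symmetric")
      }
      ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
      tol <- 1e-8 * max(abs(ev), 1)
      if (min(ev) < -tol) {
        stop2(sprintf("kernel_set: kernel %s is not PSD (min eigenvalue %.3e)",
                      nm, min(ev)))
      }
    }
  }
  structure(matrices, class = "kernel_set",
            m = vapply(matrices, function(K) attr(K, "m") %||% NA_real_, 0))
}

#' Build additive (and optionally dominance) kernels for a set of layers
#'
#' @param designs named list of standardized `hybrid_design` objects; the
#'   names (e.g. `"G"`, `"T"`) become kernel name prefixes.
#' @param genetic_model `"A"` (additive kernels only) or `"A+D"`
#'   (additive plus dominance kernel per layer).
#' @param check passed to [kernel_set()].
#' @return a `kernel_set` with kernels named `<layer>_add` and, for
#'   `"A+D"`, `<layer>_dom`.
#' @export
build_kernels <- function(designs, genetic_model = c("A+D", "A"), check = TRUE) {
  genetic_model <- match.arg(genetic_model)
  if (is.null(names(designs))) names(designs) <- vapply(designs, `[[`, "", "layer")
  out <- list()
  for (nm in names(designs)) {
    out[[paste0(nm, "_add")]] <- kinship_from_design(designs[[nm]], "additive")
    if (genetic_model == "A+D") {
      out[[paste0(nm, "_dom")]] <- kinship_from_design(designs[[nm]], "dominance")
    }
  }
  kernel_set(out, check = check)
}

#' Variance components for a multi-kernel mixed model
#'
#' @param by_kernel named non-negative numeric vector, one entry per
#'   kernel.
#' @param residual positive residual variance.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(by_kernel, residual) {
  by_kernel <- unlist(by_kernel)
  if (is.null(names(by_kernel)) && length(by_kernel)) {
    stop2("variance_components: by_kernel must be named")
  }
  if (any(!is.finite(by_kernel)) || any(by_kernel < 0)) {
    stop2("variance_components: kernel variances must be finite and non-negative")
  }
  if (!is.finite(residual) || residual < 0) {
    stop2("variance_components: residual variance must be finite and non-negative")
  }
  structure(list(by_kernel = by_kernel, residual = residual),
            class = "variance_components")
}

#' Assemble the phenotypic covariance matrix
#'
#' `V = sum_i K_i * phi2_i + I * sigma2`.
#'
#' @param kernels a `kernel_set` (or plain named list of matrices).
#' @param vc a [variance_components()] object (or a list with elements
#'   `by_kernel`, `residual`); names must match the kernels.
#' @return a symmetric matrix.
#' @export
assemble_covariance <- function(kernels, vc) {
  vc <- as_vc(vc, names(kernels))
  n <- nrow(kernels[[1L]])
  V <- diag(vc$residual, n)
  for (nm in names(kernels)) {
    phi2 <- vc$by_kernel[[nm]]
    if (phi2 != 0) V <- V + kernels[[nm]] * phi2
  }
  dimnames(V) <- dimnames(kernels[[1L]])
  V
}

as_vc <- function(vc, kernel_names) {
  if (!inherits(vc, "variance_components")) {
    vc <- variance_components(vc$by_kernel, vc$residual)
  }
  missing <- setdiff(kernel_names, names(vc$by_kernel))
  if (length(missing)) {
    stop2("assemble_covariance: no variance component for kernel(s): ",
          paste(missing, collapse = ", "))
  }
  vc
}

#' Partition kernels into training/test blocks
#'
#' @param kernels a `kernel_set`.
#' @param train_ids,test_ids disjoint row-id (or index) subsets of the
#'   kernel ordering.
#' @return a list with one element per kernel, each holding `K11`
#'   (train x train), `K21` (test x train) and `K22` (test x test).
#' @export
partition_covariance <- function(kernels, train_ids, test_ids) {
  ids <- rownames(kernels[[1L]]) %||% seq_len(nrow(kernels[[1L]]))
  to_idx <- function(x) {
    if (is.character(x)) {
      idx <- match(x, ids)
      if (anyNA(idx)) stop2("partition_covariance: unknown id(s): ",
                            paste(x[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(x)
  }
  tr <- to_idx(train_ids)
  te <- to_idx(test_ids)
  if (length(intersect(tr, te))) {
    stop2("partition_covariance: train and test sets overlap")
  }
  lapply(kernels, function(K) {
    list(K11 = K[tr, tr, drop = FALSE],
         K21 = K[te, tr, drop = FALSE],
         K22 = K[te, te, drop = FALSE])
  })
}
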