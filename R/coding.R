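#' Construct a parent-level predictor matrix
#'
#' A `parent_matrix` holds one predictor layer measured on the parental
#' lines: genotypes (layer `"G"`, coded -1/0/1 with -1 and 1 the two
#' homozygotes and 0 the heterozygote), transcript abundances (`"T"`),
#' metabolite abundances (`"M"`) or parental phenotypes (`"P"`, one column
#' per trait).
#'
#' @param values numeric matrix (parents in rows, features in columns) with
#'   unique row and column names. A data frame is coerced.
#' @param layer one of `"G"`, `"T"`, `"M"`, `"P"`.
#' @param log2_transform if `TRUE`, values are log2-transformed at load
#'   time (intended for raw transcript/metabolite abundances); all values
#'   must be positive.
#' @return an object of class `parent_matrix` with elements `values`,
#'   `parent_ids`, `feature_ids`, `layer`.
#' @export
parent_matrix <- function(values, layer = c("G", "T", "M", "P"),
                          log2_transform = FALSE) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    stop2("parent_matrix: row names (parent ids) are required")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%0*d", nchar(ncol(values)), seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop2("parent_matrix: duplicate parent id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop2("parent_matrix: duplicate feature ids")
  }
  if (anyNA(values)) {
    stop2("parent_matrix: missing values are not allowed; impute or drop features upstream")
  }
  if (log2_transform) {
    if (any(values <= 0)) {
      stop2("parent_matrix: log2 transform requires strictly positive values")
    }
    values <- log2(values)
  }
  if (layer == "G" && !all(values %in% c(-1, 0, 1))) {
    stop2("parent_matrix: layer G must be coded in {-1, 0, 1}")
  }
  structure(
    list(values = values, parent_ids = rownames(values),
         feature_ids = colnames(values), layer = layer),
    class = "parent_matrix"
  )
}

#' @export
print.parent_matrix <- function(x, ...) {
  cat(sprintf("<parent_matrix> layer %s: %d parents x %d features\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a cross plan from explicit parent pairs
#'
#' @param female,male character vectors of parent ids, one entry per cross.
#' @param reciprocal if `FALSE` (default) each cross is reduced to its
#'   canonical unordered pair (ids sorted lexicographically) and duplicate
#'   unordered pairs are an error. If `TRUE` the stored female/male order
#'   is preserved, which matters only for the P-type parental models where
#'   the two parents receive separate coefficients.
#' @return an object of class `cross_plan`: a data frame with columns
#'   `cross_id`, `female`, `male` and attribute `reciprocal`.
#' @export
cross_plan <- function(female, male, reciprocal = FALSE) {
  female <- as.character(female)
  male <- as.character(male)
  if (length(female) != length(male)) {
    stop2("cross_plan: female and male id vectors differ in length")
  }
  if (length(female) == 0L) stop2("cross_plan: empty plan")
  if (!reciprocal) {
    swap <- female > male
    tmp <- female[swap]
    female[swap] <- male[swap]
    male[swap] <- tmp
  }
  cross_id <- paste(female, male, sep = "x")
  if (anyDuplicated(cross_id)) {
    dup <- unique(cross_id[duplicated(cross_id)])
    stop2("cross_plan: duplicate cross(es): ", paste(dup, collapse = ", "),
          if (!reciprocal) " (use reciprocal = TRUE to keep ordered pairs)" else "")
  }
  plan <- data.frame(cross_id = cross_id, female = female, male = male,
                     stringsAsFactors = FALSE)
  attr(plan, "reciprocal") <- reciprocal
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

#' Enumerate candidate crosses among a set of parents
#'
#' In `all_pairs` mode every unordered pair of distinct parents is
#' generated, in lexicographic order, giving `p*(p-1)/2` crosses for `p`
#' parents. In `from_file` mode the pairs are read from a two-column
#' delimited file (see [load_cross_plan()]) and checked against
#' `parent_ids`.
#'
#' @param parent_ids character vector of unique parent ids.
#' @param mode `"all_pairs"` or `"from_file"`.
#' @param file path to a cross-plan file (only for `mode = "from_file"`).
#' @param reciprocal passed to [cross_plan()] in `from_file` mode.
#' @return a [cross_plan()] object.
#' @export
enumerate_crosses <- function(parent_ids, mode = c("all_pairs", "from_file"),
                              file = NULL, reciprocal = FALSE) {
  mode <- match.arg(mode)
  parent_ids <- as.character(parent_ids)
  if (anyDuplicated(parent_ids)) {
    stop2("enumerate_crosses: duplicate parent id(s): ",
          paste(unique(parent_ids[duplicated(parent_ids)]), collapse = ", "))
  }
  if (length(parent_ids) < 2L) stop2("enumerate_crosses: need at least 2 parents")
  if (mode == "all_pairs") {
    ids <- sort(parent_ids)
    pairs <- combn(ids, 2L)
    cross_plan(pairs[1L, ], pairs[2L, ], reciprocal = FALSE)
  } else {
    if (is.null(file)) stop2("enumerate_crosses: from_file mode needs a file")
    plan <- load_cross_plan(file, reciprocal = reciprocal)
    unknown <- setdiff(unique(c(plan$female, plan$male)), parent_ids)
    if (length(unknown)) {
      stop2("enumerate_crosses: unknown parent id(s) in plan file: ",
            paste(unknown, collapse = ", "))
    }
    plan
  }
}

new_hybrid_design <- function(Z, W, cross_ids, feature_ids, layer,
                              standardized = FALSE, convention = NULL) {
  dimnames(Z) <- list(cross_ids, feature_ids)
  dimnames(W) <- list(cross_ids, feature_ids)
  structure(
    list(Z = Z, W = W, cross_ids = cross_ids, feature_ids = feature_ids,
         layer = layer, standardized = standardized, convention = convention),
    class = "hybrid_design"
  )
}

#' @export
print.hybrid_design <- function(x, ...) {
  cat(sprintf("<hybrid_design> layer %s: %d crosses x %d features (%s)\n",
              x$layer, nrow(x$Z), ncol(x$Z),
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' Code hybrid additive and dominance designs from parent values
#'
#' For each cross and feature the additive predictor is the mid-parent
#' value `Z = (M + F) / 2` and the dominance predictor is the absolute
#' half-difference `W = |M - F| / 2`, where `M` and `F` are the male and
#' female parent values. The same rule applies to every layer; for
#' genotypes in -1/0/1 it reproduces the usual hybrid genotype coding
#' (e.g. parents 1 and -1 give Z = 0, W = 1 for the heterozygous hybrid).
#'
#' @param parents a [parent_matrix()].
#' @param plan a [cross_plan()]; every parent in the plan must be present
#'   in `parents`.
#' @return a `hybrid_design` (crosses x features matrices `Z` and `W`,
#'   not yet standardized).
#' @export
code_hybrid_layer <- function(parents, plan) {
  stopifnot(inherits(parents, "parent_matrix"), inherits(plan, "cross_plan"))
  missing <- setdiff(unique(c(plan$female, plan$male)), parents$parent_ids)
  if (length(missing)) {
    idx <- which(plan$female %in% missing | plan$male %in% missing)[1L]
    stop2(sprintf(
      "code_hybrid_layer: parent(s) %s absent from layer %s (first affected cross: %s)",
      paste(missing, collapse = ", "), parents$layer, plan$cross_id[idx]))
  }
  M <- parents$values[plan$male, , drop = FALSE]
  F_ <- parents$values[plan$female, , drop = FALSE]
  Z <- (M + F_) / 2
  W <- abs(M - F_) / 2
  new_hybrid_design(Z, W, plan$cross_id, parents$feature_ids, parents$layer)
}

#' Standardize the columns of a hybrid design
#'
#' Each column of `Z` and `W` is centered and scaled to unit variance over
#' all rows of the design, using the population (divide-by-n) variance
#' convention so that the 1/m-scaled kinship diagonal averages one.
#' Standardization is applied after coding and over the full set of
#' crosses supplied (training and candidates jointly when predicting new
#' crosses), so that kinships between tested and untested crosses live on
#' a common scale. Constant columns carry no information at this scale;
#' they are set to zero (with a warning) rather than dropped so feature
#' alignment is preserved.
#'
#' @param design a raw `hybrid_design` from [code_hybrid_layer()].
#' @param policy standardization sample; only `"full_sample"` is defined.
#' @return the design with standardized `Z` and `W` and the centering /
#'   scaling statistics stored in the `convention` field.
#' @export
standardize_columns <- function(design, policy = "full_sample") {
  stopifnot(inherits(design, "hybrid_design"))
  policy <- match.arg(policy, "full_sample")
  if (isTRUE(design$standardized)) {
    stop2("standardize_columns: design is already standardized")
  }
  std_one <- function(A, what) {
    mu <- colMeans(A)
    s <- sqrt(colMeans(sweep(A, 2L, mu, "-")^2))
    const <- s <= 1e-12
    s[const] <- 1
    out <- sweep(sweep(A, 2L, mu, "-"), 2L, s, "/")
    if (any(const)) {
      out[, const] <- 0
      warn2(sprintf("standardize_columns: %d constant %s column(s) set to zero in layer %s",
                    sum(const), what, design$layer))
    }
    list(values = out, center = mu, scale = s, constant = const)
  }
  z <- std_one(design$Z, "Z")
  w <- suppressWarnings(std_one(design$W, "W"))
  n_const_w <- sum(w$constant)
  if (n_const_w > 0) {
    # self-crosses and monomorphic features commonly zero out W columns;
    # report once rather than per column
    message(sprintf("standardize_columns: %d constant W column(s) set to zero in layer %s",
                    n_const_w, design$layer))
  }
  new_hybrid_design(
    z$values, w$values, design$cross_ids, design$feature_ids, design$layer,
    standardized = TRUE,
    convention = list(policy = policy, variance = "population",
                      center_Z = z$center, scale_Z = z$scale,
                      center_W = w$center, scale_W = w$scale)
  )
}
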