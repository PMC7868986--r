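PARENTAL_MODEL_NAMES <- c("Random", "A-One", "D-One", "AD-One", "P-One",
                          "A-All", "D-All", "AD-All", "P-All")

#' Specify a model for incorporating parental phenotypic records
#'
#' Nine named schemes are supported. `"Random"` keeps the parental
#' phenotype layer as a random kernel (additive and, under an A+D genetic
#' model, dominance kinship built from the coded P layer). The remaining
#' eight treat parental phenotypes as fixed covariates of the hybrid:
#' the coding prefix decides the columns built per trait -- `A` the
#' mid-parent value `(PM + PF)/2`, `D` the absolute half-difference
#' `|PM - PF|/2`, `AD` both, and `P` the raw male and female parental
#' values as separate columns -- while the suffix decides the trait scope
#' (`One` = the target trait only, `All` = every trait in the parental
#' phenotype matrix).
#'
#' @param name one of `"Random"`, `"A-One"`, `"D-One"`, `"AD-One"`,
#'   `"P-One"`, `"A-All"`, `"D-All"`, `"AD-All"`, `"P-All"`.
#' @param target_trait trait id (required for the `One`-scoped models).
#' @return an object of class `parental_model_spec` with fields `name`,
#'   `coding` (`"A"`, `"D"`, `"AD"`, `"P"` or `"random"`), `scope`,
#'   `target_trait`.
#' @export
parental_model_spec <- function(name, target_trait = NULL) {
  name <- match.arg(name, PARENTAL_MODEL_NAMES)
  if (name == "Random") {
    coding <- "random"
    scope <- "all"
  } else {
    parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
    coding <- parts[1L]
    scope <- tolower(parts[2L])
  }
  if (scope == "one" && is.null(target_trait)) {
    stop2("parental_model_spec: ", name, " requires a target_trait")
  }
  structure(list(name = name, coding = coding, scope = scope,
                 target_trait = target_trait),
            class = "parental_model_spec")
}

#' Build fixed-effect columns from parental phenotypes
#'
#' Constructs the covariate block prescribed by a [parental_model_spec()]
#' for each cross in the plan: per trait, `A` builds `(PM + PF)/2`, `D`
#' builds `|PM - PF|/2`, `AD` both, and `P` builds the raw male column(s)
#' followed by the female column(s). Columns are centered (means stored in
#' the `"center"` attribute so candidate crosses can be placed on the same
#' scale) and checked for rank; trailing linearly dependent columns are
#' dropped with a warning.
#'
#' @param parent_phen a [parent_matrix()] with `layer = "P"` (columns are
#'   traits).
#' @param plan a [cross_plan()]. For `P`-coded models an unordered
#'   (canonical) plan triggers a warning, since separate female/male
#'   coefficients only carry a maternal-effect interpretation when the
#'   stored parent order is real.
#' @param spec a [parental_model_spec()] with fixed-type coding (an error
#'   for `"Random"`, which builds no fixed columns).
#' @param center center the columns (default `TRUE`).
#' @return a numeric matrix (crosses x columns) with descriptive column
#'   labels and a `"center"` attribute.
#' @export
build_parental_design <- function(parent_phen, plan, spec, center = TRUE) {
  stopifnot(inherits(parent_phen, "parent_matrix"),
            inherits(plan, "cross_plan"),
            inherits(spec, "parental_model_spec"))
  if (parent_phen$layer != "P") {
    stop2("build_parental_design: parent_phen must be a layer-P matrix")
  }
  if (spec$coding == "random") {
    stop2("build_parental_design: the Random model builds no fixed columns; ",
          "include P as a random kernel instead")
  }
  traits <- if (spec$scope == "one") spec$target_trait else parent_phen$feature_ids
  missing <- setdiff(traits, parent_phen$feature_ids)
  if (length(missing)) {
    stop2("build_parental_design: trait(s) not in parental phenotypes: ",
          paste(missing, collapse = ", "))
  }
  missing_par <- setdiff(unique(c(plan$female, plan$male)), parent_phen$parent_ids)
  if (length(missing_par)) {
    stop2("build_parental_design: parent(s) without phenotypes: ",
          paste(missing_par, collapse = ", "))
  }
  if (spec$coding == "P" && !isTRUE(attr(plan, "reciprocal"))) {
    warn2("build_parental_design: plan stores canonical (unordered) pairs; ",
          "separate female/male coefficients lose their maternal-effect interpretation")
  }
  PM <- parent_phen$values[plan$male, traits, drop = FALSE]
  PF <- parent_phen$values[plan$female, traits, drop = FALSE]
  cols <- switch(spec$coding,
    A = {
      B <- (PM + PF) / 2
      colnames(B) <- paste0("midparent_", traits)
      B
    },
    D = {
      B <- abs(PM - PF) / 2
      colnames(B) <- paste0("pardiff_", traits)
      B
    },
    AD = {
      B1 <- (PM + PF) / 2
      B2 <- abs(PM - PF) / 2
      colnames(B1) <- paste0("midparent_", traits)
      colnames(B2) <- paste0("pardiff_", traits)
      cbind(B1, B2)
    },
    P = {
      colnames(PM) <- paste0("male_", traits)
      colnames(PF) <- paste0("female_", traits)
      cbind(PM, PF)
    })
  rownames(cols) <- plan$cross_id
  centers <- rep(0, ncol(cols))
  if (center) {
    centers <- colMeans(cols)
    cols <- sweep(cols, 2L, centers, "-")
  }
  # drop trailing dependent columns until the block has full rank
  while (ncol(cols) > 0L && qr(cols)$rank < ncol(cols)) {
    warn2("build_parental_design: dropping linearly dependent column ",
          colnames(cols)[ncol(cols)])
    centers <- centers[-ncol(cols)]
    cols <- cols[, -ncol(cols), drop = FALSE]
  }
  attr(cols, "center") <- centers
  attr(cols, "model") <- spec$name
  cols
}

parse_combo <- function(combo) {
  if (length(combo) == 1L && nchar(combo) > 1L) {
    combo <- strsplit(combo, "")[[1L]]
  }
  combo <- toupper(combo)
  bad <- setdiff(combo, c("G", "T", "M", "P"))
  if (length(bad)) stop2("unknown predictor layer(s): ", paste(bad, collapse = ", "))
  if (!length(combo)) stop2("predictor combination must be non-empty")
  if (anyDuplicated(combo)) stop2("duplicate layer in predictor combination")
  combo
}

#' Assemble the kernels and fixed design for one prediction model
#'
#' Combines a predictor combination (any non-empty subset of G, T, M, P),
#' a genetic model (`"A"` = additive kernels only, `"A+D"` = additive plus
#' dominance kernel per layer) and an optional parental model into the
#' kernel list and fixed-effect design consumed by [reml_fit()]. Under a
#' fixed-type parental model the P layer contributes covariate columns
#' instead of kernels; under `"Random"` (or no parental spec) the P layer
#' enters as kinship kernels like any omic layer.
#'
#' @param designs named list of standardized `hybrid_design` objects for
#'   the layers in `combo` (names `"G"`, `"T"`, `"M"`, `"P"`).
#' @param combo predictor combination, e.g. `"GTMP"` or `c("G","P")`.
#' @param genetic_model `"A"` or `"A+D"`.
#' @param parental_spec optional [parental_model_spec()]; requires `P` in
#'   `combo`.
#' @param parent_phen parental phenotype [parent_matrix()] (required for a
#'   fixed-type parental spec).
#' @param plan the [cross_plan()] the designs were coded from (required
#'   for a fixed-type parental spec).
#' @param check passed to [kernel_set()].
#' @return a list with `kernels` (a `kernel_set`), `X` (intercept plus any
#'   parental columns), `combo`, `genetic_model`, `parental_model`.
#' @export
assemble_model <- function(designs, combo, genetic_model = c("A+D", "A"),
                           parental_spec = NULL, parent_phen = NULL,
                           plan = NULL, check = TRUE) {
  genetic_model <- match.arg(genetic_model)
  combo <- parse_combo(combo)
  missing_layers <- setdiff(combo, names(designs))
  fixed_parental <- !is.null(parental_spec) && parental_spec$coding != "random"
  if (!is.null(parental_spec)) {
    if (!"P" %in% combo) {
      stop2("assemble_model: a parental model requires P in the predictor combination")
    }
  }
  kernel_layers <- if (fixed_parental) setdiff(combo, "P") else combo
  missing_layers <- setdiff(kernel_layers, names(designs))
  if (length(missing_layers)) {
    stop2("assemble_model: no design supplied for layer(s): ",
          paste(missing_layers, collapse = ", "))
  }
  if ("P" %in% combo && !fixed_parental && !"P" %in% names(designs)) {
    stop2("assemble_model: no design supplied for layer(s): P")
  }

  n <- nrow(designs[[1L]]$Z)
  X <- matrix(1, n, 1, dimnames = list(designs[[1L]]$cross_ids, "(Intercept)"))
  if (fixed_parental) {
    if (is.null(parent_phen) || is.null(plan)) {
      stop2("assemble_model: fixed parental models need parent_phen and plan")
    }
    P_block <- build_parental_design(parent_phen, plan, parental_spec)
    X <- cbind(X, P_block)
  }
  if (length(kernel_layers) == 0L) {
    stop2("assemble_model: no random kernels left; add an omic layer or use the Random parental model")
  }
  kernels <- build_kernels(designs[kernel_layers], genetic_model, check = check)
  list(kernels = kernels, X = X, combo = paste(combo, collapse = ""),
       genetic_model = genetic_model,
       parental_model = if (is.null(parental_spec)) NA_character_ else parental_spec$name,
       parental_center = if (fixed_parental) attr(X, "center") else NULL)
}
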