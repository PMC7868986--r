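#' Published top/bottom-200 summary for the rice RIL hybrid population
#'
#' A packaged reference table of predicted-phenotype summaries for the
#' well-studied Zhenshan 97 x Minghui 63 recombinant-inbred-line hybrid
#' population: for each of 14 predictor combinations (every non-empty
#' subset of G/T/M plus those subsets combined with parental phenome P
#' under the AD-All model) and four yield-related traits (YIELD, TILLER,
#' GRAIN, KGW), the mean and standard deviation of the predicted values of
#' the top 200 and bottom 200 of all 21,945 candidate crosses from 210
#' lines. It lets the selection-summary arithmetic (tail means, percent
#' gains, with-P versus without-P averages) be exercised without access to
#' the full rice dataset.
#'
#' @return a data frame with columns `predictor`, `trait`, `top_mean`,
#'   `top_sd`, `bottom_mean`, `bottom_sd`.
#' @export
rice_selection_reference <- function() {
  path <- system.file("extdata", "rice_top_bottom_reference.tsv",
                      package = "hyblup", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Percent gain of the selected tail over the discarded tail
#'
#' `100 * (mean_top / mean_bottom - 1)`, computed on unrounded means.
#'
#' @param mean_top,mean_bottom tail means of the predicted values.
#' @return percent gain (numeric).
#' @export
percent_gain <- function(mean_top, mean_bottom) {
  100 * (mean_top / mean_bottom - 1)
}

#' Summarize the tails of a cross ranking
#'
#' Sorts predictions in descending order (ties broken by ascending
#' cross id) and reports the mean and standard deviation of the top-q and
#' bottom-q crosses together with the percent gain of the top tail over
#' the bottom tail.
#'
#' @param predictions named numeric vector (names are cross ids) or the
#'   data frame returned by [predict_all_crosses()].
#' @param q tail size; must satisfy `1 <= q <= n/2`.
#' @return a list with `q`, `top` and `bottom` (each `mean`, `sd`, `ids`)
#'   and `percent_gain`.
#' @export
summarize_selection <- function(predictions, q = 200) {
  if (is.data.frame(predictions)) {
    predictions <- setNames(predictions$predicted, predictions$cross_id)
  }
  n <- length(predictions)
  if (!is_count(q) || q <= 0) stop2("summarize_selection: q must be a positive integer")
  if (q > n / 2) stop2("summarize_selection: q must be at most half the candidate count")
  ids <- names(predictions) %||% as.character(seq_len(n))
  ord <- order(-predictions, ids)
  top <- ord[seq_len(q)]
  bottom <- rev(ord)[seq_len(q)]
  list(q = q,
       top = list(mean = mean(predictions[top]), sd = sd(predictions[top]),
                  ids = ids[top]),
       bottom = list(mean = mean(predictions[bottom]), sd = sd(predictions[bottom]),
                     ids = ids[bottom]),
       percent_gain = percent_gain(mean(predictions[top]), mean(predictions[bottom])))
}

#' Predict every candidate cross among a set of parents
#'
#' Full pipeline for genome-wide cross ranking: the training crosses and
#' all candidate crosses are coded jointly per layer, standardized over
#' the joint sample (so training/candidate kinships share one scale),
#' variance components are estimated by REML on the training crosses (or
#' reused from `vc`), and every candidate is predicted by the
#' conditional-expectation BLUP formula. Training crosses are included in
#' the output (their predictions are the in-sample fitted values of the
#' same formula). Candidate kernel blocks are computed from the designs in
#' chunks, so the full candidates x candidates kinship is never formed.
#'
#' @param parents named list of [parent_matrix()] objects for the layers
#'   in `combo` (names `"G"`, `"T"`, `"M"`, `"P"`).
#' @param training_plan [cross_plan()] of phenotyped crosses.
#' @param y phenotype vector aligned to `training_plan` (or a data frame
#'   with `cross_id` and a `trait` column).
#' @param trait trait name when `y` is a data frame; also the target trait
#'   for `One`-scoped parental models.
#' @param combo predictor combination, e.g. `"GMP"`.
#' @param genetic_model `"A"` or `"A+D"`.
#' @param parental_model name of a parental model (see
#'   [parental_model_spec()]) or `NULL`; requires `"P"` in `combo` and a
#'   `"P"` entry in `parents`.
#' @param candidates optional [cross_plan()] of candidates; defaults to
#'   all unordered pairs of the parents of the first layer.
#' @param vc optional [variance_components()] to reuse (skips REML).
#' @param chunk_size number of candidate crosses predicted per chunk.
#' @return a list of class `ranking_report`: `predictions` (data frame
#'   `cross_id`, `female`, `male`, `predicted`, `rank`, `in_training`),
#'   `fit` (the `blup_fit`), `trait`, `combo`, `genetic_model`,
#'   `parental_model`, `standardization` (scope note).
#' @export
predict_all_crosses <- function(parents, training_plan, y, trait = NULL,
                                combo = "G", genetic_model = c("A+D", "A"),
                                parental_model = NULL, candidates = NULL,
                                vc = NULL, chunk_size = 5000) {
  genetic_model <- match.arg(genetic_model)
  combo <- parse_combo(combo)
  if (is.data.frame(y)) {
    if (is.null(trait)) stop2("predict_all_crosses: trait required when y is a data frame")
    y <- setNames(y[[trait]], y$cross_id)[training_plan$cross_id]
  }
  y <- as.numeric(y)
  if (length(y) != nrow(training_plan)) {
    stop2("predict_all_crosses: y not aligned to training plan")
  }
  if (is.null(candidates)) {
    candidates <- enumerate_crosses(parents[[1L]]$parent_ids)
  }
  spec <- NULL
  if (!is.null(parental_model)) {
    if (!"P" %in% combo) stop2("predict_all_crosses: parental model requires P in combo")
    if (!"P" %in% names(parents)) {
      stop2("predict_all_crosses: no parental phenotype matrix supplied for layer P")
    }
    spec <- parental_model_spec(parental_model, target_trait = trait)
  }

  # joint plan: training crosses first, then the remaining candidates
  extra <- candidates[!candidates$cross_id %in% training_plan$cross_id, , drop = FALSE]
  joint <- cross_plan(c(training_plan$female, extra$female),
                      c(training_plan$male, extra$male))
  n1 <- nrow(training_plan)
  tr_idx <- seq_len(n1)

  kernel_layers <- if (!is.null(spec) && spec$coding != "random") {
    setdiff(combo, "P")
  } else combo
  designs <- lapply(setNames(kernel_layers, kernel_layers), function(l) {
    if (!l %in% names(parents)) stop2("predict_all_crosses: missing layer ", l)
    suppressMessages(standardize_columns(code_hybrid_layer(parents[[l]], joint)))
  })

  # training kernels from the jointly standardized designs
  designs_tr <- lapply(designs, function(d) {
    new_hybrid_design(d$Z[tr_idx, , drop = FALSE], d$W[tr_idx, , drop = FALSE],
                      d$cross_ids[tr_idx], d$feature_ids, d$layer,
                      standardized = TRUE, convention = d$convention)
  })
  kernels_tr <- build_kernels(designs_tr, genetic_model,
                              check = nrow(training_plan) <= 2000)

  # fixed design: intercept plus parental columns (training centering)
  X1 <- matrix(1, n1, 1, dimnames = list(training_plan$cross_id, "(Intercept)"))
  Xc <- matrix(1, nrow(joint), 1, dimnames = list(joint$cross_id, "(Intercept)"))
  if (!is.null(spec) && spec$coding != "random") {
    blk_tr <- build_parental_design(parents$P, training_plan, spec)
    blk_all_raw <- build_parental_design(parents$P, joint, spec, center = FALSE)
    blk_all_raw <- blk_all_raw[, colnames(blk_tr), drop = FALSE]
    blk_all <- sweep(blk_all_raw, 2L, attr(blk_tr, "center"), "-")
    X1 <- cbind(X1, blk_tr)
    Xc <- cbind(Xc, blk_all)
  }

  if (is.null(vc)) {
    fit <- reml_fit(y, X1, kernels_tr)
  } else {
    vc <- as_vc(vc, names(kernels_tr))
    V <- assemble_covariance(kernels_tr, vc)
    core <- reml_core(y, X1, V)
    fit <- structure(list(vc = vc, beta = setNames(core$beta, colnames(X1)),
                          X_spec = colnames(X1), loglik = core$loglik,
                          converged = TRUE, n_iter = 0L,
                          train_ids = training_plan$cross_id,
                          y = y, X = X1, kernels = kernels_tr),
                     class = "blup_fit")
  }

  # predict all candidates (training crosses included) in chunks
  n_all <- nrow(joint)
  pred <- numeric(n_all)
  for (start in seq(1L, n_all, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_all)
    k21 <- list()
    for (l in names(designs)) {
      d <- designs[[l]]
      m <- ncol(d$Z)
      k21[[paste0(l, "_add")]] <-
        tcrossprod(d$Z[idx, , drop = FALSE], d$Z[tr_idx, , drop = FALSE]) / m
      if (genetic_model == "A+D") {
        k21[[paste0(l, "_dom")]] <-
          tcrossprod(d$W[idx, , drop = FALSE], d$W[tr_idx, , drop = FALSE]) / m
      }
    }
    k21 <- lapply(k21, function(B) {
      dimnames(B) <- list(joint$cross_id[idx], fit$train_ids); B
    })
    pred[idx] <- blup_predict(fit, k21, X2 = Xc[idx, , drop = FALSE],
                              allow_unconverged = TRUE)
  }

  out <- data.frame(cross_id = joint$cross_id, female = joint$female,
                    male = joint$male, predicted = pred,
                    in_training = joint$cross_id %in% training_plan$cross_id,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted, out$cross_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(list(predictions = out, fit = fit, trait = trait,
                 combo = paste(combo, collapse = ""),
                 genetic_model = genetic_model,
                 parental_model = if (is.null(spec)) NA_character_ else spec$name,
                 standardization = "joint training+candidate sample, population variance"),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("<ranking_report> %d crosses, combo %s, model %s%s\n",
              nrow(x$predictions), x$combo, x$genetic_model,
              if (is.na(x$parental_model)) "" else paste0(", parental ", x$parental_model)))
  print(head(x$predictions))
  invisible(x)
}
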