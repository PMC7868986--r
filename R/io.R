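detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Load a parent-level predictor matrix from a delimited file
#'
#' The canonical format is tab-separated (comma auto-detected): first
#' column holds the parent id, the header row holds feature ids, the body
#' is numeric. Ragged rows, duplicate ids, missing or non-numeric cells
#' are hard errors with row/column context -- no silent imputation.
#'
#' @param path file path.
#' @param layer predictor layer label (`"G"`, `"T"`, `"M"`, `"P"`).
#' @param log2_transform log2-transform the values at load time (for raw
#'   transcript/metabolite abundances; values must be positive).
#' @return a [parent_matrix()].
#' @export
load_matrix <- function(path, layer, log2_transform = FALSE) {
  if (!file.exists(path)) stop2("load_matrix: no such file: ", path)
  sep <- detect_sep(path)
  nf <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop2(sprintf("load_matrix: ragged file %s (line %d has %d fields, expected %d)",
                  path, bad, nf[bad], nf[1L]))
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("load_matrix: need an id column plus at least one feature")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop2("load_matrix: duplicate parent id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop2(sprintf("load_matrix: non-numeric cell at row %d, column '%s' in %s",
                      bad[1L], colnames(body)[j], path))
      }
      body[[j]] <- num
    }
    if (anyNA(body[[j]])) {
      stop2(sprintf("load_matrix: missing value at row %d, column '%s' in %s",
                    which(is.na(body[[j]]))[1L], colnames(body)[j], path))
    }
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  parent_matrix(values, layer = layer, log2_transform = log2_transform)
}

#' Write a parent matrix (or any matrix with ids) as TSV
#'
#' @param x a [parent_matrix()] or a numeric matrix with row names.
#' @param path output file path.
#' @param id_column header label of the id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "id") {
  values <- if (inherits(x, "parent_matrix")) x$values else as.matrix(x)
  # %.17g keeps doubles bit-identical across a write/read cycle
  body <- apply(values, 2L, function(col) sprintf("%.17g", col))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(values))
  df <- data.frame(rownames(values), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a cross plan from a two-column delimited file
#'
#' Columns are female id, male id; a header row is detected when the first
#' line's fields start with `female`/`male` (case-insensitive).
#'
#' @param path file path.
#' @param reciprocal passed to [cross_plan()].
#' @return a [cross_plan()].
#' @export
load_cross_plan <- function(path, reciprocal = FALSE) {
  if (!file.exists(path)) stop2("load_cross_plan: no such file: ", path)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  f_col <- grep("^female", first, ignore.case = TRUE)
  m_col <- grep("^male", first, ignore.case = TRUE)
  header <- length(f_col) == 1L && length(m_col) == 1L
  df <- read.delim(path, sep = sep, header = header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("load_cross_plan: need two columns (female, male)")
  if (header) {
    cross_plan(df[[f_col]], df[[m_col]], reciprocal = reciprocal)
  } else {
    cross_plan(df[[1L]], df[[2L]], reciprocal = reciprocal)
  }
}

#' Write a cross plan (optionally with phenotypes) as TSV
#'
#' @param plan a [cross_plan()].
#' @param path output file path.
#' @param phenotypes optional data frame with `cross_id` plus trait
#'   columns to merge in.
#' @return `path`, invisibly.
#' @export
write_cross_plan <- function(plan, path, phenotypes = NULL) {
  df <- as.data.frame(plan)
  if (!is.null(phenotypes)) {
    df <- merge(df, phenotypes, by = "cross_id", sort = FALSE)
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model or report to JSON
#'
#' Writes variance components, fixed-effect solutions, likelihood and
#' convergence metadata (for fits) or the report fields (for
#' predictability reports) as structured text.
#'
#' @param x a `blup_fit` or `predictability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  obj <- if (inherits(x, "blup_fit")) {
    list(type = "blup_fit",
         vc = c(as.list(x$vc$by_kernel), list(residual = x$vc$residual)),
         beta = as.list(x$beta), X_spec = x$X_spec, loglik = x$loglik,
         converged = x$converged, n_iter = x$n_iter,
         n_train = length(x$y),
         conventions = list(standardization = "population variance, full sample",
                            kernel_scaling = "1/m"))
  } else if (inherits(x, "predictability_report")) {
    list(type = "predictability_report", method = x$method, folds = x$folds,
         press = x$press, ss = x$ss, r2 = x$r2, r2_cor = x$r2_cor,
         vc_mode = x$vc_mode, ss_convention = x$ss_convention,
         n_repeats = x$n_repeats %||% 1L, seed = x$seed %||% NA)
  } else {
    x
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
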