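#' Published integrated-radius loading vector
#'
#' The three-decimal first-PC loadings on covalent radius, Pauling ionic
#' radius and electron density that define the integrated-radius score
#' `X1 = 0.567 CR + 0.568 r - 0.597 AR/AW`. Used to reproduce the published
#' coefficients exactly; the self-computed eigenvector agrees to within
#' 0.001 per component.
#'
#' @return Named numeric 3-vector over `CR`, `r`, `AR_AW`.
#' @export
printed_ir_loadings <- function() {
  c(CR = 0.567, r = 0.568, AR_AW = -0.597)
}

#' First principal component of a descriptor subset
#'
#' Eigendecomposition of the k x k Pearson correlation matrix of the raw
#' (untransformed) subset columns. The first eigenvector is returned with
#' unit norm, sign-oriented so the loading on the first subset descriptor is
#' positive; published tables occasionally print the globally flipped
#' vector, which changes no fit statistic.
#'
#' @param data Descriptor tibble with no missing values in `subset` columns.
#' @param subset Ordered character vector of >= 2 descriptor column names.
#' @return An object of class `pc_model`: subset, unit-norm first-PC
#'   `loading`, all `eigenvalues` (non-negative, descending, summing to k),
#'   `proportion` (eigenvalue1 / k), `sd1` (sqrt of eigenvalue1), and the
#'   column means/sds for reference.
#' @export
#' @examples
#' fit_pca(ppcr_training_table(), c("CR", "r", "AR_AW"))
fit_pca <- function(data, subset) {
  stopifnot(is.data.frame(data))
  if (length(subset) < 2) abort("subset must name at least 2 descriptors")
  missing_cols <- setdiff(subset, names(data))
  if (length(missing_cols)) {
    abort(paste0("subset column(s) not in table: ", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[subset])
  if (anyNA(X)) {
    bad <- subset[colSums(is.na(X)) > 0][1]
    abort(sprintf("missing values in subset column '%s'", bad))
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column '%s': correlation matrix singular",
                  subset[sds == 0][1]))
  }
  ev <- eigen(cor(X), symmetric = TRUE)
  loading <- ev$vectors[, 1]
  if (loading[1] < 0) loading <- -loading
  names(loading) <- subset
  structure(
    list(subset = subset,
         loading = loading,
         eigenvalues = ev$values,
         proportion = ev$values[1] / length(subset),
         sd1 = sqrt(ev$values[1]),
         center = colMeans(X),
         scale = sds,
         n = nrow(X)),
    class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("First principal component of {", paste(x$subset, collapse = ", "),
      "} (n =", x$n, ")\n")
  cat("  loading:    ", paste(sprintf("%+.4f %s", x$loading, x$subset),
                              collapse = "  "), "\n")
  cat(sprintf("  eigenvalues: %s   PC1 share %.1f%%\n",
              paste(sprintf("%.4f", x$eigenvalues), collapse = ", "),
              100 * x$proportion))
  invisible(x)
}

#' Integrated-radius (raw-projection) scores
#'
#' Projects raw, unstandardized descriptor values onto the first-PC loading:
#' `score_i = sum_j loading_j * x_ij`. This raw-projection convention — not
#' standardized PC scores — is what the published regression coefficients
#' are defined on, and is the score every downstream fit, interval and
#' leverage uses.
#'
#' @param data Tibble carrying the model's subset columns.
#' @param pcm A [fit_pca()] model.
#' @param loading_override Optional replacement loading vector (e.g.
#'   [printed_ir_loadings()]), in subset order.
#' @return Tibble with `metal_id` (row index if absent) and `score`.
#' @export
#' @examples
#' tbl <- ppcr_training_table()
#' pc_scores(tbl, fit_pca(tbl, c("CR", "r", "AR_AW")))
pc_scores <- function(data, pcm, loading_override = NULL) {
  stopifnot(inherits(pcm, "pc_model"))
  loading <- loading_override %||% pcm$loading
  if (length(loading) != length(pcm$subset)) {
    abort("loading_override length must match the subset")
  }
  missing_cols <- setdiff(pcm$subset, names(data))
  if (length(missing_cols)) {
    abort(paste0("record(s) missing subset column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[pcm$subset])
  if (anyNA(X)) {
    ids <- if ("metal_id" %in% names(data)) data$metal_id else as.character(seq_len(nrow(data)))
    abort(paste0("missing subset values for record(s): ",
                 paste(ids[rowSums(is.na(X)) > 0], collapse = ", ")))
  }
  tibble::tibble(
    metal_id = if ("metal_id" %in% names(data)) data$metal_id else as.character(seq_len(nrow(data))),
    score = as.numeric(X %*% as.numeric(loading)))
}
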