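#' Warning leverage h*
#'
#' The standard QSAR applicability-domain threshold `h* = factor (p + 1) / n`
#' with `p` the number of model predictors (1 for the integrated-radius
#' model) and `n` the number of training records; the conventional factor
#' is 3, giving h* = 0.75 at n = 8.
#'
#' @param n Training-set size.
#' @param p Number of predictors (default 1).
#' @param factor Multiplier (default 3).
#' @return The warning leverage.
#' @export
warning_leverage <- function(n, p = 1, factor = 3) {
  factor * (p + 1) / n
}

#' Cross-validate the descriptor-criteria pipeline
#'
#' For each fold, the entire pipeline — PCA loading over the subset,
#' raw-projection scoring, OLS of ln CMC on the score — is refit on the
#' remaining records and applied to the held-out ones. Reports
#' `Q2 = 1 - PRESS/SST` (SST about the full-data mean of ln CMC) and
#' `RMSE = sqrt(PRESS/n)` on the ln scale.
#'
#' With `refit_loadings = FALSE` (or a `loading_override`) the loading
#' vector is held fixed across folds and only the regression is refit; for
#' leave-one-out this reproduces the closed-form PRESS shortcut
#' `e_i / (1 - h_i)` exactly. Refitting the loadings per fold (the default)
#' is the honest validation of the whole pipeline and may differ slightly.
#'
#' @param data Training tibble (`cmc` plus subset columns).
#' @param subset Descriptor columns for the score.
#' @param k `"loo"` (default) or an integer number of folds between 2 and n.
#' @param seed Integer seed for fold shuffling (ignored for `"loo"`, which
#'   is deterministic).
#' @param refit_loadings Refit the PCA loading inside each fold?
#' @param loading_override Optional fixed loading vector (implies no refit).
#' @return Object of class `ppcr_cv`: `scheme`, `k`, `seed`, `q2_cv`,
#'   `rmse_cv` and a `predictions` tibble (`metal_id`, `fold`, `ln_obs`,
#'   `ln_pred`).
#' @export
#' @examples
#' cross_validate(ppcr_training_table(), k = "loo")
cross_validate <- function(data, subset = c("CR", "r", "AR_AW"), k = "loo",
                           seed = NULL, refit_loadings = TRUE,
                           loading_override = NULL) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  y <- ln_transform(data$cmc, "cmc")
  if (identical(k, "loo")) {
    folds <- seq_len(n)
    scheme <- "loo"
    kk <- n
  } else {
    kk <- as.integer(k)
    if (is.na(kk) || kk < 2 || kk > n) abort("k must be 'loo' or an integer in [2, n]")
    scheme <- "kfold"
    assign_folds <- function() sample(rep_len(seq_len(kk), n))
    folds <- if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
  }
  if (!is.null(loading_override)) refit_loadings <- FALSE

  ln_pred <- rep(NA_real_, n)
  for (f in unique(folds)) {
    test <- folds == f
    train <- !test
    if (sum(train) < 3) abort(sprintf("fold %d leaves fewer than 3 records for refit", f))
    pcm <- fit_pca(data[train, , drop = FALSE], subset)
    loading <- loading_override %||%
      (if (refit_loadings) pcm$loading else fit_pca(data, subset)$loading)
    s_train <- pc_scores(data[train, , drop = FALSE], pcm, loading_override = loading)$score
    mod <- lm(y[train] ~ s_train)
    s_test <- pc_scores(data[test, , drop = FALSE], pcm, loading_override = loading)$score
    ln_pred[test] <- coef(mod)[1] + coef(mod)[2] * s_test
  }
  press <- sum((y - ln_pred)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(scheme = scheme, k = kk, seed = seed,
         refit_loadings = refit_loadings && is.null(loading_override),
         q2_cv = 1 - press / sst,
         rmse_cv = sqrt(press / n),
         predictions = tibble::tibble(
           metal_id = if ("metal_id" %in% names(data)) data$metal_id else as.character(seq_len(n)),
           fold = folds, ln_obs = y, ln_pred = ln_pred)),
    class = "ppcr_cv")
}

#' @export
print.ppcr_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (k = %d%s, loadings %s)\n",
              x$scheme, x$k,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else "",
              if (x$refit_loadings) "refit per fold" else "fixed"))
  cat(sprintf("  Q2cv = %.3f   RMSEcv = %.3f (ln units)\n", x$q2_cv, x$rmse_cv))
  invisible(x)
}

#' Leverages and applicability domain
#'
#' For the one-predictor score regression the leverage of a record is
#' `h_i = 1/n + (score_i - mean score)^2 / SSX`. Training records also get
#' standardized residuals `e_i / (rse sqrt(1 - h_i))`. A record is inside
#' the applicability domain when its leverage is below the warning value
#' h* ([warning_leverage()]): predictions for out-of-domain metals
#' extrapolate beyond the training scores and should be treated as
#' unreliable.
#'
#' @param fit A `ppcr_fit`.
#' @param newdata Optional tibble of query records; default the training
#'   set (which then carries standardized residuals).
#' @param factor h* multiplier passed to [warning_leverage()].
#' @return A tibble of class `metcrit_domain` with `metal_id`, `score`,
#'   `hat`, `std_resid` (`NA` for non-training records), `in_domain`;
#'   attributes `h_star`, `n`, `p`.
#' @export
#' @examples
#' hat_values(fit_ppcr(ppcr_training_table(), loadings = "printed"))
hat_values <- function(fit, newdata = NULL, factor = 3) {
  stopifnot(inherits(fit, "ppcr_fit"))
  if (fit$score_ssx == 0) abort("zero score variance: leverages undefined")
  training <- is.null(newdata)
  sc <- if (training) fit$scores else pc_scores(newdata, fit$pcm, loading_override = fit$loading)
  h <- 1 / fit$n + (sc$score - fit$score_mean)^2 / fit$score_ssx
  hstar <- warning_leverage(fit$n, p = 1, factor = factor)
  std_resid <- if (training && !is.null(fit$residuals)) {
    fit$residuals / (fit$rse * sqrt(1 - h))
  } else rep(NA_real_, nrow(sc))
  out <- tibble::tibble(metal_id = sc$metal_id, score = sc$score, hat = h,
                        std_resid = std_resid, in_domain = h < hstar)
  attr(out, "h_star") <- hstar
  attr(out, "n") <- fit$n
  attr(out, "p") <- 1L
  class(out) <- c("metcrit_domain", class(out))
  out
}

#' Williams-plot table
#'
#' Flattens a domain report into the table a Williams plot is drawn from:
#' leverage against standardized residual per metal, with records beyond
#' the warning leverage flagged `out_of_domain` and records with
#' |standardized residual| > 3 flagged `response_outlier`.
#'
#' @param dr A [hat_values()] report.
#' @return Tibble with `metal_id`, `hat`, `std_resid`, `in_domain`,
#'   `response_outlier`; empty input yields a header-only tibble.
#' @export
williams_export <- function(dr) {
  stopifnot(inherits(dr, "metcrit_domain"))
  tibble::tibble(metal_id = dr$metal_id, hat = dr$hat,
                 std_resid = dr$std_resid, in_domain = dr$in_domain,
                 response_outlier = !is.na(dr$std_resid) & abs(dr$std_resid) > 3)
}
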