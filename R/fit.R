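#' Fit the physicochemical-properties–criteria regression
#'
#' Ordinary least squares of ln CMC on the first-principal-component
#' raw-projection score of a descriptor subset — the model
#' `ln CMC = a * X1 + b` where X1 is the integrated radius for the default
#' subset {covalent radius, ionic radius, electron density}. The fit keeps
#' everything needed downstream: score mean and centred sum of squares for
#' confidence bands and leverages, residuals for the Williams plot, and the
#' PCA model for scoring new metals.
#'
#' @param data Training tibble: `metal_id`, strictly positive `cmc` (ug/L)
#'   and the subset descriptor columns, n >= 3 rows.
#' @param subset Descriptor columns defining the score (default the
#'   integrated-radius triple `CR`, `r`, `AR_AW`).
#' @param loadings `"computed"` (eigenvector of the correlation matrix),
#'   `"printed"` (the published three-decimal integrated-radius vector;
#'   only valid for the default subset), or a numeric vector in subset
#'   order.
#' @return An object of class `ppcr_fit` with components `pcm`, `loading`
#'   (the vector actually used), `slope`, `intercept`, `r2`, `rse` (residual
#'   standard error, ln units), `f_stat`, `p_value`, `n`, `score_mean`,
#'   `score_ssx`, `scores`, `residuals`, `fitted`, `data` and the underlying
#'   `lm`.
#' @export
#' @examples
#' fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
#' glance(fit)
fit_ppcr <- function(data, subset = c("CR", "r", "AR_AW"),
                     loadings = "computed") {
  stopifnot(is.data.frame(data))
  if (!"cmc" %in% names(data)) abort("training table needs a 'cmc' column")
  if (nrow(data) < 3) abort("need at least 3 records to fit")
  pcm <- fit_pca(data, subset)
  loading <- resolve_loading(loadings, subset)
  sc <- pc_scores(data, pcm, loading_override = loading)
  s <- sc$score
  if (sd(s) == 0) abort("zero score variance: cannot regress")
  y <- ln_transform(data$cmc, "cmc")
  mod <- lm(y ~ s)
  sm <- summary(mod)
  structure(
    list(pcm = pcm,
         loading = loading %||% pcm$loading,
         loadings_mode = if (is.character(loadings)) loadings else "override",
         slope = unname(coef(mod)[2]),
         intercept = unname(coef(mod)[1]),
         r2 = sm$r.squared,
         rse = sm$sigma,
         f_stat = unname(sm$fstatistic[1]),
         p_value = unname(pf_from_summary(sm)),
         n = nrow(data),
         score_mean = mean(s),
         score_ssx = sum((s - mean(s))^2),
         scores = sc,
         residuals = unname(resid(mod)),
         fitted = unname(fitted(mod)),
         data = data,
         lm = mod),
    class = "ppcr_fit")
}

resolve_loading <- function(loadings, subset) {
  if (is.numeric(loadings)) {
    if (length(loadings) != length(subset)) {
      abort("numeric loadings must match the subset length")
    }
    return(loadings)
  }
  mode <- match.arg(loadings, c("computed", "printed"))
  if (mode == "computed") return(NULL)
  printed <- printed_ir_loadings()
  if (!identical(subset, names(printed))) {
    abort("'printed' loadings exist only for the integrated-radius subset CR, r, AR_AW")
  }
  printed
}

pf_from_summary <- function(sm) {
  f <- sm$fstatistic
  stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
}

#' @export
print.ppcr_fit <- function(x, ...) {
  cat(ppcr_equation(x), "\n")
  cat(sprintf("  R2 = %.3f   RSE = %.3f (ln units)   F = %.2f on 1 and %d df   P = %.4g   n = %d\n",
              x$r2, x$rse, x$f_stat, x$n - 2L, x$p_value, x$n))
  cat(sprintf("  score: %s projected onto (%s)  [%s loadings]\n",
              paste(x$pcm$subset, collapse = ", "),
              paste(sprintf("%.3f", x$loading), collapse = ", "),
              x$loadings_mode))
  invisible(x)
}

#' Model equation in the conventional form
#'
#' @param fit A `ppcr_fit`.
#' @return A string like `"ln CMC = -8.75·X1 + 13.34"`.
#' @export
ppcr_equation <- function(fit) {
  stopifnot(inherits(fit, "ppcr_fit"))
  sprintf("ln CMC = %.2f·X1 %s %.2f", fit$slope,
          if (fit$intercept >= 0) "+" else "-", abs(fit$intercept))
}

#' @method tidy ppcr_fit
#' @export
tidy.ppcr_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(term = c("(Intercept)", "score"),
                 estimate = sm[, 1], std.error = sm[, 2],
                 statistic = sm[, 3], p.value = sm[, 4])
}

#' @method glance ppcr_fit
#' @export
glance.ppcr_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2,
                 adj.r.squared = summary(x$lm)$adj.r.squared,
                 sigma = x$rse, statistic = x$f_stat, p.value = x$p_value,
                 df = 1L, df.residual = x$n - 2L, nobs = x$n)
}

#' @method augment ppcr_fit
#' @export
augment.ppcr_fit <- function(x, ...) {
  dplyr::bind_cols(x$scores,
                   tibble::tibble(ln_cmc = ln_transform(x$data$cmc, "cmc"),
                                  .fitted = x$fitted, .resid = x$residuals))
}

#' Predict screening-level CMCs for metal records
#'
#' Scores each record with the fit's loading vector, evaluates
#' `intercept + slope * score` on the ln scale and back-transforms to ug/L.
#' The 95% band is computed on the ln scale from the Student t quantile on
#' n - 2 degrees of freedom and back-transformed multiplicatively:
#' `"confidence"` gives the mean-response band (the band drawn around the
#' fitted line), `"prediction"` the wider single-observation band. Each
#' record also gets its leverage against the training scores and an
#' `in_domain` flag (leverage below the warning value h*, see
#' [hat_values()]).
#'
#' @param object A `ppcr_fit`.
#' @param newdata Tibble of records carrying the subset columns; default the
#'   training table.
#' @param interval `"confidence"` (default), `"prediction"` or `"none"`.
#' @param level Coverage of the band (default 0.95).
#' @param ... Unused.
#' @return Tibble with `metal_id`, `score`, `ln_pred`, `cmc_pred`, `lwr`,
#'   `upr` (ug/L; `NA` when `interval = "none"`), `hat`, `in_domain`.
#' @export
#' @examples
#' fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
#' predict(fit)
predict.ppcr_fit <- function(object, newdata = NULL,
                             interval = c("confidence", "prediction", "none"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  newdata <- newdata %||% object$data
  sc <- pc_scores(newdata, object$pcm, loading_override = object$loading)
  s <- sc$score
  ln_pred <- object$intercept + object$slope * s
  h <- 1 / object$n + (s - object$score_mean)^2 / object$score_ssx
  if (interval == "none") {
    lwr <- upr <- rep(NA_real_, length(s))
  } else {
    se <- object$rse * sqrt(h + as.integer(interval == "prediction"))
    tcrit <- qt(1 - (1 - level) / 2, df = object$n - 2L)
    lwr <- exp(ln_pred - tcrit * se)
    upr <- exp(ln_pred + tcrit * se)
  }
  hstar <- warning_leverage(object$n)
  tibble::tibble(metal_id = sc$metal_id, score = s, ln_pred = ln_pred,
                 cmc_pred = exp(ln_pred), lwr = lwr, upr = upr,
                 hat = h, in_domain = h < hstar)
}

#' Serialize a fitted model to JSON
#'
#' Stores everything [predict.ppcr_fit()] and the applicability-domain
#' functions need — subset, loading, coefficients, fit statistics, score
#' mean/SSX and n — as plain JSON, so a model file can be shipped and
#' reloaded without the training data.
#'
#' @param fit A `ppcr_fit`.
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "ppcr_fit"))
  obj <- list(format = "metcrit-model", version = 1L,
              subset = fit$pcm$subset,
              loading = unname(as.numeric(fit$loading)),
              loadings_mode = fit$loadings_mode,
              slope = fit$slope, intercept = fit$intercept,
              r2 = fit$r2, rse = fit$rse, f_stat = fit$f_stat,
              p_value = fit$p_value, n = fit$n,
              score_mean = fit$score_mean, score_ssx = fit$score_ssx,
              eigenvalues = fit$pcm$eigenvalues,
              proportion = fit$pcm$proportion,
              residuals = fit$residuals,
              metal_id = fit$scores$metal_id,
              scores = fit$scores$score)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path JSON file written by [write_model()].
#' @return A `ppcr_fit` (without the original `lm`/training data; prediction
#'   and leverage work as before).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "metcrit-model") || !identical(as.integer(obj$version), 1L)) {
    abort("not a metcrit model file (or unsupported version)")
  }
  loading <- as.numeric(obj$loading)
  names(loading) <- obj$subset
  pcm <- structure(list(subset = obj$subset, loading = loading,
                        eigenvalues = obj$eigenvalues,
                        proportion = obj$proportion,
                        sd1 = sqrt(obj$eigenvalues[1]),
                        center = NULL, scale = NULL, n = obj$n),
                   class = "pc_model")
  structure(
    list(pcm = pcm, loading = loading, loadings_mode = obj$loadings_mode,
         slope = obj$slope, intercept = obj$intercept, r2 = obj$r2,
         rse = obj$rse, f_stat = obj$f_stat, p_value = obj$p_value,
         n = obj$n, score_mean = obj$score_mean, score_ssx = obj$score_ssx,
         scores = tibble::tibble(metal_id = obj$metal_id, score = obj$scores),
         residuals = obj$residuals,
         fitted = obj$intercept + obj$slope * obj$scores,
         data = NULL, lm = NULL),
    class = "ppcr_fit")
}

#' One-screen model summary
#'
#' @param fit A `ppcr_fit` (or path to a model JSON).
#' @param style `"text"` (printed lines) or `"json"` (string).
#' @return The summary string, invisibly for `"text"`.
#' @export
model_summary <- function(fit, style = c("text", "json")) {
  style <- match.arg(style)
  if (is.character(fit)) fit <- read_model(fit)
  stopifnot(inherits(fit, "ppcr_fit"))
  if (!length(fit$pcm$subset)) abort("model has an empty descriptor subset")
  if (style == "json") {
    s <- jsonlite::toJSON(list(
      equation = ppcr_equation(fit), r2 = fit$r2, rse = fit$rse,
      f_stat = fit$f_stat, p_value = fit$p_value, n = fit$n,
      h_star = warning_leverage(fit$n)), auto_unbox = TRUE, digits = NA)
    cat(s, "\n")
    return(invisible(as.character(s)))
  }
  lines <- c(
    ppcr_equation(fit),
    sprintf("R2 = %.3f  RSE = %.3f  F = %.2f  P = %.4g  n = %d  h* = %.3f",
            fit$r2, fit$rse, fit$f_stat, fit$p_value, fit$n,
            warning_leverage(fit$n)))
  cat(lines, sep = "\n")
  invisible(paste(lines, collapse = "\n"))
}
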