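#' Default per-descriptor transform policy
#'
#' Descriptors, like environmental concentrations, tend to be log-normal, so
#' the default policy ln-transforms every descriptor that is strictly
#' positive across the table and leaves the rest raw (e.g. melting point,
#' which is negative for mercury). The response (CMC) is always modelled on
#' the natural-log scale.
#'
#' @param data Descriptor tibble.
#' @return Named character vector, one of `"ln"`/`"raw"` per descriptor
#'   column present in the table.
#' @export
default_policy <- function(data) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  descr <- setdiff(num, "cmc")
  pol <- vapply(descr, function(d) {
    v <- data[[d]]
    if (all(v > 0, na.rm = TRUE)) "ln" else "raw"
  }, character(1))
  pol
}

#' Transform policy that reproduces the published correlation screen
#'
#' The published single-descriptor screen is internally inconsistent: the
#' softness index, covalent radius and ionic radius rows match a ln-ln
#' Pearson correlation, while atomic number, atomic weight, AN/dIP and
#' electron density match raw-descriptor vs ln-CMC. This policy pins, per
#' descriptor, whichever transform reproduces the printed coefficient; it is
#' the policy the reproduction report uses.
#'
#' @return Named character vector as in [default_policy()].
#' @export
table2_policy <- function() {
  pol <- default_policy(ppcr_training_table())
  pol[c("AN", "AW", "AN_dIP", "AR_AW")] <- "raw"
  pol
}

#' Pearson screen of descriptors against ln CMC
#'
#' Correlates each numeric column other than `cmc` (after its
#' per-descriptor transform)
#' with the natural log of the criteria maximum concentration, reporting the
#' Pearson coefficient, the t statistic on n - 2 degrees of freedom and the
#' two-sided p value. No multiple-testing correction is applied.
#'
#' Descriptors with fewer than 3 complete pairs, or zero variance after
#' transformation, are flagged in the `note` column rather than dropped
#' silently; their statistics are `NA`.
#'
#' @param data Training tibble with a strictly positive `cmc` column.
#' @param policy Named character vector of `"ln"`/`"raw"` per descriptor;
#'   defaults to [default_policy()]. Requesting `"ln"` for a descriptor with
#'   non-positive values is an error.
#' @return A tibble sorted by `|r|` descending with columns `descriptor`,
#'   `transform`, `cmc_transform`, `n`, `r`, `t`, `p`, `note`.
#' @export
#' @examples
#' pearson_screen(ppcr_training_table(), policy = table2_policy())
pearson_screen <- function(data, policy = default_policy(data)) {
  stopifnot(is.data.frame(data))
  if (!"cmc" %in% names(data)) abort("training table needs a 'cmc' column")
  y <- ln_transform(data$cmc, "cmc")
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  descr <- setdiff(num, "cmc")
  if (!length(descr)) abort("no descriptor columns in table")
  policy <- policy[descr]
  policy[is.na(policy)] <- "raw"
  names(policy) <- descr

  rows <- purrr::map(descr, function(d) {
    x <- data[[d]]
    tx <- policy[[d]]
    if (tx == "ln") x <- ln_transform(x, d)
    ok <- stats::complete.cases(x, y)
    out <- tibble::tibble(descriptor = d, transform = tx, cmc_transform = "ln",
                          n = sum(ok), r = NA_real_, t = NA_real_, p = NA_real_,
                          note = NA_character_)
    if (sum(ok) < 3) {
      out$note <- "fewer than 3 complete pairs"
      return(out)
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      out$note <- "zero variance: correlation undefined"
      return(out)
    }
    r <- cor(x[ok], y[ok])
    df <- sum(ok) - 2L
    tstat <- r * sqrt(df) / sqrt(1 - r^2)
    out$r <- r
    out$t <- tstat
    out$p <- 2 * pt(-abs(tstat), df)
    out
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(abs(.data$r)))
}

#' Select significantly correlated descriptors
#'
#' Keeps descriptors with a coefficient of determination above `r2_min` and
#' a two-sided p value below `alpha` — the screen that reduces the 26
#' candidate descriptors to the handful worth carrying into the
#' principal-component model.
#'
#' @param results Output of [pearson_screen()].
#' @param r2_min Minimum r^2 (default 0.5, exclusive).
#' @param alpha Significance level (default 0.05, exclusive).
#' @return Character vector of selected descriptor names, in decreasing
#'   `|r|` order.
#' @export
significance_filter <- function(results, r2_min = 0.5, alpha = 0.05) {
  if (!nrow(results)) abort("empty screen results")
  keep <- results |>
    dplyr::filter(!is.na(.data$r), .data$r^2 > r2_min, .data$p < alpha) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
  keep$descriptor
}
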