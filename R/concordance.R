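#' Rank concordance between predicted criteria and LC50 toxicity
#'
#' A screening-level criterion is useful if, at minimum, it orders metals
#' the way measured toxicity does. Within each periodic-table group (or
#' period), this compares the ordering of predicted CMCs with the ordering
#' of amphipod LC50 values and flags the group `"concordant"`,
#' `"discordant"` or `"tie"` (exact numeric ties are reported, never broken
#' silently). Across all joined metals it also reports the Spearman rank
#' correlation between ln predicted CMC and ln LC50.
#'
#' Gold is excluded by default: its toxicity record is too thin for the
#' comparison to mean anything for this relatively unreactive metal.
#'
#' @param preds Tibble with `metal_id` and a predicted-CMC column
#'   (`cmc_pred` from [predict.ppcr_fit()], or `predicted_cmc`).
#' @param lc50 Tibble like [hyalella_lc50()]: `metal_id`, grouping columns
#'   and the LC50 columns.
#' @param by Grouping key: `"group"`, `"block"` or `"period"`.
#' @param column Which LC50 column to rank against: `"measured"` or
#'   `"nominal"`.
#' @param include_au Include gold (default `FALSE`).
#' @return Object of class `concordance_report`: `by`, `column`, `groups`
#'   (tibble with `group`, `n`, `flag`), `rho` (Spearman, ln scale),
#'   `unmatched` (metal ids present on only one side), `n_joined`.
#' @export
#' @examples
#' rank_concordance(hyalella_lc50(), hyalella_lc50(), by = "block")
rank_concordance <- function(preds, lc50, by = c("group", "block", "period"),
                             column = c("measured", "nominal"),
                             include_au = FALSE) {
  by <- match.arg(by)
  column <- match.arg(column)
  lc_col <- paste0("lc50_", column)
  if (!lc_col %in% names(lc50)) abort(paste0("lc50 table lacks column ", lc_col))
  if (!by %in% names(lc50)) abort(paste0("lc50 table lacks grouping column ", by))
  pred_col <- intersect(c("cmc_pred", "predicted_cmc"), names(preds))[1]
  if (is.na(pred_col)) abort("preds needs a 'cmc_pred' or 'predicted_cmc' column")

  if (!include_au) lc50 <- dplyr::filter(lc50, .data$metal_id != "Au")
  if (anyDuplicated(preds$metal_id) || anyDuplicated(lc50$metal_id)) {
    abort("metal_id must be unique on both sides of the join")
  }
  joined <- dplyr::inner_join(
    dplyr::select(preds, "metal_id", pred = dplyr::all_of(pred_col)),
    dplyr::select(lc50, "metal_id", group = dplyr::all_of(by),
                  lc50 = dplyr::all_of(lc_col)),
    by = "metal_id")
  unmatched <- c(setdiff(preds$metal_id, joined$metal_id),
                 setdiff(lc50$metal_id, joined$metal_id))
  if (nrow(joined) < 2) abort("fewer than 2 joined metals")

  groups <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      flag = dplyr::case_when(
        dplyr::n() < 2 ~ NA_character_,
        anyDuplicated(.data$pred) > 0 || anyDuplicated(.data$lc50) > 0 ~ "tie",
        identical(order(.data$pred), order(.data$lc50)) ~ "concordant",
        TRUE ~ "discordant"),
      .groups = "drop")

  rho <- cor(log(joined$pred), log(joined$lc50), method = "spearman")
  structure(
    list(by = by, column = column, groups = groups, rho = rho,
         unmatched = unmatched, n_joined = nrow(joined)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Rank concordance vs LC50 (%s), grouped by %s: %d metals joined\n",
              x$column, x$by, x$n_joined))
  print(x$groups)
  cat(sprintf("  overall Spearman rho (ln scale) = %.3f\n", x$rho))
  if (length(x$unmatched)) {
    cat("  unmatched:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
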