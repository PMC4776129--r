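published_checks <- function() {
  tibble::tribble(
    ~quantity,          ~published, ~tol,   ~tol_type,
    "screen_r_sigma_p",  0.88,      0.01,   "abs",
    "screen_r_CR",      -0.79,      0.01,   "abs",
    "screen_r_AN",      -0.74,      0.01,   "abs",
    "screen_r_AW",      -0.73,      0.01,   "abs",
    "screen_r_AN_dIP",  -0.73,      0.01,   "abs",
    "pc1_share_pct",    88.8,       0.3,    "abs",
    "slope",            -8.75,      0.02,   "abs",
    "intercept",        13.34,      0.02,   "abs",
    "r2",                0.63,      0.005,  "abs",
    "f_stat",           10.23,      0.05,   "abs",
    "rse",               1.58,      0.01,   "abs",
    "cmc_fit_Zn",       35,         0.05,   "rel",
    "cmc_fit_Cd",        3.47,      0.05,   "rel",
    "cmc_fit_Ag",        1.64,      0.05,   "rel",
    "cmc_fit_Ni",       75,         0.05,   "rel")
}

#' One-shot reproduction of the published criteria model
#'
#' Runs the whole pipeline on the bundled eight-metal training table — the
#' correlation screen, the integrated-radius PCA, the ln CMC regression,
#' leave-one-out cross-validation, the applicability-domain table and the
#' LC50 rank-concordance comparison — and writes each stage's result plus a
#' diff table against the published values with tolerances.
#'
#' @param out_dir Directory for the report bundle (created if needed):
#'   `screen.csv`, `model.json`, `predictions.csv`, `cv.json`,
#'   `williams.csv`, `concordance.json`, `diff.csv`.
#' @param loadings `"printed"` (default; reproduces the published
#'   coefficients to the printed decimals) or `"computed"`.
#' @param seed Seed recorded in the bundle and used for any shuffled CV.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted model, the stage results, the
#'   `diff` tibble and `pass` (all published checks within tolerance).
#' @export
#' @examples
#' \donttest{
#' rep <- run_reproduction(tempfile("repro"))
#' rep$pass
#' }
run_reproduction <- function(out_dir, loadings = "printed", seed = 1L,
                             quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  tbl <- ppcr_training_table()
  if (!nrow(tbl)) abort("stage data: training table is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage screen: Pearson correlation of 26 descriptors vs ln CMC")
  screen <- pearson_screen(tbl, policy = table2_policy())
  screen$selected <- screen$descriptor %in% significance_filter(screen)
  readr::write_csv(screen, file.path(out_dir, "screen.csv"), progress = FALSE)

  say("stage fit: integrated-radius model (", loadings, " loadings)")
  fit <- fit_ppcr(tbl, loadings = loadings)
  write_model(fit, file.path(out_dir, "model.json"))

  say("stage predict: fitted CMCs for the training metals")
  preds <- predict(fit, interval = "confidence")
  readr::write_csv(preds, file.path(out_dir, "predictions.csv"), progress = FALSE)

  say("stage validate: LOO cross-validation and Williams table")
  cv <- cross_validate(tbl, k = "loo", seed = seed)
  jsonlite::write_json(list(scheme = cv$scheme, k = cv$k, seed = seed,
                            q2_cv = cv$q2_cv, rmse_cv = cv$rmse_cv),
                       file.path(out_dir, "cv.json"),
                       auto_unbox = TRUE, digits = NA)
  wt <- williams_export(hat_values(fit))
  readr::write_csv(wt, file.path(out_dir, "williams.csv"), progress = FALSE)

  say("stage concordance: predicted CMCs vs amphipod LC50 ranks")
  lc50 <- hyalella_lc50()
  conc <- rank_concordance(lc50, lc50, by = "block", column = "measured")
  jsonlite::write_json(list(by = conc$by, column = conc$column, seed = seed,
                            rho = conc$rho, groups = conc$groups),
                       file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)

  observed <- c(
    screen_r_sigma_p = screen$r[screen$descriptor == "sigma_p"],
    screen_r_CR = screen$r[screen$descriptor == "CR"],
    screen_r_AN = screen$r[screen$descriptor == "AN"],
    screen_r_AW = screen$r[screen$descriptor == "AW"],
    screen_r_AN_dIP = screen$r[screen$descriptor == "AN_dIP"],
    pc1_share_pct = 100 * fit$pcm$proportion,
    slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
    f_stat = fit$f_stat, rse = fit$rse,
    cmc_fit_Zn = preds$cmc_pred[preds$metal_id == "Zn"],
    cmc_fit_Cd = preds$cmc_pred[preds$metal_id == "Cd"],
    cmc_fit_Ag = preds$cmc_pred[preds$metal_id == "Ag"],
    cmc_fit_Ni = preds$cmc_pred[preds$metal_id == "Ni"])
  diff <- published_checks() |>
    dplyr::mutate(observed = unname(observed[.data$quantity]),
                  rel_error = (.data$observed - .data$published) / abs(.data$published),
                  within_tol = ifelse(.data$tol_type == "rel",
                                      abs(.data$rel_error) <= .data$tol,
                                      abs(.data$observed - .data$published) <= .data$tol))
  readr::write_csv(diff, file.path(out_dir, "diff.csv"), progress = FALSE)
  pass <- all(diff$within_tol)
  say(sprintf("diff table: %d/%d published quantities within tolerance",
              sum(diff$within_tol), nrow(diff)))

  invisible(list(fit = fit, screen = screen, predictions = preds, cv = cv,
                 williams = wt, concordance = conc, diff = diff,
                 seed = seed, pass = pass))
}
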