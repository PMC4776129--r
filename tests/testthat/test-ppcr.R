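ir_subset <- c("CR", "r", "AR_AW")

test_that("integrated-radius PCA reproduces the published eigenstructure", {
  pcm <- fit_pca(ppcr_training_table(), ir_subset)
  expect_equal(pcm$eigenvalues[1], 2.665, tolerance = 1e-3)
  expect_equal(pcm$proportion, 0.888, tolerance = 1e-3)
  expect_equal(unname(pcm$loading), c(0.567, 0.568, -0.597), tolerance = 2e-3)
  # structural invariants of a correlation-matrix eigendecomposition
  expect_equal(sum(pcm$loading^2), 1, tolerance = 1e-9)
  expect_equal(sum(pcm$eigenvalues), 3, tolerance = 1e-9)
  expect_true(all(diff(pcm$eigenvalues) <= 1e-12))
  expect_true(all(pcm$eigenvalues >= -1e-12))
  expect_equal(pcm$sd1, sqrt(pcm$eigenvalues[1]))
})

test_that("pairwise correlations under the PCA match a direct Pearson oracle", {
  tbl <- ppcr_training_table()
  expect_equal(oracle_pearson(tbl$CR, tbl$r)$r, 0.7409, tolerance = 1e-4)
  expect_equal(oracle_pearson(tbl$CR, tbl$AR_AW)$r, -0.8749, tolerance = 1e-4)
  expect_equal(oracle_pearson(tbl$r, tbl$AR_AW)$r, -0.8793, tolerance = 1e-4)
})

test_that("two perfectly correlated columns give the closed-form eigenpair", {
  tbl <- tibble::tibble(metal_id = letters[1:5], a = 1:5, b = 2 * (1:5) + 3)
  pcm <- fit_pca(tbl, c("a", "b"))
  expect_equal(pcm$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(unname(pcm$loading), c(1, 1) / sqrt(2), tolerance = 1e-9)
})

test_that("first eigenpair matches power iteration on random tables", {
  for (seed in 1:4) {
    k <- 2 + seed %% 4                    # 3, 4, 5, 2 columns
    tbl <- random_table(n = 12, k = k, seed = seed)
    pcm <- fit_pca(tbl, paste0("d", seq_len(k)))
    orc <- oracle_power_iteration(stats::cor(as.matrix(tbl[paste0("d", seq_len(k))])))
    expect_equal(pcm$eigenvalues[1], orc$value, tolerance = 1e-9)
    expect_equal(unname(pcm$loading), orc$vector, tolerance = 1e-9)
  }
})

test_that("PCA errors name the offending column", {
  tbl <- ppcr_training_table()
  tbl$CR[3] <- NA
  expect_error(fit_pca(tbl, ir_subset), "CR")
  tbl2 <- ppcr_training_table()
  tbl2$r <- 1
  expect_error(fit_pca(tbl2, c("CR", "r")), "constant column 'r'")
  expect_error(fit_pca(ppcr_training_table(), "CR"), "at least 2")
})

test_that("raw-projection scores reproduce the published X1 values", {
  tbl <- ppcr_training_table()
  pcm <- fit_pca(tbl, ir_subset)
  sc <- pc_scores(tbl, pcm, loading_override = printed_ir_loadings())
  expect_equal(sc$score[sc$metal_id == "Cd"], 1.3810, tolerance = 1e-4)
  expect_equal(sc$score[sc$metal_id == "Ag"], 1.4658, tolerance = 1e-4)
  # projection identity: unit loading on one descriptor returns it unchanged
  sc1 <- pc_scores(tbl, pcm, loading_override = c(1, 0, 0))
  expect_equal(sc1$score, tbl$CR)
  # missing subset values are a per-record error
  tbl$r[tbl$metal_id == "Hg"] <- NA
  expect_error(pc_scores(tbl, pcm), "Hg")
})

test_that("fit with printed loadings reproduces the published regression", {
  fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
  expect_equal(fit$slope, -8.7492, tolerance = 1e-4)
  expect_equal(fit$intercept, 13.3364, tolerance = 1e-4)
  expect_equal(fit$r2, 0.6303, tolerance = 1e-4)
  expect_equal(fit$f_stat, 10.227, tolerance = 1e-3)
  expect_equal(fit$rse, 1.5754, tolerance = 1e-4)
  # largest-magnitude residual is Cr(VI)
  i <- which(fit$data$metal_id == "Cr(VI)")
  expect_equal(fit$residuals[i], -2.312, tolerance = 1e-3)
  expect_equal(which.max(abs(fit$residuals)), i)
  expect_equal(ppcr_equation(fit), "ln CMC = -8.75·X1 + 13.34")
})

test_that("fit statistics satisfy their algebraic identities", {
  for (fit in list(fit_ppcr(ppcr_training_table(), loadings = "printed"),
                   fit_ppcr(random_table(10, 3, seed = 5), subset = paste0("d", 1:3)))) {
    n <- fit$n
    y <- log(fit$data$cmc)
    sst <- sum((y - mean(y))^2)
    expect_equal(fit$f_stat, fit$r2 / (1 - fit$r2) * (n - 2), tolerance = 1e-9)
    expect_equal(fit$rse^2, (1 - fit$r2) * sst / (n - 2), tolerance = 1e-9)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  }
})

test_that("slope and intercept match the closed-form least-squares sums", {
  for (seed in 1:5) {
    tbl <- random_table(n = 9, k = 3, seed = seed)
    fit <- fit_ppcr(tbl, subset = paste0("d", 1:3))
    s <- fit$scores$score
    orc <- oracle_ols(s, log(tbl$cmc))
    expect_equal(fit$slope, orc$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-12)
  }
})

test_that("R2, F and P are invariant under affine score rescaling", {
  tbl <- ppcr_training_table()
  base <- fit_ppcr(tbl, loadings = "printed")
  for (c0 in c(2, -1, 0.25)) {
    scaled <- fit_ppcr(tbl, loadings = c0 * printed_ir_loadings())
    expect_equal(scaled$r2, base$r2, tolerance = 1e-12)
    expect_equal(scaled$f_stat, base$f_stat, tolerance = 1e-9)
    expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
    expect_equal(scaled$slope, base$slope / c0, tolerance = 1e-9)
  }
})

test_that("predictions back-transform to the published fitted CMCs", {
  fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
  pr <- predict(fit)
  cmc_of <- function(m) pr$cmc_pred[pr$metal_id == m]
  expect_equal(cmc_of("Ag"), 1.67, tolerance = 5e-3)   # published fitted 1.64
  expect_equal(cmc_of("Zn"), 35.9, tolerance = 5e-3)   # published fitted 35
  expect_equal(pr$ln_pred[pr$metal_id == "Ag"], 0.512, tolerance = 5e-3)
  # regression passes through the centroid
  centroid <- tibble::tibble(metal_id = "centroid",
                             CR = 1, r = 1, AR_AW = 1)
  # solve for a record whose score equals the mean training score
  L <- fit$loading
  centroid$AR_AW <- (fit$score_mean - L[1] * 1 - L[2] * 1) / L[3]
  pc <- predict(fit, centroid)
  expect_equal(pc$ln_pred, mean(log(fit$data$cmc)), tolerance = 1e-9)
  expect_equal(pc$hat, 1 / fit$n, tolerance = 1e-9)
  # monotone: negative slope means CMC strictly decreases with score
  ord <- order(pr$score)
  expect_true(all(diff(pr$cmc_pred[ord]) < 0 | diff(pr$score[ord]) == 0))
})

test_that("interval types nest correctly and back-transform multiplicatively", {
  fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
  conf <- predict(fit, interval = "confidence")
  pred <- predict(fit, interval = "prediction")
  none <- predict(fit, interval = "none")
  expect_true(all(pred$lwr < conf$lwr & pred$upr > conf$upr))
  expect_true(all(conf$lwr < conf$cmc_pred & conf$upr > conf$cmc_pred))
  expect_true(all(is.na(none$lwr)))
  # band is symmetric on the ln scale
  expect_equal(log(conf$upr) - conf$ln_pred, conf$ln_pred - log(conf$lwr),
               tolerance = 1e-9)
})

test_that("slope recovery on larger synthetic tables is within 3 SE", {
  tbl <- simulate_training_table(n = 200, k = 3, planted_slope = -2,
                                 noise_sd = 0.1, seed = 9)
  fit <- fit_ppcr(tbl, subset = paste0("d", 1:3))
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - (-2)), 3 * se)
})

test_that("model JSON serialization round-trips", {
  fit <- fit_ppcr(ppcr_training_table(), loadings = "printed")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  new_metal <- tibble::tibble(metal_id = "Mn", CR = 1.39, r = 0.83,
                              AR_AW = 1.61 / 54.94)
  expect_equal(predict(back, new_metal), predict(fit, new_metal),
               tolerance = 1e-12)
  # a second write of the reloaded model is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(read_model(metcrit_example("table1_training.csv")))
})
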