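#' Simulate a training table with a planted descriptor-criteria relationship
#'
#' Generates a synthetic metal table whose ln CMC is exactly
#' `planted_slope` times the first-principal-component raw-projection score
#' of `k` log-normal descriptors, plus Gaussian noise. Because the truth is
#' planted on the same score convention the fitting pipeline uses, the
#' recovered slope can be checked against the generating one, and with
#' `noise_sd = 0` the downstream fit interpolates (R^2 = 1).
#'
#' Descriptors are drawn i.i.d. log-normal with meanlog 0 and sdlog 0.5 —
#' positive quantities of order one with a few-fold spread, the scale of the
#' radius and ratio descriptors real tables contain.
#'
#' @param n Number of synthetic metals (>= 4).
#' @param k Number of descriptor columns (>= 1), named `d1 ... dk`.
#' @param planted_slope True slope of ln CMC per unit PC1 score.
#' @param noise_sd Standard deviation of ln-scale noise (>= 0).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A tibble with `metal_id`, `d1..dk` and `cmc` (ug/L). Attribute
#'   `"truth"` records the planted slope, loading vector and scores.
#' @export
#' @examples
#' simulate_training_table(n = 12, k = 3, planted_slope = -2,
#'                         noise_sd = 0.1, seed = 42)
simulate_training_table <- function(n, k = 3, planted_slope = -2,
                                    noise_sd = 0.5, seed = 1L) {
  stopifnot(n >= 4, k >= 1, noise_sd >= 0)
  if (n <= k + 1) {
    warn(sprintf("n = %d with k = %d descriptors risks rank deficiency", n, k))
  }
  withr::with_seed(seed, {
    X <- matrix(rlnorm(n * k, meanlog = 0, sdlog = 0.5), nrow = n)
    colnames(X) <- paste0("d", seq_len(k))
    if (k == 1L) {
      loading <- c(d1 = 1)
    } else {
      ev <- eigen(cor(X), symmetric = TRUE)
      loading <- ev$vectors[, 1]
      if (loading[1] < 0) loading <- -loading
      names(loading) <- colnames(X)
    }
    score <- as.numeric(X %*% loading)
    ln_cmc <- planted_slope * score + rnorm(n, sd = noise_sd)
    out <- tibble::as_tibble(as.data.frame(X))
    out <- dplyr::bind_cols(
      tibble::tibble(metal_id = sprintf("M%02d", seq_len(n))), out)
    out$cmc <- exp(ln_cmc)
    attr(out, "truth") <- list(planted_slope = planted_slope,
                               loading = loading, score = score,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}
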