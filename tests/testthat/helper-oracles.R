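# Independent textbook implementations used to cross-check the package.

# Pearson r, t and two-sided p from raw sums (no cor()/cor.test()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# Leading eigenpair of a symmetric PSD matrix by power iteration.
oracle_power_iteration <- function(M, tol = 1e-14, max_iter = 10000) {
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    v_new <- as.numeric(w) / sqrt(sum(w^2))
    lambda_new <- as.numeric(t(v_new) %*% M %*% v_new)
    if (abs(lambda_new - lambda) < tol && sqrt(sum((v_new - v)^2)) < tol) {
      v <- v_new; lambda <- lambda_new; break
    }
    v <- v_new; lambda <- lambda_new
  }
  if (v[1] < 0) v <- -v
  list(value = lambda, vector = v)
}

# Simple-regression slope/intercept from the closed-form sum formulas.
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept)
}

# Random positive descriptor table for property tests.
random_table <- function(n, k, seed) {
  withr::with_seed(seed, {
    X <- matrix(stats::rlnorm(n * k, 0, 0.5), nrow = n)
    colnames(X) <- paste0("d", seq_len(k))
    out <- tibble::as_tibble(as.data.frame(X))
    out$metal_id <- sprintf("M%02d", seq_len(n))
    out$cmc <- stats::rlnorm(n, 2, 1)
    out
  })
}
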