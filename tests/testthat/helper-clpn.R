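# Shared test utilities: deterministic toy panels, an independent
# coordinate-descent LASSO oracle, and null-model generator specs.

toy_values <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * 22, 5, 2)), n, 22)
  colnames(m) <- clpnet:::analysis_columns()
  m
}

toy_panel <- function(n = 40, seed = 1, stage = NULL) {
  v <- toy_values(n, seed)
  if (is.null(stage)) stage <- rep(c("I", "II", "III", "IV"), length.out = n)
  panel_dataset(v, stage = stage)
}

# Independent coordinate-descent oracle for
#   min 1/(2n) sum((y - b0 - X b)^2) + lambda * sum(|b|)
# (cycled soft-thresholding; no shared code with the estimator).
cd_lasso <- function(x, y, lambda, max_iter = 20000, tol = 1e-13) {
  x <- as.matrix(x)
  p <- ncol(x)
  b0 <- mean(y)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  b <- numeric(p)
  denom <- colMeans(xc^2)
  r <- y - b0
  for (it in seq_len(max_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      zj <- mean(xc[, j] * r) + denom[j] * b[j]
      bj <- sign(zj) * max(abs(zj) - lambda, 0) / denom[j]
      r <- r - xc[, j] * (bj - b[j])
      b[j] <- bj
    }
    if (max(abs(b - b_old)) < tol) break
  }
  list(beta = b, intercept = b0 - sum(xm * b))
}

zero_cross <- function() {
  codes <- clpnet:::node_codes()
  matrix(0, 11, 11, dimnames = list(codes, codes))
}

# Two-wave cohort with no temporal signal at all: pure-noise wave 2.
null_sim_spec <- function(n, seed, mcar_rate = 0) {
  clpn_sim_spec(n = n, auto_coeffs = rep(0, 11), cross_matrix = zero_cross(),
                noise_sd = rep(1, 11), mcar_rate = mcar_rate, seed = seed)
}

# Covariate-free settings: the default generator carries no covariate
# effects, so simulation tests skip the (slow) covariate adjustment.
fast_settings <- function(...) clpn_settings(use_covariates = FALSE, ...)
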