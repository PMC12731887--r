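# ML estimation of a multivariate-normal mean/covariance under arbitrary
# missingness via EM. Patterns are processed jointly; rows observing no
# variable contribute nothing. Returns ML (1/n) covariance.
em_mvnorm <- function(Y, max_iter = 500, tol = 1e-8) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, k)
  pat_key <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  pat_miss <- lapply(pats, function(rows) is.na(Y[rows[1], ]))

  for (it in seq_len(max_iter)) {
    S1 <- numeric(k)
    S2 <- matrix(0, k, k)
    for (p in seq_along(pats)) {
      rows <- pats[[p]]; miss <- pat_miss[[p]]; obs <- !miss
      m <- length(rows)
      if (!any(obs)) next
      Yo <- Y[rows, obs, drop = FALSE]
      if (!any(miss)) {
        S1[obs] <- S1[obs] + colSums(Yo)
        S2[obs, obs] <- S2[obs, obs] + crossprod(Yo)
        next
      }
      So <- sigma[obs, obs, drop = FALSE]
      B <- sigma[miss, obs, drop = FALSE] %*% solve(So)
      # conditional means of the missing block given the observed block
      dev <- sweep(Yo, 2, mu[obs])
      Ym <- matrix(mu[miss], m, sum(miss), byrow = TRUE) + dev %*% t(B)
      Cm <- sigma[miss, miss, drop = FALSE] - B %*% sigma[obs, miss, drop = FALSE]
      S1[obs] <- S1[obs] + colSums(Yo)
      S1[miss] <- S1[miss] + colSums(Ym)
      S2[obs, obs] <- S2[obs, obs] + crossprod(Yo)
      S2[obs, miss] <- S2[obs, miss] + crossprod(Yo, Ym)
      S2[miss, obs] <- S2[miss, obs] + crossprod(Ym, Yo)
      S2[miss, miss] <- S2[miss, miss] + crossprod(Ym) + m * Cm
    }
    mu_new <- S1 / n
    sigma_new <- S2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- (sigma_new + t(sigma_new)) / 2
    if (delta < tol * (1 + max(abs(sigma)))) break
  }
  list(mu = mu, sigma = sigma, iterations = it)
}

#' Little's test of missing completely at random (MCAR)
#'
#' Compares each missingness pattern's observed-variable means against the
#' pooled EM (maximum-likelihood) estimates of the mean and covariance;
#' under MCAR the summed squared standardized deviations follow a
#' chi-square distribution with `sum(k_p) - k` degrees of freedom, where
#' `k_p` counts the variables observed in pattern p.
#'
#' @param data a [panel_dataset()] (the 22 analysis variables are used) or
#'   a numeric matrix with `NA`s.
#' @return An object of class `htest` with `statistic` (chi-square),
#'   `parameter` (df) and `p.value`.
#' @export
little_mcar_test <- function(data) {
  Y <- if (inherits(data, "panel_dataset")) data$values else as.matrix(data)
  dn <- deparse(substitute(data))
  pat_key <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  if (length(unique(pat_key)) < 2) {
    stop("need at least two distinct missingness patterns (is the data complete?)")
  }
  k <- ncol(Y)
  fit <- em_mvnorm(Y)
  d2 <- 0
  df <- 0
  for (rows in split(seq_len(nrow(Y)), pat_key)) {
    obs <- !is.na(Y[rows[1], ])
    if (!any(obs)) next
    m <- length(rows)
    ybar <- colMeans(Y[rows, obs, drop = FALSE])
    dev <- ybar - fit$mu[obs]
    d2 <- d2 + m * drop(crossprod(dev, solve(fit$sigma[obs, obs, drop = FALSE], dev)))
    df <- df + sum(obs)
  }
  df <- df - k
  structure(
    list(statistic = c(`chi-square` = d2),
         parameter = c(df = df),
         p.value = pchisq(d2, df, lower.tail = FALSE),
         method = "Little's MCAR test",
         data.name = dn),
    class = "htest"
  )
}
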