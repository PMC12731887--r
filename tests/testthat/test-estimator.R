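make_toy_regression <- function(n = 120, p = 4, seed = 31) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- c(0.5, -0.3, rep(0, p - 2))
  y <- drop(x %*% beta) + rnorm(n, sd = 0.8)
  list(x = x, y = y)
}

test_that("the penalty limit forces an exactly empty lagged model", {
  toy <- make_toy_regression()
  fit <- fit_node(toy$y, toy$x, settings = clpn_settings(lambda = Inf))
  expect_identical(unname(fit$coefficients), rep(0, 4))

  # covariates stay free in the limit
  covs <- data.frame(age = rnorm(120, 50, 10))
  fit2 <- fit_node(toy$y, toy$x, covariates = covs,
                   settings = clpn_settings(lambda = Inf))
  expect_identical(unname(fit2$coefficients), rep(0, 4))
  expect_true(is.finite(fit2$covariate_coefficients[["age"]]))
})

test_that("the unpenalized fit matches the closed-form least-squares oracle", {
  toy <- make_toy_regression(n = 150, p = 6, seed = 7)
  fit <- fit_node(toy$y, toy$x, settings = clpn_settings(lambda = 0))
  zx <- scale(toy$x); zy <- as.numeric(scale(toy$y))
  ols <- solve(crossprod(zx), crossprod(zx, zy))
  expect_lt(max(abs(fit$coefficients - drop(ols))), 1e-6)
})

test_that("fixed-penalty fits match an independent coordinate-descent oracle", {
  for (lam in c(0.02, 0.08, 0.2)) {
    toy <- make_toy_regression(n = 90, p = 3, seed = 13)
    fit <- fit_node(toy$y, toy$x, settings = clpn_settings(lambda = lam))
    zx <- scale(toy$x); zy <- as.numeric(scale(toy$y))
    oracle <- cd_lasso(zx, zy, lam)
    expect_lt(max(abs(fit$coefficients - oracle$beta)), 1e-6)
  }
})

test_that("the active set shrinks monotonically along the penalty path", {
  toy <- make_toy_regression(n = 200, p = 8, seed = 3)
  lams <- c(0, 0.01, 0.03, 0.06, 0.1, 0.2, 0.5)
  nnz <- vapply(lams, function(l) {
    sum(fit_node(toy$y, toy$x, settings = clpn_settings(lambda = l))$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("fit_node is equivariant under predictor relabeling", {
  toy <- make_toy_regression(n = 100, p = 5, seed = 17)
  perm <- c(3, 1, 5, 2, 4)
  fit <- fit_node(toy$y, toy$x, settings = clpn_settings(lambda = 0.05))
  fit_p <- fit_node(toy$y, toy$x[, perm], settings = clpn_settings(lambda = 0.05))
  expect_equal(unname(fit_p$coefficients), unname(fit$coefficients[perm]),
               tolerance = 1e-8)
})

test_that("fit_node rejects degenerate inputs", {
  toy <- make_toy_regression()
  expect_error(fit_node(rep(1, 120), toy$x), "degenerate outcome")
  expect_error(fit_node(toy$y[1:20], toy$x[1:20, ]), "insufficient data")
  x_bad <- toy$x; x_bad[, 2] <- 3
  expect_error(fit_node(toy$y, x_bad), "constant predictor")
  y_na <- toy$y; y_na[5] <- NA
  expect_error(fit_node(y_na, toy$x), "missing values")
})

test_that("estimate_clpn assembles the coefficient and OR matrices", {
  coh <- simulate_cohort(clpn_sim_spec(n = 400, seed = 23, mcar_rate = 0))
  net <- estimate_clpn(coh$data, fast_settings())
  expect_s3_class(net, "clpn")
  expect_equal(dim(net$coeff), c(11, 11))
  expect_equal(net$or_matrix, exp(net$coeff), tolerance = 1e-12)
  expect_equal(rownames(net$coeff), clpnet:::node_codes())
  # autoregressive diagonal present and positive under the default truth
  expect_true(all(diag(net$coeff) > 0))

  withmiss <- simulate_cohort(clpn_sim_spec(n = 100, seed = 2))
  expect_error(estimate_clpn(withmiss$data, fast_settings()),
               "listwise_complete")
})

test_that("estimation on a null cohort returns a sparse network", {
  coh <- simulate_cohort(null_sim_spec(n = 426, seed = 2))
  # CV-minimum rule: mostly empty (calibrated floor over null replicates)
  net <- estimate_clpn(coh$data, fast_settings())
  off <- row(net$coeff) != col(net$coeff)
  expect_gte(mean(net$coeff[off] == 0), 0.7)
  # the conservative 1-SE rule prunes the null network completely
  net1se <- estimate_clpn(coh$data, fast_settings(lambda_rule = "1se"))
  expect_true(all(net1se$coeff[row(net1se$coeff) != col(net1se$coeff)] == 0))
})

test_that("odds-ratio conversion is the exact elementwise exponential", {
  expect_identical(to_odds_ratios(0), 1)
  expect_equal(to_odds_ratios(log(1.332)), 1.332)
  m <- matrix(rnorm(9, sd = 0.3), 3, 3)
  expect_lt(max(abs(log(to_odds_ratios(m)) - m)), 1e-12)
})

test_that("strip_autoregressive zeroes the diagonal and is idempotent", {
  fx <- fixture_network()
  expect_identical(strip_autoregressive(fx)$coeff, fx$coeff)  # diagonal already 1.000
  m <- diag(0.5, 4); m[1, 2] <- 0.3
  net <- clpn_network(m)
  s1 <- strip_autoregressive(net)
  expect_identical(unname(diag(s1$coeff)), rep(0, 4))
  expect_equal(s1$coeff[1, 2], 0.3)
  expect_identical(strip_autoregressive(s1)$coeff, s1$coeff)
})

test_that("edge_census counts signed nonzero cross-lagged edges", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.2; m[2, 1] <- 0.1; m[3, 4] <- -0.3; m[4, 3] <- -0.05
  cen <- edge_census(clpn_network(m))
  expect_equal(cen$n_nonzero_cross, 4)
  expect_equal(cen$n_positive, 2)
  expect_equal(cen$positive_share, 0.5)

  cen0 <- edge_census(clpn_network(matrix(0, 3, 3)))
  expect_equal(cen0$n_nonzero_cross, 0)
  expect_true(is.na(cen0$positive_share))
  expect_true(is.na(cen0$mean_or_cross))
})

test_that("the logistic mode fits dichotomized outcomes", {
  coh <- simulate_cohort(clpn_sim_spec(n = 400, seed = 29, mcar_rate = 0))
  bin <- dichotomize_wave2(coh$data)
  net <- estimate_clpn(bin, clpn_settings(family = "binomial",
                                          use_covariates = FALSE))
  expect_true(all(is.finite(net$coeff)))
  expect_equal(net$or_matrix, exp(net$coeff), tolerance = 1e-12)
  # the strong planted paths keep their sign under dichotomization
  expect_gte(net$coeff["D2", "D1"], 0)
})
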