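test_that("the default generating spec encodes the calibrated conditions", {
  spec <- clpn_sim_spec()
  expect_equal(unname(spec$t1_means["D1"]), 3.30)
  expect_equal(unname(spec$t1_sds["D1"]), 2.13)
  expect_true(all(diag(spec$cross_matrix) == 0))
  expect_equal(spec$mcar_rate, 0.0467)
  expect_equal(sum(spec$stage_mix), 1)
  # autoregressive paths dominate the cross-lagged ones on average
  nz <- spec$cross_matrix[spec$cross_matrix != 0]
  expect_gt(mean(abs(spec$auto_coeffs)), mean(abs(nz)))
})

test_that("spec validation rejects impossible configurations", {
  expect_error(clpn_sim_spec(mcar_rate = 1.2), "mcar_rate")
  expect_error(clpn_sim_spec(stage_mix = c(I = 1, II = 1, III = 0, IV = 0)),
               "sum to 1")
  bad <- zero_cross(); diag(bad) <- 0.5
  expect_error(clpn_sim_spec(cross_matrix = bad), "diagonal")
  expect_error(clpn_sim_spec(within_construct_corr = -0.95,
                             between_construct_corr = 0.9),
               "positive definite")
})

test_that("generation is deterministic given the spec seed", {
  a <- simulate_cohort(clpn_sim_spec(n = 80, seed = 42))
  b <- simulate_cohort(clpn_sim_spec(n = 80, seed = 42))
  expect_identical(a$data$values, b$data$values)
  expect_identical(as.character(a$data$stage), as.character(b$data$stage))
  c <- simulate_cohort(clpn_sim_spec(n = 80, seed = 43))
  expect_false(identical(a$data$values, c$data$values))
})

test_that("a zero-coefficient spec yields no wave-1 to wave-2 association", {
  coh <- simulate_cohort(null_sim_spec(n = 10000, seed = 1))
  r <- cor(clpnet:::t1_matrix(coh$data), clpnet:::t2_matrix(coh$data))
  expect_lt(max(abs(r)), 0.05)
})

test_that("wave-1 moments match the truncated-normal closed form", {
  spec <- clpn_sim_spec(n = 10000, seed = 5)
  coh <- simulate_cohort(spec)
  t1 <- clpnet:::t1_matrix(coh$data)
  mu <- spec$t1_means; sg <- spec$t1_sds
  z <- mu / sg
  # E[max(N(mu, sg), 0)] and its implied Monte-Carlo band
  m_clip <- mu * pnorm(z) + sg * dnorm(z)
  for (j in seq_len(11)) {
    se <- sg[j] / sqrt(10000)
    expect_lt(abs(mean(t1[, j]) - m_clip[j]), 4 * se)
  }
  # headline calibration: D1 wave-1 mean lands within 0.1 of 3.30
  expect_lt(abs(mean(t1[, "D1_T1"]) - 3.30), 0.1)
})

test_that("an ordinary least-squares oracle recovers planted coefficients", {
  coh <- simulate_cohort(clpn_sim_spec(n = 10000, seed = 11, mcar_rate = 0))
  Z1 <- scale(clpnet:::t1_matrix(coh$data))
  colnames(Z1) <- clpnet:::node_codes()
  z_f3 <- as.numeric(scale(coh$data$values[, "F3_T2"]))
  b <- coef(lm(z_f3 ~ Z1))
  expect_lt(abs(b[["Z1D3"]] - coh$truth$coeff["D3", "F3"]), 0.05)
  z_f2 <- as.numeric(scale(coh$data$values[, "F2_T2"]))
  b2 <- coef(lm(z_f2 ~ Z1))
  expect_lt(abs(b2[["Z1D1"]] - coh$truth$coeff["D1", "F2"]), 0.05)
})

test_that("wave-2 dropout is whole-wave and near the specified rate", {
  coh <- simulate_cohort(clpn_sim_spec(n = 20000, seed = 13))
  m <- coh$data$mask
  t1_cols <- paste0(clpnet:::node_codes(), "_T1")
  expect_false(any(m[, t1_cols]))
  dropped <- rowSums(m[, paste0(clpnet:::node_codes(), "_T2")])
  expect_true(all(dropped %in% c(0, 11)))
  expect_lt(abs(mean(dropped > 0) - 0.0467), 0.006)
})

test_that("stage stratification swaps the cross-lagged structure for
           advanced-stage subjects only", {
  # stage_shift equal to the base matrix reproduces the homogeneous cohort
  spec0 <- clpn_sim_spec(n = 300, seed = 17,
                         stage_shift = default_cross_matrix())
  hom <- simulate_cohort(clpn_sim_spec(n = 300, seed = 17))
  strat <- simulate_stage_stratified(spec0)
  expect_identical(strat$data$values, hom$data$values)

  # a planted advanced-only edge is recovered per subgroup by OLS
  shift <- default_cross_matrix()
  shift["D2", "F7"] <- 0.5
  spec_s <- clpn_sim_spec(n = 12000, seed = 19, mcar_rate = 0,
                          stage_shift = shift)
  coh <- simulate_stage_stratified(spec_s)
  split <- split_by_stage(coh$data)
  est <- vapply(split, function(d) {
    Z1 <- scale(clpnet:::t1_matrix(d))
    colnames(Z1) <- clpnet:::node_codes()
    # outcome on the generation scale (spec mean/SD), so the planted
    # standardized coefficient is the regression target
    zf7 <- (d$values[, "F7_T2"] - spec_s$t2_means["F7"]) / spec_s$t2_sds["F7"]
    coef(lm(zf7 ~ Z1))[["Z1D2"]]
  }, numeric(1))
  expect_lt(abs(est[["early"]] - 0), 0.06)
  expect_lt(abs(est[["advanced"]] - 0.5), 0.06)

  expect_error(simulate_stage_stratified(clpn_sim_spec(n = 100)),
               "stage_shift")
})

test_that("the stage mix reproduces the cohort's early/advanced split", {
  share <- vapply(1:50, function(s) {
    coh <- simulate_cohort(clpn_sim_spec(n = 426, seed = 100 + s))
    mean(coh$data$stage %in% c("I", "II"))
  }, numeric(1))
  expect_lt(abs(mean(share) - (44 + 173) / 426), 0.01)
})
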