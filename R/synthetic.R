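# Calibration constants: subscale-level summary statistics and cohort
# composition of the reference two-wave breast-cancer cohort (n = 426,
# discharge and three months post-discharge).
ref_t1_means <- function() c(D1 = 3.30, D2 = 2.23, D3 = 1.41, D4 = 1.98,
                             F1 = 14.67, F2 = 17.40, F3 = 7.05, F4 = 13.58,
                             F5 = 5.84, F6 = 8.58, F7 = 17.31)
ref_t1_sds <- function() c(D1 = 2.13, D2 = 1.45, D3 = 0.82, D4 = 1.18,
                           F1 = 6.66, F2 = 5.34, F3 = 2.95, F4 = 4.53,
                           F5 = 2.46, F6 = 3.20, F7 = 7.20)
ref_t2_means <- function() c(D1 = 2.58, D2 = 2.07, D3 = 0.73, D4 = 1.19,
                             F1 = 13.13, F2 = 15.37, F3 = 5.23, F4 = 8.93,
                             F5 = 9.11, F6 = 7.24, F7 = 15.53)
ref_t2_sds <- function() c(D1 = 1.74, D2 = 1.59, D3 = 0.75, D4 = 1.23,
                           F1 = 5.76, F2 = 4.68, F3 = 2.28, F4 = 5.41,
                           F5 = 4.68, F6 = 3.07, F7 = 9.18)
ref_stage_mix <- function() c(I = 44, II = 173, III = 168, IV = 41) / 426

#' Default ground-truth cross-lagged coefficient matrix
#'
#' Sparse standardized cross-lagged structure qualitatively mirroring the
#' reference cohort's estimated network: strong positive paths out of the
#' death-anxiety cognition and time-awareness nodes (D2->D1, D3->D4,
#' D3->F3, D1->F2/F4/F7, D4->F1), weak positive within-FCR paths
#' (F2->F1, F1->F6), and weak negative paths out of coping strategies
#' (F7). Rows are wave-1 predictors, columns wave-2 outcomes; the diagonal
#' (autoregressive paths) is zero by construction.
#'
#' @return 11 x 11 numeric matrix with node-code dimnames.
#' @export
default_cross_matrix <- function() {
  codes <- node_codes()
  m <- matrix(0, 11, 11, dimnames = list(codes, codes))
  m["D2", "D1"] <- 0.29
  m["D3", "D4"] <- 0.20
  m["D3", "F3"] <- 0.31
  m["D1", "F2"] <- 0.24
  m["D1", "F4"] <- 0.26
  m["D1", "F7"] <- 0.23
  m["D4", "F1"] <- 0.20
  m["F2", "F1"] <- 0.06
  m["F1", "F6"] <- 0.03
  m["F7", c("F1", "F2", "F3", "F4", "F5")] <- c(-0.07, -0.06, -0.07, -0.08, -0.06)
  m
}

#' Specification of a synthetic two-wave cohort
#'
#' Defines the generating model for [simulate_cohort()]: wave-1 subscales
#' are block-correlated Gaussians calibrated to the reference cohort's
#' means/SDs (truncated at 0), and standardized wave-2 scores follow a
#' linear autoregressive + cross-lagged model with Gaussian residuals.
#' Wave-2 dropout is missing completely at random at the subject level.
#'
#' @param n number of subjects.
#' @param t1_means,t1_sds,t2_means,t2_sds 11-vectors of subscale means/SDs
#'   per wave; defaults are the reference cohort's values.
#' @param within_construct_corr,between_construct_corr wave-1 latent
#'   correlations within the DA and FCR blocks and between them.
#' @param auto_coeffs 11-vector of standardized autoregressive coefficients.
#' @param cross_matrix 11 x 11 standardized cross-lagged coefficient matrix
#'   (rows predictors, columns outcomes, zero diagonal).
#' @param covariate_effects optional named list `covariate -> 11-vector`
#'   of standardized effects on the wave-2 outcomes (only `age` supported).
#' @param noise_sd residual SDs on the standardized scale; `NULL` sets
#'   each outcome's residual so its standardized variance is 1.
#' @param mcar_rate per-subject probability of losing the whole second wave.
#' @param stage_mix probabilities over stages I--IV.
#' @param stage_shift optional replacement `cross_matrix` used for
#'   advanced-stage (III/IV) subjects.
#' @param seed integer seed making generation deterministic.
#' @return An object of class `clpn_sim_spec`.
#' @export
clpn_sim_spec <- function(n = 426,
                          t1_means = ref_t1_means(), t1_sds = ref_t1_sds(),
                          t2_means = ref_t2_means(), t2_sds = ref_t2_sds(),
                          within_construct_corr = 0.4,
                          between_construct_corr = 0.2,
                          auto_coeffs = rep(0.45, 11),
                          cross_matrix = default_cross_matrix(),
                          covariate_effects = NULL,
                          noise_sd = NULL,
                          mcar_rate = 0.0467,
                          stage_mix = ref_stage_mix(),
                          stage_shift = NULL,
                          seed = 1) {
  stopifnot(length(t1_means) == 11, length(t1_sds) == 11,
            length(t2_means) == 11, length(t2_sds) == 11,
            length(auto_coeffs) == 11)
  cross_matrix <- as.matrix(cross_matrix)
  if (!all(dim(cross_matrix) == c(11, 11))) stop("`cross_matrix` must be 11 x 11")
  if (any(diag(cross_matrix) != 0)) stop("`cross_matrix` diagonal must be zero")
  if (!is.null(stage_shift)) {
    stage_shift <- as.matrix(stage_shift)
    if (!all(dim(stage_shift) == c(11, 11))) stop("`stage_shift` must be 11 x 11")
    if (any(diag(stage_shift) != 0)) stop("`stage_shift` diagonal must be zero")
  }
  if (mcar_rate < 0 || mcar_rate >= 1) stop("`mcar_rate` must be in [0, 1)")
  if (abs(sum(stage_mix) - 1) > 1e-8) stop("`stage_mix` must sum to 1")
  R <- t1_correlation(within_construct_corr, between_construct_corr)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("implied wave-1 correlation matrix is not positive definite")
  structure(
    list(n = n, t1_means = t1_means, t1_sds = t1_sds,
         t2_means = t2_means, t2_sds = t2_sds,
         within_construct_corr = within_construct_corr,
         between_construct_corr = between_construct_corr,
         auto_coeffs = auto_coeffs, cross_matrix = cross_matrix,
         covariate_effects = covariate_effects, noise_sd = noise_sd,
         mcar_rate = mcar_rate, stage_mix = stage_mix,
         stage_shift = stage_shift, seed = seed),
    class = "clpn_sim_spec"
  )
}

# Block-exchangeable wave-1 correlation: rho_w within DA and within FCR,
# rho_b across constructs.
t1_correlation <- function(rho_w, rho_b) {
  part <- node_partition()
  same <- outer(part, part, "==")
  R <- ifelse(same, rho_w, rho_b)
  diag(R) <- 1
  dimnames(R) <- list(names(part), names(part))
  R
}

# Full 11x11 coefficient matrix (autoregressive diagonal + cross paths).
truth_matrix <- function(auto, cross) {
  B <- cross
  diag(B) <- auto
  B
}

#' Generate a synthetic two-wave cohort with known ground truth
#'
#' Wave 1 is multivariate normal with the spec's block-exchangeable
#' correlation, rescaled to the target means/SDs and truncated at zero
#' (scores are non-negative item sums). Standardized wave-2 outcomes are
#' `z(T2_j) = auto_j z(T1_j) + sum_i cross[i,j] z(T1_i) + covariate terms
#' + noise`, rescaled to the wave-2 means/SDs and truncated at zero. When
#' `stage_shift` is given, advanced-stage (III/IV) subjects are generated
#' from it instead of `cross_matrix`. Generation is deterministic given
#' `spec$seed` and leaves the caller's RNG untouched.
#'
#' @param spec a [clpn_sim_spec()].
#' @return An object of class `clpn_cohort`: list with elements `data`
#'   (a [panel_dataset()]) and `truth` (list with the full standardized
#'   coefficient matrix `coeff`, and `coeff_advanced` when stage-shifted).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "clpn_sim_spec"))
  with_preserved_seed(spec$seed, {
    n <- spec$n
    codes <- node_codes()
    R <- t1_correlation(spec$within_construct_corr, spec$between_construct_corr)
    Z1 <- mvrnorm(n, mu = rep(0, 11), Sigma = R)
    T1 <- pmax(sweep(sweep(Z1, 2, spec$t1_sds, "*"), 2, spec$t1_means, "+"), 0)
    colnames(T1) <- paste0(codes, "_T1")
    # standardize the realized (truncated) wave-1 scores: the linear model
    # for wave 2 is defined on this scale
    Zt <- scale(T1)

    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = spec$stage_mix)
    covariates <- draw_covariates(n)

    B_early <- truth_matrix(spec$auto_coeffs, spec$cross_matrix)
    B_adv <- if (is.null(spec$stage_shift)) B_early else
      truth_matrix(spec$auto_coeffs, spec$stage_shift)
    adv <- stage %in% c("III", "IV")
    eta <- matrix(0, n, 11)
    eta[!adv, ] <- Zt[!adv, , drop = FALSE] %*% B_early
    if (any(adv)) eta[adv, ] <- Zt[adv, , drop = FALSE] %*% B_adv

    if (!is.null(spec$covariate_effects)) {
      for (cv in names(spec$covariate_effects)) {
        if (cv != "age") stop("only `age` covariate effects are supported")
        zage <- as.numeric(scale(covariates$age))
        eta <- eta + outer(zage, spec$covariate_effects[[cv]])
      }
    }

    noise_sd <- spec$noise_sd
    if (is.null(noise_sd)) {
      # residual SD making each standardized outcome's variance ~ 1
      noise_sd <- vapply(seq_len(11), function(j) {
        v <- drop(crossprod(B_early[, j], R %*% B_early[, j]))
        sqrt(max(1 - v, 0.1))
      }, numeric(1))
    }
    eta <- eta + sweep(matrix(rnorm(n * 11), n, 11), 2, noise_sd, "*")
    T2 <- pmax(sweep(sweep(eta, 2, spec$t2_sds, "*"), 2, spec$t2_means, "+"), 0)
    colnames(T2) <- paste0(codes, "_T2")

    if (spec$mcar_rate > 0) {
      drop2 <- runif(n) < spec$mcar_rate
      T2[drop2, ] <- NA
    }

    data <- panel_dataset(cbind(T1, T2), stage = stage, covariates = covariates)
    truth <- list(coeff = B_early,
                  coeff_advanced = if (is.null(spec$stage_shift)) NULL else B_adv,
                  noise_sd = noise_sd)
    structure(list(data = data, truth = truth, spec = spec),
              class = "clpn_cohort")
  })
}

#' Generate a stage-stratified cohort with differing subgroup structure
#'
#' Thin wrapper over [simulate_cohort()] that requires a `stage_shift`
#' cross-lagged matrix: early-stage (I/II) subjects follow
#' `spec$cross_matrix`, advanced-stage (III/IV) subjects follow
#' `spec$stage_shift`.
#'
#' @param spec a [clpn_sim_spec()] with non-`NULL` `stage_shift`.
#' @return A `clpn_cohort`; see [simulate_cohort()].
#' @export
simulate_stage_stratified <- function(spec) {
  if (is.null(spec$stage_shift)) {
    stop("`spec$stage_shift` must be provided for stage-stratified generation")
  }
  simulate_cohort(spec)
}

# Covariates drawn to match the reference cohort's composition: age
# truncated-normal(47.30, 11.27) on [18, 90]; categorical covariates
# multinomial with the cohort's observed proportions.
draw_covariates <- function(n) {
  lo <- pnorm((18 - 47.30) / 11.27)
  hi <- pnorm((90 - 47.30) / 11.27)
  age <- 47.30 + 11.27 * qnorm(runif(n, lo, hi))
  data.frame(
    age = age,
    education = factor(sample(c("junior_or_less", "high_school", "bachelor_plus"),
                              n, TRUE, prob = c(218, 140, 68) / 426)),
    marital = factor(sample(c("married", "other"), n, TRUE,
                            prob = c(382, 44) / 426)),
    occupation = factor(sample(c("in_service", "none", "retired"), n, TRUE,
                               prob = c(350, 34, 42) / 426)),
    income = factor(sample(c("low", "middle", "high"), n, TRUE,
                           prob = c(134, 141, 151) / 426))
  )
}

#' @export
print.clpn_cohort <- function(x, ...) {
  cat("Synthetic two-wave cohort:", n_subjects(x$data), "subjects\n")
  nz <- sum(x$truth$coeff != 0) - sum(diag(x$truth$coeff) != 0)
  cat("  ground truth: ", nz, " nonzero cross-lagged paths, ",
      if (is.null(x$truth$coeff_advanced)) "homogeneous" else "stage-stratified",
      "\n", sep = "")
  invisible(x)
}
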