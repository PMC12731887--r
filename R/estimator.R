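#' Estimation settings for cross-lagged panel networks
#'
#' @param family `"gaussian"` (default) fits linear LASSO regressions on
#'   standardized continuous outcomes; `"binomial"` fits logistic LASSO
#'   regressions (outcomes must be 0/1, e.g. via [dichotomize_wave2()]).
#' @param lambda penalty control: `NULL` selects lambda per node by
#'   K-fold cross-validation; a scalar (or 11-vector, one per node) forces
#'   that penalty; `Inf` forces the empty lagged model; `0` gives the
#'   unpenalized fit.
#' @param nfolds number of cross-validation folds.
#' @param lambda_rule `"min"` (CV-minimum, default) or `"1se"`.
#' @param use_covariates include the dataset's covariates, unpenalized.
#' @param zero_tol coefficients below this magnitude are treated as
#'   structural zeros by census/centrality code.
#' @param seed seed for the cross-validation fold assignment.
#' @return An object of class `clpn_settings`.
#' @export
clpn_settings <- function(family = c("gaussian", "binomial"), lambda = NULL,
                          nfolds = 10, lambda_rule = c("min", "1se"),
                          use_covariates = TRUE, zero_tol = 1e-9, seed = 1) {
  structure(
    list(family = match.arg(family), lambda = lambda, nfolds = nfolds,
         lambda_rule = match.arg(lambda_rule), use_covariates = use_covariates,
         zero_tol = zero_tol, seed = seed),
    class = "clpn_settings"
  )
}

#' Fit one node-wise penalized regression
#'
#' Regresses a wave-2 outcome on all standardized wave-1 predictors (L1
#' penalized) plus optional unpenalized covariates. In the Gaussian mode
#' the outcome is standardized too, so lagged coefficients are standardized
#' effects comparable across nodes.
#'
#' @param y wave-2 outcome vector.
#' @param x matrix of wave-1 predictors (columns named by node code).
#' @param covariates optional covariate data frame (expanded via
#'   `model.matrix`, never penalized).
#' @param settings a [clpn_settings()].
#' @return List with `coefficients` (named lagged coefficients on the
#'   standardized scale), `covariate_coefficients`, `intercept`, `lambda`.
#' @export
fit_node <- function(y, x, covariates = NULL, settings = clpn_settings()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("`y` and `x` disagree on the number of subjects")
  if (n < 30) stop("insufficient data: need at least 30 subjects, got ", n)
  if (anyNA(y) || anyNA(x)) stop("missing values: apply listwise_complete() upstream")
  if (sd(y) == 0) stop("degenerate outcome: constant across subjects")
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  xsd <- sqrt(colSums(xc^2) / (n - 1))
  if (any(xsd == 0)) {
    stop("constant predictor(s): ", paste(colnames(x)[xsd == 0], collapse = ", "))
  }
  xs <- sweep(xc, 2, xsd, "/")
  p <- ncol(xs)

  family <- settings$family
  if (family == "gaussian") {
    ys <- as.numeric(scale(y))
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial mode needs a 0/1 outcome")
    ys <- y
  }

  X <- xs
  pf <- rep(1, p)
  cov_names <- NULL
  if (!is.null(covariates) && isTRUE(settings$use_covariates) && ncol(covariates) > 0) {
    mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    num <- vapply(seq_len(ncol(mm)), function(j) length(unique(mm[, j])) > 2, logical(1))
    mm[, num] <- scale(mm[, num, drop = FALSE])
    X <- cbind(xs, mm)
    pf <- c(pf, rep(0, ncol(mm)))
    cov_names <- colnames(mm)
  }

  lam <- settings$lambda
  if (is.null(lam)) {
    foldid <- with_preserved_seed(settings$seed,
                                  sample(rep(seq_len(settings$nfolds), length.out = n)))
    cvfit <- cv.glmnet(X, ys, family = family, foldid = foldid,
                       penalty.factor = pf, standardize = FALSE)
    lam <- if (settings$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    b <- as.numeric(coef(cvfit, s = lam))
  } else if (is.infinite(lam)) {
    # exact penalty limit: lagged coefficients vanish, covariates stay free
    b <- numeric(1 + ncol(X))
    if (!is.null(cov_names)) {
      mm <- X[, -seq_len(p), drop = FALSE]
      ols <- lm(ys ~ mm)
      b[1] <- coef(ols)[1]
      b[1 + p + seq_along(cov_names)] <- coef(ols)[-1]
    } else if (family == "gaussian") {
      b[1] <- 0
    } else {
      b[1] <- qlogis_safe(mean(ys))
    }
  } else if (lam > 0) {
    # short warm-start path down to the requested penalty
    fit <- glmnet(X, ys, family = family, penalty.factor = pf,
                  standardize = FALSE, thresh = 1e-12,
                  lambda = lam * c(64, 16, 4, 1))
    k <- length(fit$lambda)   # requested penalty is the path's last knot
    b <- c(fit$a0[k], as.vector(fit$beta[, k]))
  } else {
    fit <- glmnet(X, ys, family = family, penalty.factor = pf,
                  standardize = FALSE, thresh = 1e-12)
    b <- as.numeric(coef(fit, s = lam, exact = TRUE, x = X, y = ys,
                         family = family, penalty.factor = pf,
                         standardize = FALSE, thresh = 1e-12))
  }

  lagged <- setNames(b[1 + seq_len(p)], colnames(x))
  covb <- if (is.null(cov_names)) NULL else setNames(b[1 + p + seq_along(cov_names)], cov_names)
  list(coefficients = lagged, covariate_coefficients = covb,
       intercept = b[1], lambda = lam, family = family)
}

qlogis_safe <- function(p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

#' Estimate the directed T1 -> T2 cross-lagged panel network
#'
#' Runs one penalized regression per wave-2 node on all eleven wave-1
#' subscales (plus unpenalized covariates) and assembles the coefficient
#' and odds-ratio matrices. Row i, column j holds the standardized effect
#' of node i at wave 1 on node j at wave 2; the diagonal carries the
#' autoregressive paths.
#'
#' @param data a complete-case [panel_dataset()] (see [listwise_complete()]).
#' @param settings a [clpn_settings()].
#' @return An object of class `clpn`: list with `nodes`, `coeff`,
#'   `or_matrix = exp(coeff)`, `lambda_per_node`, `covariate_coeffs`, `meta`.
#' @export
estimate_clpn <- function(data, settings = clpn_settings()) {
  stopifnot(inherits(data, "panel_dataset"))
  if (any(data$mask)) {
    stop("dataset contains missing analysis values; apply listwise_complete() first")
  }
  X <- t1_matrix(data)
  colnames(X) <- node_codes()
  T2 <- t2_matrix(data)
  codes <- node_codes()
  coeff <- matrix(0, 11, 11, dimnames = list(codes, codes))
  lambdas <- setNames(numeric(11), codes)
  covb <- NULL
  lam_spec <- settings$lambda
  for (j in seq_len(11)) {
    s <- settings
    if (!is.null(lam_spec) && length(lam_spec) == 11) s$lambda <- lam_spec[j]
    fit <- tryCatch(
      fit_node(T2[, j], X, covariates = data$covariates, settings = s),
      error = function(e) stop("node ", codes[j], ": ", conditionMessage(e),
                               call. = FALSE)
    )
    coeff[, j] <- fit$coefficients
    lambdas[j] <- fit$lambda
    if (!is.null(fit$covariate_coefficients)) {
      if (is.null(covb)) {
        covb <- matrix(0, length(fit$covariate_coefficients), 11,
                       dimnames = list(names(fit$covariate_coefficients), codes))
      }
      covb[, j] <- fit$covariate_coefficients
    }
  }
  clpn_network(coeff, lambda_per_node = lambdas, covariate_coeffs = covb,
               meta = list(settings = settings, n = n_subjects(data),
                           family = settings$family, estimated = TRUE))
}

#' Construct a network object from a coefficient matrix
#'
#' @param coeff square coefficient (log-OR scale) matrix, rows predictors.
#' @param nodes node table (`code`, `name`, `construct`); defaults to
#'   [clpn_nodes()] for 11 x 11 input, otherwise inferred from dimnames
#'   with a single pseudo-construct.
#' @param lambda_per_node,covariate_coeffs,meta optional estimation records.
#' @return An object of class `clpn`.
#' @export
clpn_network <- function(coeff, nodes = NULL, lambda_per_node = NULL,
                         covariate_coeffs = NULL, meta = list()) {
  coeff <- as.matrix(coeff)
  if (nrow(coeff) != ncol(coeff)) stop("`coeff` must be square")
  if (is.null(nodes)) {
    if (nrow(coeff) == 11) {
      nodes <- clpn_nodes()
    } else {
      cds <- rownames(coeff)
      if (is.null(cds)) cds <- paste0("V", seq_len(nrow(coeff)))
      nodes <- data.frame(code = cds, name = cds, construct = "all",
                          stringsAsFactors = FALSE)
    }
  }
  if (nrow(nodes) != nrow(coeff)) stop("`nodes` and `coeff` disagree on size")
  dimnames(coeff) <- list(nodes$code, nodes$code)
  structure(
    list(nodes = nodes, coeff = coeff, or_matrix = exp(coeff),
         lambda_per_node = lambda_per_node, covariate_coeffs = covariate_coeffs,
         meta = meta),
    class = "clpn"
  )
}

#' Wrap a printed odds-ratio adjacency matrix as a network
#'
#' Entries equal to 1 are absent edges (zero coefficients); the coefficient
#' matrix is the elementwise log of the OR matrix.
#'
#' @param or_matrix square OR matrix, predictors in rows.
#' @param nodes optional node table; defaults as in [clpn_network()].
#' @return An object of class `clpn`.
#' @export
clpn_from_or <- function(or_matrix, nodes = NULL) {
  or_matrix <- as.matrix(or_matrix)
  if (any(or_matrix <= 0)) stop("odds ratios must be positive")
  clpn_network(log(or_matrix), nodes = nodes, meta = list(estimated = FALSE))
}

#' Exponentiate coefficients into odds ratios
#'
#' Elementwise `exp`; a zero coefficient maps to an OR of exactly 1.
#'
#' @param coeff coefficient matrix (or vector).
#' @return Matrix (or vector) of odds ratios.
#' @export
to_odds_ratios <- function(coeff) exp(coeff)

#' Remove autoregressive paths for display and centrality
#'
#' Returns a copy of the network with the diagonal coefficients set to 0
#' (odds ratio 1); cross-lagged entries are untouched. Idempotent.
#'
#' @param net a `clpn` network.
#' @return A `clpn` network without autoregressive edges.
#' @export
strip_autoregressive <- function(net) {
  stopifnot(inherits(net, "clpn"))
  coeff <- net$coeff
  diag(coeff) <- 0
  out <- net
  out$coeff <- coeff
  out$or_matrix <- exp(coeff)
  out
}

#' Census of the network's edges
#'
#' Counts and summarizes the retained (nonzero) cross-lagged edges and the
#' autoregressive paths. A coefficient within `zero_tol` of 0 counts as an
#' absent edge, so fixture matrices printed to 3 decimals behave exactly.
#'
#' @param net a `clpn` network.
#' @param zero_tol structural-zero tolerance on the coefficient scale.
#' @return List: `n_nonzero_cross`, `n_positive`, `positive_share`,
#'   `mean_or_cross`, `mean_or_auto` (share/means are `NA` when the
#'   corresponding edge set is empty).
#' @export
edge_census <- function(net, zero_tol = 1e-9) {
  stopifnot(inherits(net, "clpn"))
  co <- net$coeff
  off <- row(co) != col(co)
  nz <- abs(co) > zero_tol
  cross <- off & nz
  auto <- !off & nz
  n_cross <- sum(cross)
  n_pos <- sum(cross & co > 0)
  list(
    n_nonzero_cross = n_cross,
    n_positive = n_pos,
    positive_share = if (n_cross > 0) n_pos / n_cross else NA_real_,
    mean_or_cross = if (n_cross > 0) mean(net$or_matrix[cross]) else NA_real_,
    mean_or_auto = if (any(auto)) mean(net$or_matrix[auto]) else NA_real_
  )
}

#' @export
print.clpn <- function(x, ...) {
  cen <- edge_census(x)
  cat("Cross-lagged panel network over", nrow(x$coeff), "nodes\n")
  cat("  nonzero cross-lagged edges:", cen$n_nonzero_cross,
      sprintf("(%d positive)", cen$n_positive), "\n")
  if (!is.null(x$meta$n)) cat("  estimated from n =", x$meta$n, "subjects\n")
  invisible(x)
}
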