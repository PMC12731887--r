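# Centrality vector straight from a coefficient matrix (fast path for
# bootstrap replicates; avoids building a full network object per slice).
centrality_from_coeff <- function(coeff, index, construct,
                                  scale = c("coeff", "or_minus_1")) {
  scale <- match.arg(scale)
  W <- if (scale == "coeff") coeff else exp(coeff) - 1
  diag(W) <- 0
  switch(index,
    oei = rowSums(W),
    iei = colSums(W),
    bridge_oei = ,
    bridge = {
      W[!outer(construct, construct, "!=")] <- 0
      rowSums(W)
    },
    bridge_iei = {
      W[!outer(construct, construct, "!=")] <- 0
      colSums(W)
    },
    stop("unknown centrality index: ", index)
  )
}

# Per-node lambda vector of a fitted network, used to freeze the penalty
# across resamples/subsamples when refitting the selection is too costly.
frozen_lambda_settings <- function(settings, net) {
  settings$lambda <- unname(net$lambda_per_node)
  settings
}

#' Nonparametric bootstrap of the network's edge weights
#'
#' Resamples subjects with replacement, re-estimates the full network per
#' resample, and reports percentile 95% confidence intervals per edge on
#' the coefficient scale. The replicate coefficient array is kept so that
#' edge and centrality difference tests can reuse the same resamples.
#'
#' @param data a complete-case [panel_dataset()].
#' @param settings a [clpn_settings()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed; resample b draws its own RNG substream from a
#'   seed table generated once from `seed`, so results are independent of
#'   execution order.
#' @param refit_lambda when `TRUE` (default) the penalty is re-selected by
#'   cross-validation inside every resample (full-pipeline bootstrap);
#'   `FALSE` freezes the full-sample per-node penalties for speed.
#' @param conf confidence level for the percentile intervals.
#' @return An object of class `clpn_boot`: `estimate` (full-sample coeff),
#'   `ci_low`, `ci_high`, `coeff_boot` (nodes x nodes x replicates),
#'   `n_boot`, `failures`, `seed`, `network` (full-sample fit).
#' @export
bootstrap_edges <- function(data, settings = clpn_settings(), n_boot = 1000,
                            seed = 1, refit_lambda = TRUE, conf = 0.95) {
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  full <- estimate_clpn(data, settings)
  boot_settings <- if (refit_lambda) settings else frozen_lambda_settings(settings, full)
  n <- n_subjects(data)
  seeds <- derive_seeds(seed, n_boot)
  codes <- node_codes()
  arr <- array(NA_real_, dim = c(11, 11, n_boot),
               dimnames = list(codes, codes, NULL))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_preserved_seed(seeds[b], sample.int(n, n, replace = TRUE))
    est <- tryCatch(estimate_clpn(subset_panel(data, idx), boot_settings),
                    error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else arr[, , b] <- est$coeff
  }
  if (failures > 0.1 * n_boot) {
    stop("bootstrap aborted: ", failures, " of ", n_boot, " resamples failed")
  }
  ok <- apply(arr, 3, function(m) !anyNA(m))
  arr <- arr[, , ok, drop = FALSE]
  alpha <- (1 - conf) / 2
  ci_low <- apply(arr, c(1, 2), quantile, probs = alpha)
  ci_high <- apply(arr, c(1, 2), quantile, probs = 1 - alpha)
  structure(
    list(estimate = full$coeff, ci_low = ci_low, ci_high = ci_high,
         coeff_boot = arr, n_boot = n_boot, failures = failures,
         conf = conf, seed = seed, network = full, settings = settings),
    class = "clpn_boot"
  )
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat("Bootstrap summary:", dim(x$coeff_boot)[3], "successful resamples",
      sprintf("(%d failed)\n", x$failures))
  covered <- mean(x$ci_low <= x$estimate & x$estimate <= x$ci_high)
  cat(sprintf("  %.0f%% percentile CIs; %.1f%% of edges have estimate inside CI\n",
              100 * x$conf, 100 * covered))
  invisible(x)
}

#' Case-dropping correlation-stability (CS) coefficient
#'
#' For each drop proportion p in `props`, draws `n_sub` subsamples keeping
#' (1-p) of the subjects, re-estimates the network, and correlates the
#' subsample centrality with the full-sample centrality across nodes. The
#' CS coefficient is the largest p at which at least `conf` of the
#' correlations reach `cor_threshold` (0 if none). Values above 0.25 are
#' conventionally acceptable, above 0.50 highly robust.
#'
#' @param data a complete-case [panel_dataset()].
#' @param settings a [clpn_settings()].
#' @param index `"oei"`, `"iei"`, `"bridge"` (= bridge-OEI) or
#'   `"bridge_iei"`.
#' @param n_sub subsamples per drop proportion.
#' @param seed integer seed (substreamed per subsample).
#' @param props grid of drop proportions.
#' @param cor_threshold,conf correlation threshold and required fraction.
#' @param scale centrality scale, see [expected_influence()].
#' @param refit_lambda re-select the penalty inside every subsample
#'   (`TRUE`, default) or freeze the full-sample per-node penalties.
#' @param min_n smallest admissible subsample size; proportions dropping
#'   below it are marked infeasible and excluded.
#' @return The CS value, with attribute `table` (per-proportion fraction
#'   of correlations >= threshold) and `degenerate` flag when the
#'   full-sample centrality is constant (CS = 0).
#' @export
cs_coefficient <- function(data, settings = clpn_settings(), index = "oei",
                           n_sub = 250, seed = 1,
                           props = seq(0.05, 0.75, by = 0.05),
                           cor_threshold = 0.7, conf = 0.95,
                           scale = "coeff", refit_lambda = TRUE,
                           min_n = 30) {
  full <- estimate_clpn(data, settings)
  construct <- full$nodes$construct
  cent_full <- centrality_from_coeff(full$coeff, index, construct, scale)
  if (sd(cent_full) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    attr(out, "table") <- NULL
    return(out)
  }
  sub_settings <- if (refit_lambda) settings else frozen_lambda_settings(settings, full)
  n <- n_subjects(data)
  seeds <- derive_seeds(seed, length(props) * n_sub)
  ok_frac <- setNames(rep(NA_real_, length(props)), props)
  for (i in seq_along(props)) {
    m <- round((1 - props[i]) * n)
    if (m < min_n) next  # infeasible at this proportion
    hits <- logical(n_sub)
    for (s in seq_len(n_sub)) {
      sd_i <- seeds[(i - 1) * n_sub + s]
      idx <- with_preserved_seed(sd_i, sample.int(n, m))
      est <- tryCatch(estimate_clpn(subset_panel(data, idx), sub_settings),
                      error = function(e) NULL)
      if (is.null(est)) next
      cent <- centrality_from_coeff(est$coeff, index, construct, scale)
      r <- suppressWarnings(cor(cent, cent_full))
      hits[s] <- is.finite(r) && r >= cor_threshold
    }
    ok_frac[i] <- mean(hits)
  }
  qualifying <- props[!is.na(ok_frac) & ok_frac >= conf]
  out <- if (length(qualifying) > 0) max(qualifying) else 0
  attr(out, "table") <- data.frame(drop_proportion = props, frac_stable = unname(ok_frac))
  attr(out, "degenerate") <- FALSE
  out
}

boot_edge_series <- function(boot, edge) {
  codes <- rownames(boot$estimate)
  i <- match(edge[1], codes); j <- match(edge[2], codes)
  if (is.na(i) || is.na(j)) stop("unknown node code in edge: ",
                                 paste(edge, collapse = " -> "))
  boot$coeff_boot[i, j, ]
}

#' Bootstrap difference test between two edge weights
#'
#' Percentile test on the bootstrap distribution of `w(edge_a) - w(edge_b)`
#' (coefficient scale): the difference is significant when the 95% CI
#' excludes 0. Comparing an edge with itself is flagged trivially
#' non-significant.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param edge_a,edge_b length-2 vectors `c(from, to)` of node codes.
#' @param conf confidence level.
#' @return List: `significant`, `ci`, `estimate`, `trivial`.
#' @export
edge_difference_test <- function(boot, edge_a, edge_b, conf = 0.95) {
  stopifnot(inherits(boot, "clpn_boot"))
  if (identical(unname(edge_a), unname(edge_b))) {
    return(list(significant = FALSE, ci = c(0, 0), estimate = 0, trivial = TRUE))
  }
  d <- boot_edge_series(boot, edge_a) - boot_edge_series(boot, edge_b)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(d, c(alpha, 1 - alpha)))
  codes <- rownames(boot$estimate)
  est <- boot$estimate[match(edge_a[1], codes), match(edge_a[2], codes)] -
    boot$estimate[match(edge_b[1], codes), match(edge_b[2], codes)]
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci, estimate = est,
       trivial = FALSE)
}

#' Bootstrap difference test between two nodes' centrality
#'
#' Percentile test on the bootstrap distribution of
#' `index(node_a) - index(node_b)`, recomputing the centrality index from
#' each bootstrap replicate's coefficient matrix.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param node_a,node_b node codes.
#' @param index `"oei"`, `"iei"`, `"bridge"` or `"bridge_iei"`.
#' @param scale centrality scale.
#' @param conf confidence level.
#' @return List: `significant`, `ci`, `estimate`, `trivial`.
#' @export
centrality_difference_test <- function(boot, node_a, node_b, index = "oei",
                                       scale = "coeff", conf = 0.95) {
  stopifnot(inherits(boot, "clpn_boot"))
  if (identical(node_a, node_b)) {
    return(list(significant = FALSE, ci = c(0, 0), estimate = 0, trivial = TRUE))
  }
  codes <- rownames(boot$estimate)
  ia <- match(node_a, codes); ib <- match(node_b, codes)
  if (is.na(ia) || is.na(ib)) stop("unknown node code")
  construct <- boot$network$nodes$construct
  B <- dim(boot$coeff_boot)[3]
  d <- vapply(seq_len(B), function(b) {
    cent <- centrality_from_coeff(boot$coeff_boot[, , b], index, construct, scale)
    cent[ia] - cent[ib]
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(d, c(alpha, 1 - alpha)))
  cent_full <- centrality_from_coeff(boot$estimate, index, construct, scale)
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       estimate = cent_full[ia] - cent_full[ib], trivial = FALSE)
}
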