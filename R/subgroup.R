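#' Split a cohort into early- and advanced-stage subgroups
#'
#' Early stage pools stages I and II, advanced stage pools III and IV.
#'
#' @param data a [panel_dataset()].
#' @return List with elements `early` and `advanced` ([panel_dataset()]s)
#'   and attribute `counts`.
#' @export
split_by_stage <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  stage <- as.character(data$stage)
  early_idx <- which(stage %in% c("I", "II"))
  adv_idx <- which(stage %in% c("III", "IV"))
  if (length(early_idx) == 0) stop("empty subgroup: early (stages I/II)")
  if (length(adv_idx) == 0) stop("empty subgroup: advanced (stages III/IV)")
  out <- list(early = subset_panel(data, early_idx),
              advanced = subset_panel(data, adv_idx))
  attr(out, "counts") <- c(early = length(early_idx), advanced = length(adv_idx))
  out
}

#' Estimate and compare subgroup networks
#'
#' Fits the cross-lagged panel network separately in each subgroup with a
#' shared selection procedure (the penalty itself is re-selected per group,
#' since the groups differ in size), and reports per-group centralities,
#' block extrema, and the elementwise coefficient difference
#' `edge_delta = coeff_early - coeff_advanced`. The comparison is
#' descriptive; [permutation_comparison()] adds an inferential test.
#'
#' @param early,advanced complete-case [panel_dataset()]s.
#' @param settings a [clpn_settings()].
#' @param scale centrality scale for the per-group tables.
#' @return An object of class `clpn_comparison`.
#' @export
compare_networks <- function(early, advanced, settings = clpn_settings(),
                             scale = "coeff") {
  groups <- list(early = early, advanced = advanced)
  nets <- lapply(names(groups), function(g) {
    tryCatch(estimate_clpn(groups[[g]], settings),
             error = function(e) stop(g, " subgroup: ", conditionMessage(e),
                                      call. = FALSE))
  })
  names(nets) <- names(groups)
  cents <- lapply(nets, centrality_table, scale = scale)
  blocks <- list(c("DA", "DA"), c("FCR", "FCR"), c("DA", "FCR"), c("FCR", "DA"))
  extrema <- lapply(nets, function(net) {
    out <- lapply(blocks, function(b) {
      tryCatch(block_extremum(net, b[1], b[2], rank = 1), error = function(e) NULL)
    })
    names(out) <- vapply(blocks, paste, "", collapse = "->")
    out
  })
  structure(
    list(group_networks = nets, group_centralities = cents,
         group_extrema = extrema,
         edge_delta = nets$early$coeff - nets$advanced$coeff,
         counts = c(early = n_subjects(early), advanced = n_subjects(advanced)),
         settings = settings),
    class = "clpn_comparison"
  )
}

#' @export
print.clpn_comparison <- function(x, ...) {
  cat("Subgroup network comparison: early n =", x$counts["early"],
      "vs advanced n =", x$counts["advanced"], "\n")
  off <- row(x$edge_delta) != col(x$edge_delta)
  cat(sprintf("  max |cross-lagged difference| = %.3f, mean |difference| = %.3f\n",
              max(abs(x$edge_delta[off])), mean(abs(x$edge_delta[off]))))
  invisible(x)
}

# Cross-lagged comparison statistics between two coefficient matrices:
# the largest absolute edge difference and the global-strength difference,
# both over off-diagonal (cross-lagged) entries.
comparison_stats <- function(coeff_a, coeff_b) {
  off <- row(coeff_a) != col(coeff_a)
  c(max_edge_diff = max(abs(coeff_a[off] - coeff_b[off])),
    strength_diff = abs(sum(abs(coeff_a[off])) - sum(abs(coeff_b[off]))))
}

#' Permutation test for subgroup network differences
#'
#' Permutes subjects across the two group labels, re-estimates both
#' networks per permutation, and compares the observed statistics --
#' maximum absolute cross-lagged edge difference and absolute
#' global-strength difference -- against their permutation distributions.
#' The p-value is the fraction of permuted statistics at least as large as
#' the observed one.
#'
#' @param early,advanced complete-case [panel_dataset()]s.
#' @param settings a [clpn_settings()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (substreamed per permutation).
#' @param refit_lambda re-select the penalty inside every permutation
#'   (`TRUE`, default) or freeze each group's full-sample penalties.
#' @return List: `max_edge_diff_p`, `strength_diff_p`, `observed`,
#'   `n_perm`.
#' @export
permutation_comparison <- function(early, advanced, settings = clpn_settings(),
                                   n_perm = 500, seed = 1,
                                   refit_lambda = TRUE) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  net_e <- estimate_clpn(early, settings)
  net_a <- estimate_clpn(advanced, settings)
  obs <- comparison_stats(net_e$coeff, net_a$coeff)
  set_e <- if (refit_lambda) settings else frozen_lambda_settings(settings, net_e)
  set_a <- if (refit_lambda) settings else frozen_lambda_settings(settings, net_a)
  pooled <- bind_panels(early, advanced)
  n_e <- n_subjects(early)
  n <- n_subjects(pooled)
  seeds <- derive_seeds(seed, n_perm)
  perm <- matrix(NA_real_, n_perm, 2)
  for (b in seq_len(n_perm)) {
    idx <- with_preserved_seed(seeds[b], sample.int(n, n))
    pe <- tryCatch(estimate_clpn(subset_panel(pooled, idx[seq_len(n_e)]), set_e),
                   error = function(e) NULL)
    pa <- tryCatch(estimate_clpn(subset_panel(pooled, idx[-seq_len(n_e)]), set_a),
                   error = function(e) NULL)
    if (is.null(pe) || is.null(pa)) next
    perm[b, ] <- comparison_stats(pe$coeff, pa$coeff)
  }
  perm <- perm[complete.cases(perm), , drop = FALSE]
  list(
    max_edge_diff_p = mean(perm[, 1] >= obs["max_edge_diff"]),
    strength_diff_p = mean(perm[, 2] >= obs["strength_diff"]),
    observed = obs,
    n_perm = nrow(perm)
  )
}
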