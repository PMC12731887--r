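fmt3 <- function(x) formatC(x, format = "f", digits = 3)

md_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) fmt3(col) else as.character(col)
  }, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Render a markdown analysis report
#'
#' Assembles a deterministic markdown report: the odds-ratio adjacency
#' matrix (predictors in rows), the ranked cross-lagged edges, the
#' centrality table, a stability section (CS coefficients and CI coverage
#' when a bootstrap summary is supplied, an explicit "not computed" marker
#' otherwise), and an optional subgroup-comparison section. Output is
#' byte-stable: the same inputs always render the same text.
#'
#' @param network a `clpn` network (mandatory).
#' @param centrality a [centrality_table()] data frame (mandatory).
#' @param boot optional [bootstrap_edges()] result; may carry an attribute
#'   `cs` (named numeric vector of CS coefficients) for the stability
#'   section.
#' @param comparison optional [compare_networks()] result.
#' @param file optional path; when given the report is also written there.
#' @return Character vector of markdown lines, invisibly when written.
#' @export
render_report <- function(network, centrality, boot = NULL, comparison = NULL,
                          file = NULL) {
  if (missing(network) || !inherits(network, "clpn")) {
    stop("mandatory section missing: `network` must be a clpn object")
  }
  if (missing(centrality) || !is.data.frame(centrality)) {
    stop("mandatory section missing: `centrality` must be a centrality table")
  }
  lines <- c("# Cross-lagged panel network report", "")

  or <- network$or_matrix
  adj <- data.frame(predictor = rownames(or), as.data.frame(or),
                    check.names = FALSE)
  lines <- c(lines, "## Adjacency matrix (odds ratios, predictors in rows)", "",
             md_table(adj), "")

  cen <- edge_census(network)
  lines <- c(lines,
             sprintf("Nonzero cross-lagged edges: %d (%d positive).",
                     cen$n_nonzero_cross, cen$n_positive), "")

  edges <- ranked_edges(network, top_k = 10)
  lines <- c(lines, "## Strongest cross-lagged edges", "",
             if (nrow(edges) > 0) md_table(edges) else "No nonzero cross-lagged edges.",
             "")

  lines <- c(lines, "## Centrality", "", md_table(centrality), "")

  lines <- c(lines, "## Stability", "")
  if (is.null(boot)) {
    lines <- c(lines, "Stability: not computed.", "")
  } else {
    nb <- dim(boot$coeff_boot)[3]
    covered <- mean(boot$ci_low <= boot$estimate & boot$estimate <= boot$ci_high)
    lines <- c(lines,
               sprintf("Bootstrap resamples: %d (of %d requested; %d failed).",
                       nb, boot$n_boot, boot$failures),
               sprintf("Edges with the point estimate inside the %.0f%% CI: %.1f%%.",
                       100 * boot$conf, 100 * covered))
    cs <- attr(boot, "cs")
    if (!is.null(cs)) {
      lines <- c(lines, "",
                 paste0("CS(", names(cs), ") = ", fmt3(as.numeric(cs))))
    }
    lines <- c(lines, "")
  }

  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "clpn_comparison"))
    off <- row(comparison$edge_delta) != col(comparison$edge_delta)
    lines <- c(lines, "## Subgroup comparison", "",
               sprintf("Early n = %d, advanced n = %d.",
                       comparison$counts["early"], comparison$counts["advanced"]),
               sprintf("Max |cross-lagged difference| = %s; mean |difference| = %s.",
                       fmt3(max(abs(comparison$edge_delta[off]))),
                       fmt3(mean(abs(comparison$edge_delta[off])))), "")
    for (g in names(comparison$group_extrema)) {
      ex <- comparison$group_extrema[[g]][["DA->FCR"]]
      if (!is.null(ex)) {
        lines <- c(lines, sprintf("Strongest DA->FCR edge (%s): %s -> %s (OR = %s).",
                                  g, ex$edge["from"], ex$edge["to"], fmt3(ex$or)))
      }
    }
    lines <- c(lines, "")
  }

  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
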