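#' Load a bundled worked-example fixture
#'
#' The package ships the printed summary tables of the reference two-wave
#' breast-cancer cohort as plain-text fixtures: the 11 x 11 odds-ratio
#' adjacency matrix of the estimated T1 -> T2 network (predictors in rows,
#' entries printed to 3 decimals, diagonal 1.000), the per-subscale
#' descriptive statistics at both waves, and the tumour-stage counts.
#' Values are transcribed verbatim, never recomputed.
#'
#' @param name one of `"table3_or_matrix"`, `"table2_descriptives"`,
#'   `"table1_stage_counts"`, `"node_labels"`.
#' @return The fixture: a numeric matrix, a data frame, or the node table.
#' @examples
#' or <- load_fixture("table3_or_matrix")
#' or["D3", "F3"]
#' @export
load_fixture <- function(name = c("table3_or_matrix", "table2_descriptives",
                                  "table1_stage_counts", "node_labels")) {
  name <- match.arg(name)
  if (name == "node_labels") return(clpn_nodes())
  path <- system.file("extdata", paste0(name, ".csv"), package = "clpnet")
  if (path == "") stop("fixture file not found: ", name)
  if (name == "table3_or_matrix") {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    return(m)
  }
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' The reference cohort's network as a `clpn` object
#'
#' Convenience wrapper: [load_fixture()]'s OR adjacency matrix wrapped via
#' [clpn_from_or()], ready for centrality and edge-ranking functions.
#' Entries printed as 1.000 are absent edges.
#'
#' @return A `clpn` network.
#' @export
fixture_network <- function() {
  clpn_from_or(load_fixture("table3_or_matrix"))
}
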