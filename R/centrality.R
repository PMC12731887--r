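# Edge-weight matrix on the requested scale with autoregressive paths
# removed. "coeff" sums log-OR coefficients; "or_minus_1" sums OR - 1
# (the natural scale for fixture matrices printed as odds ratios).
weights_matrix <- function(net, scale = c("coeff", "or_minus_1")) {
  scale <- match.arg(scale)
  W <- if (scale == "coeff") net$coeff else net$or_matrix - 1
  diag(W) <- 0
  W
}

#' Expected influence centrality of a directed network
#'
#' Out-expected influence of node i is the signed sum of its outgoing
#' cross-lagged edges (predictive force); in-expected influence of node j
#' is the signed sum of its incoming edges (predictability). Autoregressive
#' paths are always excluded. Negative edges keep their sign: this is
#' expected influence, not strength.
#'
#' @param net a `clpn` network.
#' @param direction `"out"` or `"in"`.
#' @param scale `"coeff"` (log-OR, default for estimated networks) or
#'   `"or_minus_1"` (for OR-scale fixture matrices).
#' @return Named numeric vector over the nodes.
#' @export
expected_influence <- function(net, direction = c("out", "in"),
                               scale = c("coeff", "or_minus_1")) {
  stopifnot(inherits(net, "clpn"))
  direction <- match.arg(direction)
  W <- weights_matrix(net, scale)
  if (direction == "out") rowSums(W) else colSums(W)
}

#' One-step bridge expected influence
#'
#' Expected influence restricted to edges crossing the construct partition
#' (e.g. DA vs FCR): bridge-OEI of node i sums its edges into the other
#' construct, bridge-IEI its edges received from the other construct.
#'
#' @param net a `clpn` network.
#' @param partition named vector node code -> construct; defaults to the
#'   network's node table. Must 2-color all nodes.
#' @inheritParams expected_influence
#' @return Named numeric vector over the nodes.
#' @export
bridge_expected_influence <- function(net, partition = NULL,
                                      direction = c("out", "in"),
                                      scale = c("coeff", "or_minus_1")) {
  stopifnot(inherits(net, "clpn"))
  direction <- match.arg(direction)
  if (is.null(partition)) partition <- node_partition(net$nodes)
  codes <- net$nodes$code
  if (!all(codes %in% names(partition))) {
    stop("partition must cover every node")
  }
  grp <- partition[codes]
  if (length(unique(grp)) != 2) {
    stop("partition must split the nodes into exactly two constructs")
  }
  W <- weights_matrix(net, scale)
  crossing <- outer(grp, grp, "!=")
  W[!crossing] <- 0
  if (direction == "out") rowSums(W) else colSums(W)
}

#' Centrality table with raw and standardized indices
#'
#' Collects OEI, IEI and the one-step bridge indices on one scale, plus
#' per-index z-scores across the nodes.
#'
#' @param net a `clpn` network.
#' @param scale `"coeff"` or `"or_minus_1"`.
#' @param partition optional construct partition for the bridge indices.
#' @return Data frame: `node`, `construct`, `oei`, `iei`, `bridge_oei`,
#'   `bridge_iei`, `scale`, and `z_*` columns.
#' @export
centrality_table <- function(net, scale = c("coeff", "or_minus_1"),
                             partition = NULL) {
  scale <- match.arg(scale)
  out <- data.frame(
    node = net$nodes$code,
    construct = net$nodes$construct,
    oei = expected_influence(net, "out", scale),
    iei = expected_influence(net, "in", scale),
    bridge_oei = bridge_expected_influence(net, partition, "out", scale),
    bridge_iei = bridge_expected_influence(net, partition, "in", scale),
    scale = scale,
    row.names = NULL
  )
  for (idx in c("oei", "iei", "bridge_oei", "bridge_iei")) {
    v <- out[[idx]]
    s <- sd(v)
    out[[paste0("z_", idx)]] <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  }
  out
}

block_of <- function(net, block) {
  if (identical(block, "all")) rep(TRUE, nrow(net$nodes))
  else {
    if (!block %in% net$nodes$construct) stop("unknown construct block: ", block)
    net$nodes$construct == block
  }
}

#' Rank-th strongest edge within a predictor/outcome block
#'
#' Finds the rank-th largest odds ratio among nonzero cross-lagged edges
#' whose predictor lies in `from_block` and outcome in `to_block`
#' (`"DA"`, `"FCR"` or `"all"`). Ties break lexicographically by
#' (predictor, outcome) node order.
#'
#' @param net a `clpn` network.
#' @param from_block,to_block construct name or `"all"`.
#' @param rank positive integer.
#' @param zero_tol structural-zero tolerance on the coefficient scale.
#' @return List with `edge` (named from/to codes) and `or`.
#' @export
block_extremum <- function(net, from_block = "all", to_block = "all",
                           rank = 1, zero_tol = 1e-9) {
  stopifnot(inherits(net, "clpn"), rank >= 1)
  rows <- block_of(net, from_block)
  cols <- block_of(net, to_block)
  if (!any(rows) || !any(cols)) stop("empty block")
  keep <- outer(rows, cols, "&") & row(net$coeff) != col(net$coeff) &
    abs(net$coeff) > zero_tol
  if (!any(keep)) stop("no nonzero edges in block ", from_block, " -> ", to_block)
  idx <- which(keep, arr.ind = TRUE)
  ors <- net$or_matrix[keep]
  ord <- order(-ors, idx[, 1], idx[, 2])
  if (rank > length(ord)) {
    stop("rank ", rank, " exceeds the ", length(ord), " nonzero edges in the block")
  }
  pick <- idx[ord[rank], ]
  codes <- net$nodes$code
  list(edge = c(from = codes[pick[1]], to = codes[pick[2]]),
       or = net$or_matrix[pick[1], pick[2]])
}

#' Cross-lagged edges ranked by magnitude
#'
#' All nonzero cross-lagged (off-diagonal) edges sorted by absolute
#' coefficient, descending; ties break lexicographically by
#' (predictor, outcome) node order.
#'
#' @param net a `clpn` network.
#' @param top_k optional cap on the number of edges returned.
#' @param zero_tol structural-zero tolerance.
#' @return Data frame: `from`, `to`, `coeff`, `or`.
#' @export
ranked_edges <- function(net, top_k = NULL, zero_tol = 1e-9) {
  stopifnot(inherits(net, "clpn"))
  keep <- row(net$coeff) != col(net$coeff) & abs(net$coeff) > zero_tol
  idx <- which(keep, arr.ind = TRUE)
  codes <- net$nodes$code
  out <- data.frame(
    from = codes[idx[, 1]],
    to = codes[idx[, 2]],
    coeff = net$coeff[keep],
    or = net$or_matrix[keep],
    row.names = NULL
  )
  out <- out[order(-abs(out$coeff), idx[, 1], idx[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}
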