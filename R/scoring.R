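#' Score subscales from item-level responses
#'
#' Sums mapped items into subscale scores. The analysis unit of the
#' pipeline is the subscale (network nodes are instrument dimensions);
#' item-level data only enter through this summation.
#'
#' @param items numeric matrix or data frame, one row per subject, one
#'   column per item.
#' @param map named list: subscale code -> character vector of item column
#'   names. The map must cover every item exactly once.
#' @return Numeric matrix of subscale scores (subjects x subscales).
#' @examples
#' items <- matrix(rpois(20, 2), 5, 4,
#'                 dimnames = list(NULL, c("q1", "q2", "q3", "q4")))
#' score_subscales(items, list(D1 = c("q1", "q2"), D2 = c("q3", "q4")))
#' @export
score_subscales <- function(items, map) {
  items <- as.matrix(items)
  mapped <- unlist(map, use.names = FALSE)
  if (anyDuplicated(mapped)) {
    stop("item(s) mapped to more than one subscale: ",
         paste(unique(mapped[duplicated(mapped)]), collapse = ", "))
  }
  unmapped <- setdiff(colnames(items), mapped)
  if (length(unmapped) > 0) {
    stop("unmapped item(s): ", paste(unmapped, collapse = ", "))
  }
  absent <- setdiff(mapped, colnames(items))
  if (length(absent) > 0) {
    stop("mapped item(s) not present in the item table: ",
         paste(absent, collapse = ", "))
  }
  out <- sapply(map, function(cols) rowSums(items[, cols, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(items),
                                       dimnames = list(NULL, names(map)))
  out
}

#' Death-anxiety screening cutoff
#'
#' A total Death Anxiety Scale score of 7 or more indicates the presence
#' of death anxiety.
#'
#' @param total_da_score non-negative DAS total score(s).
#' @return Logical vector: `TRUE` where the score meets the cutoff.
#' @export
da_present <- function(total_da_score) {
  if (any(total_da_score < 0, na.rm = TRUE)) {
    stop("DAS total score cannot be negative")
  }
  total_da_score >= 7
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total),
#' computed over complete rows.
#'
#' @param items numeric matrix or data frame of item responses (>= 2 columns).
#' @return Scalar alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop("Cronbach's alpha requires at least 2 items")
  items <- items[complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  total_var <- var(rowSums(items))
  if (total_var == 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / total_var)
}

#' Median-split dichotomization of wave-2 outcomes
#'
#' Produces the binary-outcome reading of the panel: each T2 subscale is
#' recoded to 1 when above its observed median, 0 otherwise. Used with the
#' logistic estimation mode; the default pipeline keeps T2 continuous.
#'
#' @param data a [panel_dataset()].
#' @return A [panel_dataset()] with 0/1 wave-2 values.
#' @export
dichotomize_wave2 <- function(data) {
  v <- data$values
  t2 <- paste0(node_codes(), "_T2")
  for (cn in t2) {
    med <- median(v[, cn], na.rm = TRUE)
    v[, cn] <- as.numeric(v[, cn] > med)
  }
  panel_dataset(v, stage = as.character(data$stage),
                covariates = data$covariates, id = data$id)
}
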