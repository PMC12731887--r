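#' Canonical node set of the death-anxiety / fear-of-recurrence network
#'
#' The eleven analysis nodes are the subscale dimensions of the two
#' instruments: four death-anxiety (DA) dimensions from Templer's Death
#' Anxiety Scale (D1 Cognition, D2 Emotion, D3 Time awareness, D4 Stress and
#' pain) and seven fear-of-cancer-recurrence (FCR) dimensions from the Fear
#' of Cancer Recurrence Inventory (F1 Triggers ... F7 Coping strategies).
#'
#' @return A data frame with columns `code`, `name` and `construct`
#'   (`"DA"` or `"FCR"`), in the fixed analysis order D1--D4, F1--F7.
#' @examples
#' clpn_nodes()
#' @export
clpn_nodes <- function() {
  data.frame(
    code = c("D1", "D2", "D3", "D4", "F1", "F2", "F3", "F4", "F5", "F6", "F7"),
    name = c("Cognition", "Emotion", "Time awareness", "Stress and pain",
             "Triggers", "Severity", "Psychological distress",
             "Functioning impairment", "Insight", "Reassurance",
             "Coping strategies"),
    construct = c(rep("DA", 4), rep("FCR", 7)),
    stringsAsFactors = FALSE
  )
}

node_codes <- function() clpn_nodes()$code

# Column names of the 22 analysis variables, wave 1 then wave 2.
analysis_columns <- function() {
  codes <- node_codes()
  c(paste0(codes, "_T1"), paste0(codes, "_T2"))
}

#' Construct partition of a node set
#'
#' @param nodes a node data frame as returned by [clpn_nodes()].
#' @return Named character vector mapping node code to construct.
#' @export
node_partition <- function(nodes = clpn_nodes()) {
  setNames(nodes$construct, nodes$code)
}
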