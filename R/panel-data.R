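#' Two-wave panel dataset
#'
#' Container for subject-level two-wave subscale scores plus covariates and
#' cancer stage. The 22 analysis variables are the eleven subscales (see
#' [clpn_nodes()]) measured at discharge (T1) and three months later (T2).
#' Missing values are carried both as `NA` in `values` and in the logical
#' `mask` (`TRUE` = absent), so that missingness structure survives
#' subsetting and can be inspected directly.
#'
#' @param values numeric matrix or data frame with the 22 analysis columns
#'   named `D1_T1 ... F7_T1, D1_T2 ... F7_T2` (any order; reordered
#'   canonically). Observed scores must be non-negative (subscales are sums
#'   of non-negative items).
#' @param stage per-subject tumour stage, values in `I, II, III, IV`.
#' @param covariates optional data frame of adjustment covariates (age,
#'   education, marital status, occupation, income). Missing levels of
#'   categorical covariates are kept as an explicit `"unknown"` level,
#'   never imputed.
#' @param id optional subject identifiers; must be unique.
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(values, stage, covariates = NULL, id = NULL) {
  cols <- analysis_columns()
  values <- as.data.frame(values)
  missing_cols <- setdiff(cols, names(values))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- as.matrix(values[, cols, drop = FALSE])
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop("subscale scores must be non-negative")
  }
  stage <- as.character(stage)
  if (length(stage) != n) stop("`stage` must have one entry per subject")
  bad <- !stage %in% c("I", "II", "III", "IV")
  if (any(bad)) stop("invalid stage value(s): ", paste(unique(stage[bad]), collapse = ", "))
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("duplicate subject id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("`covariates` must have one row per subject")
    covariates[] <- lapply(covariates, function(x) {
      if (is.numeric(x)) return(x)
      x <- as.character(x)
      x[is.na(x)] <- "unknown"
      factor(x)
    })
  }
  structure(
    list(values = values, mask = is.na(values), stage = factor(stage, levels = c("I", "II", "III", "IV")),
         covariates = covariates, id = id, nodes = clpn_nodes()),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Two-wave panel dataset:", n_subjects(x), "subjects,",
      ncol(x$values), "analysis variables\n")
  nmiss <- sum(rowSums(x$mask) > 0)
  cat("  subjects with any missing analysis value:", nmiss, "\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  cat("  stage distribution:", paste(names(table(x$stage)), as.integer(table(x$stage)),
                                     sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a panel dataset
#' @param data a [panel_dataset()].
#' @export
n_subjects <- function(data) nrow(data$values)

t1_matrix <- function(data) data$values[, paste0(node_codes(), "_T1"), drop = FALSE]
t2_matrix <- function(data) data$values[, paste0(node_codes(), "_T2"), drop = FALSE]

# Row subset preserving all aligned components. Indices may repeat
# (bootstrap resamples), so subjects get fresh sequential ids.
subset_panel <- function(data, idx) {
  panel_dataset(
    values = data$values[idx, , drop = FALSE],
    stage = as.character(data$stage)[idx],
    covariates = if (is.null(data$covariates)) NULL else data$covariates[idx, , drop = FALSE],
    id = if (anyDuplicated(idx)) NULL else data$id[idx]
  )
}

#' @export
`[.panel_dataset` <- function(x, i, ...) subset_panel(x, i)

# Row-bind two panel datasets (used by permutation tests).
bind_panels <- function(a, b) {
  cov <- NULL
  if (!is.null(a$covariates) && !is.null(b$covariates)) {
    cov <- rbind(a$covariates, b$covariates)
  }
  panel_dataset(
    values = rbind(a$values, b$values),
    stage = c(as.character(a$stage), as.character(b$stage)),
    covariates = cov,
    id = seq_len(n_subjects(a) + n_subjects(b))
  )
}

#' Read a two-wave panel CSV
#'
#' Reads a subject-per-row CSV holding the 22 subscale columns, a stage
#' column and optional covariates. Cells that cannot be parsed as numbers
#' (empty strings, stray text) become missing values and are recorded in
#' the missingness mask.
#'
#' @param path path to a CSV file with a header row.
#' @param schema optional list overriding column names: elements `id`,
#'   `stage`, `covariates` (character vector), `t1` and `t2` (named
#'   11-vectors mapping node code to column name). Defaults expect columns
#'   `D1_T1 ... F7_T2`, `stage`, optional `id`, and any of
#'   `age, education, marital, occupation, income`.
#' @return A [panel_dataset()].
#' @export
read_panel <- function(path, schema = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  codes <- node_codes()
  default <- list(
    id = "id", stage = "stage",
    covariates = intersect(c("age", "education", "marital", "occupation", "income"),
                           names(raw)),
    t1 = setNames(paste0(codes, "_T1"), codes),
    t2 = setNames(paste0(codes, "_T2"), codes)
  )
  if (!is.null(schema)) default[names(schema)] <- schema
  schema <- default

  needed <- c(unname(schema$t1), unname(schema$t2), schema$stage)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- sapply(c(schema$t1, schema$t2), function(cn) {
    suppressWarnings(as.numeric(raw[[cn]]))
  })
  if (is.null(dim(values))) values <- matrix(values, nrow = nrow(raw))
  colnames(values) <- analysis_columns()

  id <- if (schema$id %in% names(raw)) raw[[schema$id]] else NULL
  cov <- NULL
  if (length(schema$covariates) > 0) {
    cov <- raw[, schema$covariates, drop = FALSE]
    if ("age" %in% names(cov)) cov$age <- suppressWarnings(as.numeric(cov$age))
  }
  panel_dataset(values, stage = raw[[schema$stage]], covariates = cov, id = id)
}

#' Write a panel dataset to CSV
#'
#' Inverse of [read_panel()]: one row per subject with the 22 subscale
#' columns, `id`, `stage` and any covariates.
#'
#' @param data a [panel_dataset()].
#' @param path output file path.
#' @export
write_panel <- function(data, path) {
  out <- data.frame(id = data$id, stage = as.character(data$stage),
                    data$values, check.names = FALSE)
  if (!is.null(data$covariates)) out <- cbind(out, data$covariates)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Restrict to subjects with complete analysis variables
#'
#' Listwise deletion over the 22 subscale variables: subjects with any
#' missing analysis value are dropped. The retained object carries the
#' retention fraction and counts as attributes.
#'
#' @param data a [panel_dataset()].
#' @return The complete-case [panel_dataset()], with attributes
#'   `retention` (fraction retained), `n_retained` and `n_dropped`.
#' @export
listwise_complete <- function(data) {
  keep <- rowSums(data$mask) == 0
  if (!any(keep)) stop("listwise deletion removed every subject")
  out <- subset_panel(data, which(keep))
  attr(out, "retention") <- mean(keep)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-subscale descriptive statistics by wave
#'
#' Arithmetic mean and sample standard deviation of each subscale at each
#' wave, computed over observed values.
#'
#' @param data a [panel_dataset()].
#' @param file optional path; when given the table is also written as CSV.
#' @return Data frame with columns `code`, `name`, `t1_mean`, `t1_sd`,
#'   `t2_mean`, `t2_sd`.
#' @export
descriptives <- function(data, file = NULL) {
  t1 <- t1_matrix(data); t2 <- t2_matrix(data)
  out <- data.frame(
    code = node_codes(),
    name = clpn_nodes()$name,
    t1_mean = colMeans(t1, na.rm = TRUE),
    t1_sd = apply(t1, 2, sd, na.rm = TRUE),
    t2_mean = colMeans(t2, na.rm = TRUE),
    t2_sd = apply(t2, 2, sd, na.rm = TRUE),
    row.names = NULL
  )
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
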