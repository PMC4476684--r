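#' Read a CSV file into a discrete dataset
#'
#' Reads an RFC-4180 CSV with a header row. Cells equal to any of the
#' `missing_markers` (default: the empty cell, `?`, and `NA`) become
#' missing. Column kinds are inferred by a numeric-majority heuristic --
#' a column whose non-missing values all parse as numbers and take more
#' than `max_discrete_levels` distinct values is treated as continuous,
#' everything else as discrete -- and can be overridden exactly by a schema
#' sidecar. A header-only file yields a 0-row dataset with a warning.
#'
#' @param path CSV path.
#' @param target Target column name.
#' @param positive Positive target value (default: last domain value).
#' @param missing_markers Strings mapped to missing.
#' @param schema Optional schema: either a path to a sidecar written by
#'   [write_csv_dataset()] (lines `name|kind|v1,v2,...`) or a data frame
#'   with columns `variable`, `kind`, and optionally `domain`
#'   (comma-separated).
#' @param max_discrete_levels Numeric columns with at most this many
#'   distinct values stay discrete.
#' @return A [discrete_dataset()]; the number of rows dropped for a missing
#'   target is available as `$n_dropped_missing_target`.
#' @export
read_csv_dataset <- function(path, target, positive = NULL,
                             missing_markers = c("", "?", "NA"),
                             schema = NULL, max_discrete_levels = 10) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, stringsAsFactors = FALSE)
  if (!target %in% names(raw)) {
    stop("target column '", target, "' absent from ", path, call. = FALSE)
  }
  if (nrow(raw) == 0) warning("file has a header but no rows: ", path)
  for (nm in names(raw)) {
    col <- raw[[nm]]
    col[col %in% missing_markers] <- NA
    raw[[nm]] <- col
  }
  sch <- read_schema(schema)
  for (nm in setdiff(names(raw), target)) {
    col <- raw[[nm]]
    kind <- sch$kind[match(nm, sch$variable)]
    if (!is.na(kind) && kind == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad)) {
        stop("unparseable numeric value(s) in continuous column '", nm,
             "': e.g. '", col[bad][1], "'", call. = FALSE)
      }
      raw[[nm]] <- num
    } else if (!is.na(kind)) {
      dom <- sch$domain[[match(nm, sch$variable)]]
      raw[[nm]] <- if (length(dom) > 0) factor(col, levels = dom) else col
    } else {
      num <- suppressWarnings(as.numeric(col))
      nonmiss <- !is.na(col)
      if (sum(nonmiss) > 0 && all(!is.na(num[nonmiss])) &&
          length(unique(num[nonmiss])) > max_discrete_levels) {
        raw[[nm]] <- num
      }
    }
  }
  discrete_dataset(raw, target = target, positive = positive)
}

read_schema <- function(schema) {
  empty <- list(variable = character(), kind = character(), domain = list())
  if (is.null(schema)) return(empty)
  if (is.data.frame(schema)) {
    dom <- if ("domain" %in% names(schema)) {
      lapply(schema$domain, function(d) {
        if (is.na(d) || !nzchar(d)) character() else
          strsplit(d, ",", fixed = TRUE)[[1]]
      })
    } else {
      rep(list(character()), nrow(schema))
    }
    return(list(variable = as.character(schema$variable),
                kind = as.character(schema$kind), domain = dom))
  }
  lines <- readLines(schema)
  parts <- strsplit(lines, "|", fixed = TRUE)
  list(
    variable = vapply(parts, `[`, "", 1),
    kind = vapply(parts, `[`, "", 2),
    domain = lapply(parts, function(p) {
      if (length(p) < 3 || !nzchar(p[3])) character() else
        strsplit(p[3], ",", fixed = TRUE)[[1]]
    })
  )
}

#' Write a discrete dataset as CSV plus a schema sidecar
#'
#' The CSV stores values with missing as empty cells; the sidecar
#' (`<path>.schema`) records each column's kind and, for discrete columns,
#' the full domain, so [read_csv_dataset()] restores the dataset exactly --
#' including domain values unobserved in the rows.
#'
#' @inheritParams dataset_variables
#' @param path Output CSV path.
#' @export
write_csv_dataset <- function(data, path) {
  stopifnot(inherits(data, "discrete_dataset"))
  df <- data$data
  out <- df
  for (nm in names(out)) out[[nm]] <- as.character(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  lines <- vapply(names(df), function(nm) {
    col <- df[[nm]]
    if (is.factor(col)) {
      paste0(nm, "|discrete|", paste(levels(col), collapse = ","))
    } else {
      paste0(nm, "|continuous|")
    }
  }, "")
  writeLines(lines, paste0(path, ".schema"))
  invisible(path)
}

#' Write cross-validation prediction records as CSV
#'
#' One row per (individual, method): id, method, fold, predicted
#' probability (6 decimals), thresholded label, and true outcome. An empty
#' record set writes the header only.
#'
#' @inheritParams auc_with_ci
#' @param path Output CSV path.
#' @export
write_predictions <- function(records, path) {
  out <- data.frame(
    id = records$id,
    method = records$method,
    fold = records$fold,
    prob = sprintf("%.6f", records$prob),
    label = records$label,
    outcome = records$outcome,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    out <- data.frame(id = integer(), method = character(), fold = integer(),
                      prob = character(), label = logical(),
                      outcome = logical())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a metric report: tab-separated table plus a key-value twin
#'
#' `metrics` is a data frame like [summarize_cv()] output, optionally with
#' a `dataset` column when several cohorts are reported. The main file is a
#' TSV table; `<path>.kv` holds the same numbers as
#' `dataset.method.metric<TAB>value` lines for machine consumption.
#'
#' @param metrics Data frame of per-(dataset, method) metrics.
#' @param path Output TSV path.
#' @export
write_report <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  keycols <- intersect(c("dataset", "method"), names(metrics))
  numcols <- setdiff(names(metrics), keycols)
  lines <- character(0)
  for (i in seq_len(nrow(metrics))) {
    prefix <- paste(unlist(metrics[i, keycols, drop = FALSE]), collapse = ".")
    for (cn in numcols) {
      lines <- c(lines, paste0(prefix, ".", cn, "\t",
                               format(metrics[i, cn], digits = 10)))
    }
  }
  writeLines(lines, paste0(path, ".kv"))
  invisible(path)
}
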