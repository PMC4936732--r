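#' Construct a raw (possibly incomplete) cohort
#'
#' Validates a per-patient table against the schema: every cell must be a
#' category label or one of the variable's missing-data codes.  Labels are
#' normalized through a documented alias map (case, underscores, en-dashes).
#'
#' @param records data.frame with one column per schema variable.
#' @param schema a \code{tbi_schema}.
#' @return A \code{raw_cohort}: the validated data.frame (character columns,
#'   canonical labels) with the schema attached as an attribute.
#' @export
raw_cohort <- function(records, schema = crash_schema()) {
  miss <- setdiff(names(schema), names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  out <- records[names(schema)]
  for (nm in names(schema)) {
    var <- schema[[nm]]
    vals <- normalize_label(as.character(out[[nm]]))
    ok <- vals %in% normalize_label(valid_labels(var))
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("unrecognized label '%s' for variable '%s' at row %d",
                   as.character(out[[nm]])[bad], nm, bad))
    }
    canon <- valid_labels(var)
    out[[nm]] <- canon[match(vals, normalize_label(canon))]
  }
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("raw_cohort", "data.frame"))
}

#' Read a cohort from a delimited text file
#'
#' Comma-separated UTF-8 with a mandatory header row naming the schema
#' variables.  Unknown labels are rejected with the offending row and
#' variable named.
#'
#' @param path file path.
#' @param schema a \code{tbi_schema}.
#' @return a \code{raw_cohort}; row order preserved.
#' @export
read_cohort <- function(path, schema = crash_schema()) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  raw_cohort(df, schema)
}

#' Write a cohort to CSV
#'
#' @param cohort a \code{raw_cohort} or \code{cohort}.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(lapply(cohort, as.character),
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Complete-case filter
#'
#' Drops every record carrying a missing-data code on any of the 13
#' predictors or the outcome, mirroring a complete-case exclusion rule.
#' Retained records are returned as a \code{cohort} (factor columns over the
#' category sets only).
#'
#' @param raw a \code{raw_cohort}.
#' @return list with elements \code{cohort} (the retained records),
#'   \code{report} (an \code{exclusion_report}: per variable x missing code
#'   counts, plus totals).  Counts satisfy retained + excluded = input n.
#' @export
complete_case_filter <- function(raw) {
  schema <- attr(raw, "schema")
  stopifnot(!is.null(schema))
  n <- nrow(raw)
  missing_mask <- matrix(FALSE, n, length(schema),
                         dimnames = list(NULL, names(schema)))
  rows <- list()
  for (nm in names(schema)) {
    codes <- schema[[nm]]$missing_codes
    if (!length(codes)) next
    for (code in codes) {
      hit <- raw[[nm]] == code
      missing_mask[, nm] <- missing_mask[, nm] | hit
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, code = code, count = sum(hit),
        stringsAsFactors = FALSE)
    }
  }
  keep <- !apply(missing_mask, 1L, any)
  report <- do.call(rbind, rows) %||%
    data.frame(variable = character(), code = character(), count = integer())
  report <- structure(list(per_code = report,
                           n_input = n,
                           n_retained = sum(keep),
                           n_excluded = sum(!keep)),
                      class = "exclusion_report")
  list(cohort = as_cohort(raw[keep, , drop = FALSE], schema),
       report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Complete-case filter: %d of %d retained (%d excluded)\n",
              x$n_retained, x$n_input, x$n_excluded))
  if (nrow(x$per_code)) print(x$per_code, row.names = FALSE)
  invisible(x)
}

# Coerce a complete table (no missing codes) to a `cohort` of factors.
as_cohort <- function(df, schema = attr(df, "schema") %||% crash_schema()) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)[names(schema)]
  for (nm in names(schema)) {
    bad <- !(as.character(out[[nm]]) %in% schema[[nm]]$categories)
    if (any(bad))
      stop(sprintf("variable '%s' carries a missing code or unknown label at row %d",
                   nm, which(bad)[1L]))
    out[[nm]] <- factor(as.character(out[[nm]]), levels = schema[[nm]]$categories)
  }
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("cohort", "data.frame"))
}

#' Binary outcome vector of a cohort
#'
#' @param cohort a \code{cohort}.
#' @return integer vector, 1 = poor outcome (death or severe disability).
#' @export
outcome_binary <- function(cohort) {
  as.integer(as.character(cohort$outcome) == poor_label())
}

#' Frequency summary of a cohort
#'
#' Per variable x category counts and percentages, in the style of a
#' three-panel patient-characteristics table: \code{"complete"} (complete
#' cases only), \code{"missing"} (records excluded by the complete-case
#' rule), or \code{"entire"}.  Missing codes appear as categories in the
#' missing/entire panels.  Percentages are computed over the panel's record
#' count and rounded half-up to 2 decimals; within a variable they sum to
#' 100 up to rounding.
#'
#' @param cohort a \code{raw_cohort} or \code{cohort}.
#' @param panel one of \code{"entire"}, \code{"complete"}, \code{"missing"}.
#' @return data.frame with columns variable, category, count, percent, and
#'   an attribute \code{denominator}.
#' @export
summarize_cohort <- function(cohort, panel = c("entire", "complete", "missing")) {
  panel <- match.arg(panel)
  schema <- attr(cohort, "schema") %||% crash_schema()
  df <- as.data.frame(lapply(cohort, as.character), stringsAsFactors = FALSE)
  if (panel != "entire") {
    mm <- rep(FALSE, nrow(df))
    for (nm in names(schema))
      mm <- mm | df[[nm]] %in% schema[[nm]]$missing_codes
    df <- df[if (panel == "complete") !mm else mm, , drop = FALSE]
  }
  denom <- nrow(df)
  rows <- lapply(names(schema), function(nm) {
    labs <- valid_labels(schema[[nm]])
    cnt <- as.integer(table(factor(df[[nm]], levels = labs)))
    keep <- cnt > 0 | labs %in% schema[[nm]]$categories
    data.frame(variable = nm, category = labs[keep], count = cnt[keep],
               percent = if (denom > 0) round_half_up(100 * cnt[keep] / denom)
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  attr(out, "panel") <- panel
  out
}
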