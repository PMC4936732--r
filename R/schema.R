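#' CRASH-style admission variable schema
#'
#' The 13 categorical admission predictors and the six-month dichotomized
#' outcome used throughout the package, with their category sets, variable
#' groups and missing-data codes.  Predictors span patient/injury
#' characteristics (sex, age band, injury cause, major extracranial injury),
#' clinical assessment (pupillary response and the three Glasgow Coma Scale
#' components), and five CT findings (petechial hemorrhage, subarachnoid
#' bleed, obliterated third ventricle/basal cisterns, midline shift,
#' hematoma).  The positive outcome class is death or severe disability.
#'
#' @return An object of class \code{tbi_schema}: a named list with one entry
#'   per variable, each a list with elements \code{name}, \code{group}
#'   (\code{"epidemiology"}, \code{"assessment"}, \code{"imaging"} or
#'   \code{"outcome"}), \code{categories} (ordered character vector) and
#'   \code{missing_codes}.
#' @examples
#' sch <- crash_schema()
#' names(sch)
#' sch$motor$categories
#' @export
crash_schema <- function() {
  v <- function(name, group, categories, missing_codes = character()) {
    list(name = name, group = group, categories = categories,
         missing_codes = missing_codes)
  }
  sch <- list(
    sex    = v("sex", "epidemiology", c("male", "female")),
    age    = v("age", "epidemiology",
               c("<20", "20-24", "25-29", "30-34", "35-44", "45-54", ">55")),
    cause  = v("cause", "epidemiology",
               c("road traffic accident", "fall >2 meters", "other"),
               "no data"),
    ec     = v("ec", "epidemiology", c("yes", "no"), "no data"),
    eye    = v("eye", "assessment",
               c("no response", "to pain", "to verbal stimulus", "spontaneous")),
    motor  = v("motor", "assessment",
               c("no response", "extension", "abnormal flexion", "withdrawal",
                 "localises", "follows commands")),
    verbal = v("verbal", "assessment",
               c("no response", "incomprehensible sounds", "single words",
                 "confused", "orientated")),
    pupils = v("pupils", "assessment",
               c("both reactive", "no response unilateral", "no response"),
               "unable to assess"),
    phm    = v("phm", "imaging", c("yes", "no"), c("scan not done", "no data")),
    sah    = v("sah", "imaging", c("yes", "no"), c("scan not done", "no data")),
    oblt   = v("oblt", "imaging", c("yes", "no"), c("scan not done", "no data")),
    mdls   = v("mdls", "imaging", c("yes", "no"), c("scan not done", "no data")),
    hmt    = v("hmt", "imaging", c("yes", "no"), c("scan not done", "no data")),
    outcome = v("outcome", "outcome",
                c("death or severe disability",
                  "moderate disability or good recovery"),
                c("alive disability unknown", "no data"))
  )
  structure(sch, class = "tbi_schema")
}

#' @export
print.tbi_schema <- function(x, ...) {
  cat("Variable schema:", length(x), "variables\n")
  for (v in x) {
    cat(sprintf("  %-8s [%s] %d categories%s\n", v$name, v$group,
                length(v$categories),
                if (length(v$missing_codes))
                  paste0("; missing codes: ",
                         paste(v$missing_codes, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Names of the 13 predictor variables
#'
#' @param schema a \code{tbi_schema}
#' @return character vector of predictor names (everything but the outcome).
#' @export
predictor_names <- function(schema = crash_schema()) {
  setdiff(names(schema), "outcome")
}

# Positive (poor-outcome) label.
poor_label <- function() "death or severe disability"

# Alias map: tolerate lowercase/underscored/hyphen-variant labels on input.
normalize_label <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("_", " ", y, fixed = TRUE)
  y <- gsub("–", "-", y)             # en-dash in age bands
  y <- gsub(">\\s+", ">", y); y <- gsub("<\\s+", "<", y)
  y <- gsub("\\s+", " ", y)
  # historical/typo variants
  y[y == "abnomal flexion"] <- "abnormal flexion"
  y[y == "alive, disability unknown"] <- "alive disability unknown"
  y
}

# Valid labels (categories + missing codes) for a schema variable.
valid_labels <- function(var) c(var$categories, var$missing_codes)
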