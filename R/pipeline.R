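#' Pipeline configuration
#'
#' One structure driving the full analysis: simulate (or load) a raw
#' cohort, complete-case filter, rank predictors four ways (Nagelkerke,
#' full AUC, specificity- and sensitivity-targeted standardized pAUC),
#' skeletonize under both partial-area targets, learn constrained Bayesian
#' networks around each key-predictor set, and report.  All stage seeds are
#' derived deterministically from \code{seed}.
#'
#' @param input either a file path (character) to a cohort CSV, or
#'   \code{NULL} to simulate.
#' @param n cohort size when simulating; default 5000.
#' @param folds,cycles cross-validation settings.
#' @param range partial-area interval.
#' @param alpha significance level for the skeletonization stopping rule.
#' @param boot_reps bootstrap replicates for partial-area comparisons.
#' @param bn_restarts hill-climbing restarts.
#' @param seed master seed (required).
#' @param out_dir optional output directory for artifacts.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = NULL, n = 5000L, folds = 5L,
                            cycles = 6L, range = c(0.9, 1), alpha = 0.05,
                            boot_reps = 500L, bn_restarts = 3L, seed,
                            out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input = input, n = as.integer(n), folds = as.integer(folds),
                 cycles = as.integer(cycles), range = range, alpha = alpha,
                 boot_reps = as.integer(boot_reps),
                 bn_restarts = as.integer(bn_restarts),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path file path (extension .yaml/.yml or .json).
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' @param config a \code{pipeline_config}.
#' @return a report bundle (list) with the frequency tables, the four
#'   importance rankings, the AIC elimination trace, both selection traces
#'   and key-predictor sets, both learned networks with CPTs and scripted
#'   probability queries, and a manifest of seeds and settings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seeds <- list(sample = derive_seed(config$seed, 1L),
                missing = derive_seed(config$seed, 2L),
                cv = derive_seed(config$seed, 3L),
                boot = derive_seed(config$seed, 4L),
                bn = derive_seed(config$seed, 5L))

  raw <- stage("input", {
    if (is.null(config$input)) {
      model <- calibrate(default_truth(seeds$sample))
      complete <- sample_cohort(model, config$n, seeds$sample)
      apply_missingness(complete, default_missingness(), seeds$missing)
    } else read_cohort(config$input)
  })
  filt <- stage("filter", complete_case_filter(raw))
  cohort <- filt$cohort
  freq <- stage("summarize", list(
    entire = summarize_cohort(raw, "entire"),
    complete = summarize_cohort(raw, "complete"),
    missing = summarize_cohort(raw, "missing")))

  spec_sp <- metric_spec("pauc_specificity", config$range, config$folds,
                         config$cycles, seeds$cv, config$boot_reps, seeds$boot)
  spec_se <- spec_sp; spec_se$target <- "pauc_sensitivity"

  rankings <- stage("rank", c(
    list(nagelkerke = nagelkerke_drop_ranking(cohort)),
    roc_drop_rankings(cohort, spec = spec_sp)))
  aic_trace <- stage("aic", aic_backward_eliminate(cohort))
  sel_sp <- stage("select_sp",
                  skeletonize(cohort, rankings$pauc_specificity, spec_sp,
                              config$alpha))
  sel_se <- stage("select_se",
                  skeletonize(cohort, rankings$pauc_sensitivity, spec_se,
                              config$alpha))

  bn_for <- function(keys, seed) {
    wl <- cbind(keys, rep("outcome", length(keys)))
    g <- hill_climb(cohort, constraints = edge_constraints(whitelist = wl),
                    restarts = config$bn_restarts, seed = seed)
    fit <- fit_cpts(g, cohort)
    queries <- list(
      cause_given_young = query(fit, "cause", list(age = "<20")),
      cause_given_old = query(fit, "cause", list(age = ">55")),
      ec_given_rta = query(fit, "ec", list(cause = "road traffic accident")),
      ec_given_fall = query(fit, "ec", list(cause = "fall >2 meters")),
      ec_given_other = query(fit, "ec", list(cause = "other")))
    list(dag = g, bn = fit, queries = queries,
         dot = dag_to_dot(g, highlight = keys))
  }
  bn_sp <- stage("bn_sp", bn_for(sel_sp$key_predictors, seeds$bn))
  bn_se <- stage("bn_se", bn_for(sel_se$key_predictors,
                                 derive_seed(seeds$bn, 1L)))

  bundle <- list(
    frequency_tables = freq,
    exclusion_report = filt$report,
    rankings = rankings,
    aic_trace = aic_trace,
    selection = list(specificity = sel_sp, sensitivity = sel_se),
    key_predictors = list(specificity = sel_sp$key_predictors,
                          sensitivity = sel_se$key_predictors),
    networks = list(specificity = bn_sp, sensitivity = bn_se),
    manifest = list(package_version = as.character(utils::packageVersion("tbirank")),
                    seed = config$seed, stage_seeds = seeds,
                    n_raw = nrow(raw), n_complete = nrow(cohort),
                    settings = unclass(config)))
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE)
  for (p in names(bundle$frequency_tables))
    utils::write.csv(bundle$frequency_tables[[p]],
                     file.path(dir, paste0("frequency_", p, ".csv")),
                     row.names = FALSE)
  wj(bundle$exclusion_report[c("n_input", "n_retained", "n_excluded")],
     "exclusion_report.json")
  utils::write.csv(bundle$exclusion_report$per_code,
                   file.path(dir, "exclusions_per_code.csv"), row.names = FALSE)
  for (r in names(bundle$rankings))
    utils::write.csv(bundle$rankings[[r]],
                     file.path(dir, paste0("ranking_", r, ".csv")),
                     row.names = FALSE)
  utils::write.csv(bundle$aic_trace$trace, file.path(dir, "aic_trace.csv"),
                   row.names = FALSE)
  for (s in names(bundle$selection)) {
    utils::write.csv(bundle$selection[[s]]$trace,
                     file.path(dir, paste0("selection_", s, ".csv")),
                     row.names = FALSE)
    utils::write.csv(trace_matrix(bundle$selection[[s]]),
                     file.path(dir, paste0("selection_", s, "_models.csv")))
  }
  wj(bundle$key_predictors, "key_predictors.json")
  for (s in names(bundle$networks)) {
    net <- bundle$networks[[s]]
    writeLines(net$dot, file.path(dir, paste0("bn_", s, ".dot")))
    utils::write.csv(as.data.frame(net$dag$edges),
                     file.path(dir, paste0("bn_", s, "_edges.csv")),
                     row.names = FALSE)
    wj(lapply(net$queries, as.list), paste0("bn_", s, "_queries.json"))
  }
  wj(bundle$manifest, "manifest.json")
  invisible(dir)
}
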