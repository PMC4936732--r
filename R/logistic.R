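#' Dummy-coded design matrix for a predictor subset
#'
#' One indicator block per predictor, reference category = first listed
#' category, deterministic column order (\code{"var=category"}).  The full
#' 13-predictor admission model yields 29 indicator columns.
#'
#' @param cohort a \code{cohort}.
#' @param predictors character vector, non-empty subset of the predictor
#'   names.
#' @return object of class \code{design_matrix}: list with \code{x}
#'   (numeric matrix), \code{block_map} (predictor -> column indices),
#'   \code{y} (binary outcome, 1 = poor).
#' @export
encode_design <- function(cohort, predictors = NULL) {
  schema <- attr(cohort, "schema") %||% crash_schema()
  predictors <- predictors %||% setdiff(names(schema), "outcome")
  stopifnot(length(predictors) >= 1,
            all(predictors %in% setdiff(names(schema), "outcome")))
  cols <- list(); block_map <- list()
  for (v in predictors) {
    f <- cohort[[v]]
    if (length(unique(as.integer(f))) < 2L)
      stop(sprintf("predictor '%s' has a single observed category", v))
    cats <- levels(f)
    block <- vapply(cats[-1], function(k) as.numeric(f == k),
                    numeric(nrow(cohort)))
    colnames(block) <- paste0(v, "=", cats[-1])
    block_map[[v]] <- ncol(do.call(cbind, cols) %||%
                             matrix(nrow = 0, ncol = 0)) + seq_len(ncol(block))
    cols[[v]] <- block
  }
  x <- do.call(cbind, cols)
  structure(list(x = x, block_map = block_map, y = outcome_binary(cohort)),
            class = "design_matrix")
}

#' Maximum-likelihood logistic fit
#'
#' Fits the binary-outcome logistic model by iteratively reweighted least
#' squares (\code{stats::glm.fit}).  Aliased/unidentified coefficients (e.g.
#' a category absent from the data) come back as \code{NA} and are treated
#' as zero in prediction.  Non-convergence is flagged, never silent.
#'
#' @param design a \code{design_matrix}.
#' @return object of class \code{fitted_logistic}: \code{intercept},
#'   \code{coefficients}, \code{log_likelihood}, \code{n}, \code{n_par},
#'   \code{aic}, \code{converged}.
#' @export
fit_logistic <- function(design) {
  x <- cbind(`(Intercept)` = 1, design$x)
  y <- design$y
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  mu <- pmin(pmax(fit$fitted.values, 1e-15), 1 - 1e-15)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  beta <- fit$coefficients
  k <- sum(!is.na(beta))
  structure(list(intercept = beta[1L], coefficients = beta[-1L],
                 log_likelihood = ll, n = length(y), n_par = k,
                 aic = 2 * k - 2 * ll, converged = isTRUE(fit$converged)),
            class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, %d parameters, logLik = %.3f, AIC = %.2f%s\n",
              x$n, x$n_par, x$log_likelihood, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

# Predicted probabilities on new design rows; NA coefficients dropped.
predict_logistic <- function(fit, x) {
  beta <- c(fit$intercept, fit$coefficients)
  beta[is.na(beta)] <- 0
  as.vector(stats::plogis(cbind(1, x) %*% beta))
}

#' Repeated cross-validated out-of-sample predictions
#'
#' Repeated K-fold cross validation: per cycle an independent random
#' partition into \code{folds} folds, each fold predicted by a logistic
#' model trained on the remainder.  The partition depends only on the
#' record count and \code{split_seed}, never on the predictor subset, so
#' any two models evaluated with the same seed share identical fold
#' memberships (the pairing guarantee for model comparison).  Predictions
#' from all (record, cycle) pairs are pooled.
#'
#' @param cohort a \code{cohort}.
#' @param predictors predictor subset.
#' @param folds number of folds (>= 2); default 5.
#' @param cycles number of independent repetitions; default 6.
#' @param split_seed integer seed (required).
#' @return object of class \code{cv_predictions}: data.frame with columns
#'   \code{record}, \code{cycle}, \code{prob}, \code{outcome}; attributes
#'   \code{folds_matrix} (n x cycles fold ids), \code{split_seed},
#'   \code{dropped_levels} (log of categories absent from a training fold).
#' @export
cv_predict <- function(cohort, predictors = NULL, folds = 5L, cycles = 6L,
                       split_seed) {
  stopifnot(folds >= 2L, cycles >= 1L)
  design <- encode_design(cohort, predictors)
  n <- length(design$y)
  fm <- cv_fold_matrix(n, folds, cycles, split_seed)
  prob <- matrix(NA_real_, n, cycles)
  dropped <- character()
  for (cy in seq_len(cycles)) {
    for (f in seq_len(folds)) {
      test <- fm[, cy] == f
      xtr <- design$x[!test, , drop = FALSE]
      fit <- fit_logistic(structure(list(x = xtr, y = design$y[!test]),
                                    class = "design_matrix"))
      if (anyNA(fit$coefficients)) {
        nas <- names(fit$coefficients)[is.na(fit$coefficients)]
        dropped <- c(dropped, sprintf("cycle %d fold %d: %s", cy, f,
                                      paste(nas, collapse = ", ")))
      }
      prob[test, cy] <- predict_logistic(fit, design$x[test, , drop = FALSE])
    }
  }
  out <- data.frame(record = rep(seq_len(n), cycles),
                    cycle = rep(seq_len(cycles), each = n),
                    prob = as.vector(prob),
                    outcome = rep(design$y, cycles))
  structure(out, folds_matrix = fm, split_seed = split_seed,
            folds = folds, cycles = cycles, dropped_levels = dropped,
            class = c("cv_predictions", "data.frame"))
}

# Fold memberships: function of (n, folds, cycles, split_seed) only.
cv_fold_matrix <- function(n, folds, cycles, split_seed) {
  with_seed(split_seed,
            vapply(seq_len(cycles),
                   function(cy) sample(rep_len(seq_len(folds), n)),
                   integer(n)))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R2 = 1 - exp(2 (ll0 - ll1) / n), normalized by its maximum
#' 1 - exp(2 ll0 / n) so the value is bounded in [0, 1].
#'
#' @param full fitted model of interest (a \code{fitted_logistic}).
#' @param null intercept-only fit on the same records.
#' @return Nagelkerke R-squared.
#' @export
nagelkerke_r2 <- function(full, null) {
  stopifnot(full$n == null$n)
  if (full$log_likelihood < null$log_likelihood - 1e-8)
    stop("full model likelihood below null likelihood; models are not nested fits on the same data")
  n <- full$n
  cox_snell <- 1 - exp(2 * (null$log_likelihood - full$log_likelihood) / n)
  max_cs <- 1 - exp(2 * null$log_likelihood / n)
  cox_snell / max_cs
}

# Intercept-only fit for a cohort.
fit_null <- function(cohort) {
  y <- outcome_binary(cohort)
  fit_logistic(structure(list(x = matrix(numeric(0), length(y), 0), y = y),
                         class = "design_matrix"))
}

#' Drop-one importance ranking by Nagelkerke R-squared
#'
#' Importance of a predictor = R2 of the full model minus R2 of the model
#' excluding it, both fitted on the full data (no cross validation, in the
#' style of goodness-of-fit importance rankings).  Descending rank, ties
#' broken alphabetically.
#'
#' @param cohort a \code{cohort}.
#' @param predictors predictor set (>= 2).
#' @return an importance table: data.frame with \code{predictor},
#'   \code{metric_full}, \code{metric_without}, \code{drop},
#'   \code{percent_drop}, \code{rank}.
#' @export
nagelkerke_drop_ranking <- function(cohort, predictors = NULL) {
  schema <- attr(cohort, "schema") %||% crash_schema()
  predictors <- predictors %||% setdiff(names(schema), "outcome")
  stopifnot(length(predictors) >= 2)
  null <- fit_null(cohort)
  r2_all <- nagelkerke_r2(fit_logistic(encode_design(cohort, predictors)), null)
  r2_wo <- vapply(predictors, function(v) {
    nagelkerke_r2(fit_logistic(encode_design(cohort, setdiff(predictors, v))),
                  null)
  }, numeric(1))
  make_importance_table(predictors, r2_all, r2_wo)
}

make_importance_table <- function(predictors, metric_full, metric_without) {
  drop <- metric_full - metric_without
  out <- data.frame(predictor = predictors,
                    metric_full = metric_full,
                    metric_without = metric_without,
                    drop = drop,
                    percent_drop = 100 * drop / metric_full,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$drop, out$predictor), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Backward elimination by AIC over whole predictor blocks
#'
#' Starting from the complete model, repeatedly removes the predictor whose
#' exclusion most lowers the model AIC; stops when no single removal lowers
#' it.  Each candidate model is a full-data logistic fit.
#'
#' @param cohort a \code{cohort}.
#' @param predictors starting predictor set.
#' @return list of class \code{aic_trace}: \code{trace} (data.frame with
#'   \code{step}, \code{removed}, \code{aic}, \code{n_predictors}),
#'   \code{final_predictors}, \code{final_aic}.
#' @export
aic_backward_eliminate <- function(cohort, predictors = NULL) {
  schema <- attr(cohort, "schema") %||% crash_schema()
  predictors <- predictors %||% setdiff(names(schema), "outcome")
  stopifnot(length(predictors) >= 1)
  current <- sort(predictors)
  aic_of <- function(set) {
    if (!length(set)) return(fit_null(cohort)$aic)
    fit_logistic(encode_design(cohort, set))$aic
  }
  cur_aic <- aic_of(current)
  trace <- data.frame(step = 0L, removed = NA_character_, aic = cur_aic,
                      n_predictors = length(current),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(current)) break
    cand <- vapply(current, function(v) aic_of(setdiff(current, v)),
                   numeric(1))
    if (min(cand) >= cur_aic) break
    worst <- names(cand)[which.min(cand)]
    current <- setdiff(current, worst)
    cur_aic <- min(cand)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     aic = cur_aic,
                                     n_predictors = length(current)))
  }
  structure(list(trace = trace, final_predictors = current,
                 final_aic = cur_aic),
            class = "aic_trace")
}

#' @export
print.aic_trace <- function(x, ...) {
  cat("AIC backward elimination:\n")
  print(x$trace, row.names = FALSE)
  cat("Final model:", if (length(x$final_predictors))
      paste(x$final_predictors, collapse = ", ") else "(intercept only)",
      sprintf("(AIC %.2f)\n", x$final_aic))
  invisible(x)
}
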