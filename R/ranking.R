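#' Metric specification for ROC-based ranking and selection
#'
#' Bundles the ROC target, partial-area range and cross-validation settings
#' used by \code{\link{drop_one_importance}} and \code{\link{skeletonize}}.
#'
#' @param target \code{"full_auc"}, \code{"pauc_specificity"} or
#'   \code{"pauc_sensitivity"}.
#' @param range partial-area interval; default \code{c(0.9, 1)}.
#' @param folds,cycles cross-validation settings (default 5-fold, 6 cycles).
#' @param split_seed integer seed for the fold partitions (required).
#' @param boot_reps bootstrap replicates for partial-area comparisons/CIs.
#' @param boot_seed seed for the bootstrap; derived from \code{split_seed}
#'   when omitted.
#' @return object of class \code{metric_spec}.
#' @export
metric_spec <- function(target = c("full_auc", "pauc_specificity",
                                   "pauc_sensitivity"),
                        range = c(0.9, 1), folds = 5L, cycles = 6L,
                        split_seed, boot_reps = 2000L, boot_seed = NULL) {
  target <- match.arg(target)
  stopifnot(length(range) == 2, range[1] >= 0, range[2] <= 1,
            range[1] < range[2])
  structure(list(target = target, range = range, folds = folds,
                 cycles = cycles, split_seed = split_seed,
                 boot_reps = boot_reps,
                 boot_seed = boot_seed %||% derive_seed(split_seed, 77L)),
            class = "metric_spec")
}

# Pooled out-of-sample scores for a subset under a spec's CV settings.
cv_pooled <- function(cohort, predictors, spec) {
  cv <- cv_predict(cohort, predictors, folds = spec$folds,
                   cycles = spec$cycles, split_seed = spec$split_seed)
  list(prob = cv$prob, y = cv$outcome)
}

eval_metric <- function(pooled, spec) {
  roc_metric(pooled$prob, pooled$y, spec$target, spec$range)
}

#' Drop-one variable importance under an ROC target
#'
#' The complete model's pooled cross-validated predictions give the
#' reference metric; for each predictor, the model excluding it is
#' cross-validated with identical fold memberships and the percent drop
#' \code{100 * (metric_full - metric_without) / metric_full} scores its
#' importance (a greater decrease means a more important predictor;
#' negative drops are possible and retained).  Ties are broken
#' alphabetically.
#'
#' @param cohort a \code{cohort}.
#' @param predictors predictor set (>= 2).
#' @param spec a \code{\link{metric_spec}}.
#' @return an importance table (see \code{\link{nagelkerke_drop_ranking}}).
#' @export
drop_one_importance <- function(cohort, predictors = NULL, spec) {
  schema <- attr(cohort, "schema") %||% crash_schema()
  predictors <- predictors %||% setdiff(names(schema), "outcome")
  stopifnot(length(predictors) >= 2)
  full <- eval_metric(cv_pooled(cohort, predictors, spec), spec)
  without <- vapply(predictors, function(v) {
    eval_metric(cv_pooled(cohort, setdiff(predictors, v), spec), spec)
  }, numeric(1))
  make_importance_table(predictors, full, without)
}

#' All three ROC drop-one rankings from one set of cross-validation runs
#'
#' Computes pooled CV predictions once per leave-one-out subset and scores
#' them under the full AUC and both standardized partial-AUC targets, so
#' the three rankings are guaranteed to share data and splits.
#'
#' @inheritParams drop_one_importance
#' @param spec a \code{\link{metric_spec}}; its \code{target} is ignored.
#' @return named list of importance tables (\code{full_auc},
#'   \code{pauc_specificity}, \code{pauc_sensitivity}).
#' @export
roc_drop_rankings <- function(cohort, predictors = NULL, spec) {
  schema <- attr(cohort, "schema") %||% crash_schema()
  predictors <- predictors %||% setdiff(names(schema), "outcome")
  stopifnot(length(predictors) >= 2)
  targets <- c("full_auc", "pauc_specificity", "pauc_sensitivity")
  pooled_full <- cv_pooled(cohort, predictors, spec)
  pooled_wo <- lapply(predictors, function(v)
    cv_pooled(cohort, setdiff(predictors, v), spec))
  out <- lapply(targets, function(tg) {
    sp <- spec; sp$target <- tg
    make_importance_table(
      predictors,
      eval_metric(pooled_full, sp),
      vapply(pooled_wo, eval_metric, numeric(1), spec = sp))
  })
  names(out) <- targets
  out
}

#' Stepwise model skeletonization with a significance stopping rule
#'
#' The ranking is computed once on the complete model and fixed.  Model k
#' (k = 1 .. p-1) drops the k lowest-ranked predictors; each model's pooled
#' cross-validated predictions are compared against the complete model's
#' (paired, identical fold memberships) -- by the DeLong test for the full
#' AUC target, by the stratified paired bootstrap for partial-area targets.
#' The selected ("most simplistic") model is the last one before the
#' reduced model is first significantly \emph{worse} than the complete
#' model at \code{alpha} (the rule is directional: a reduced model whose
#' metric is significantly \emph{higher} than the complete model's does not
#' stop the elimination, since the rule watches for a significant drop);
#' its retained predictors are the key predictors.
#'
#' @param cohort a \code{cohort}.
#' @param ranking an importance table covering all predictors (from
#'   \code{\link{drop_one_importance}} or \code{\link{roc_drop_rankings}}).
#' @param spec a \code{\link{metric_spec}}.
#' @param alpha significance level for the stopping rule; default 0.05.
#' @return object of class \code{selection_trace}: \code{trace} (data.frame
#'   with one row per model: \code{model}, \code{dropped}, \code{n_predictors},
#'   \code{metric}, \code{ci_low}, \code{ci_high}, \code{p_value}),
#'   \code{models} (list of retained predictor sets),
#'   \code{selected_index} (0 = complete model), \code{key_predictors},
#'   \code{complete_significant} flag, \code{spec}, \code{alpha}.
#' @export
skeletonize <- function(cohort, ranking, spec, alpha = 0.05) {
  stopifnot(inherits(ranking, "importance_table"), alpha > 0, alpha <= 1)
  preds <- ranking$predictor[order(ranking$rank)]
  p <- length(preds)
  stopifnot(p >= 2)
  pooled_full <- cv_pooled(cohort, preds, spec)
  ci_of <- function(pooled) {
    if (spec$target == "full_auc") {
      a <- auc(roc_curve(pooled$prob, pooled$y))
      se <- sqrt(delong_auc_variance(pooled$prob, pooled$y))
      c(a, a - 1.96 * se, a + 1.96 * se)
    } else {
      axis <- sub("pauc_", "", spec$target)
      ci <- pauc_ci(pooled$prob, pooled$y, axis, spec$range,
                    reps = spec$boot_reps, seed = spec$boot_seed)
      c(ci$estimate, ci$ci_low, ci$ci_high)
    }
  }
  cmp_full <- function(pooled) {
    if (spec$target == "full_auc") {
      delong_test(pooled_full$prob, pooled$prob, pooled_full$y)
    } else {
      axis <- sub("pauc_", "", spec$target)
      bootstrap_pauc_test(pooled_full$prob, pooled$prob, pooled_full$y,
                          axis, spec$range, reps = spec$boot_reps,
                          seed = spec$boot_seed)
    }
  }
  est0 <- ci_of(pooled_full)
  trace <- data.frame(model = 0L, dropped = NA_character_,
                      n_predictors = p, metric = est0[1],
                      ci_low = est0[2], ci_high = est0[3],
                      delta = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  models <- list(preds)
  for (k in seq_len(p - 1L)) {
    retained <- preds[seq_len(p - k)]
    pooled <- cv_pooled(cohort, retained, spec)
    est <- ci_of(pooled)
    tst <- cmp_full(pooled)
    trace <- rbind(trace, data.frame(
      model = k, dropped = preds[p - k + 1L], n_predictors = p - k,
      metric = est[1], ci_low = est[2], ci_high = est[3],
      delta = tst$estimate, p_value = tst$p_value,
      stringsAsFactors = FALSE))
    models[[k + 1L]] <- retained
  }
  # significant *drop*: two-sided p below alpha with the complete model ahead
  sig <- which(trace$p_value[-1] < alpha & trace$delta[-1] > 0)
  selected <- if (!length(sig)) p - 1L else min(sig) - 1L
  structure(list(trace = trace, models = models,
                 selected_index = selected,
                 key_predictors = models[[selected + 1L]],
                 complete_significant = length(sig) > 0 && min(sig) == 1L,
                 spec = spec, alpha = alpha),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Stepwise skeletonization (%s, alpha = %g):\n",
              x$spec$target, x$alpha))
  print(x$trace, row.names = FALSE, digits = 4)
  cat("Selected model:", x$selected_index, "- key predictors:",
      paste(x$key_predictors, collapse = ", "), "\n")
  if (x$complete_significant)
    cat("NOTE: the first reduced model already differed significantly; the complete model was kept.\n")
  invisible(x)
}

#' Model-inclusion matrix of a selection trace
#'
#' Variables x models "+" layout mirroring a stepwise-selection summary
#' table: rows ordered by rank, one column per model, \code{"+"} marking
#' inclusion.
#'
#' @param trace a \code{selection_trace}.
#' @return character matrix.
#' @export
trace_matrix <- function(trace) {
  preds <- trace$models[[1]]
  m <- vapply(trace$models, function(set)
    ifelse(preds %in% set, "+", ""), character(length(preds)))
  dimnames(m) <- list(preds,
                      c("complete", paste0("model", seq_len(ncol(m) - 1L))))
  m
}
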