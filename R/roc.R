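#' Empirical ROC curve
#'
#' Operating points from all distinct score thresholds, ties grouped (so the
#' trapezoidal area equals the Mann-Whitney statistic with half credit for
#' ties), with the corner points (specificity 0, sensitivity 1) and
#' (specificity 1, sensitivity 0) always present.  Higher scores are taken
#' to indicate the positive class.
#'
#' @param scores numeric vector of predicted scores/probabilities.
#' @param labels binary vector (0/1, logical, or a two-level factor whose
#'   second level is the positive class unless it contains the poor-outcome
#'   label).
#' @return object of class \code{roc_points}: list with \code{sp}, \code{se}
#'   (specificity non-decreasing, sensitivity non-increasing), \code{n_pos},
#'   \code{n_neg}.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build an ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  last <- c(s[-1] != s[-length(s)], TRUE)   # end of each tie group
  tp <- cumsum(yy)[last]
  fp <- cumsum(1 - yy)[last]
  se <- c(0, tp / n_pos)
  sp <- c(1, 1 - fp / n_neg)
  # reverse so specificity is non-decreasing
  structure(list(sp = rev(sp), se = rev(se), n_pos = n_pos, n_neg = n_neg),
            class = "roc_points")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    lv <- levels(labels)
    pos <- if (poor_label() %in% lv) poor_label() else lv[2L]
    as.integer(labels == pos)
  } else as.integer(as.numeric(labels) != 0)
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, %d positives / %d negatives, AUC %.4f\n",
              length(x$sp), x$n_pos, x$n_neg, auc(x)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the operating points; identical to the normalized
#' Mann-Whitney U with half credit for ties.
#'
#' @param x an \code{roc_points} object, or a score vector (then
#'   \code{labels} is required).
#' @param labels binary labels when \code{x} is a score vector.
#' @return AUC in [0, 1].
#' @export
auc <- function(x, labels = NULL) {
  if (!inherits(x, "roc_points")) x <- roc_curve(x, labels)
  sum(diff(x$sp) * (utils::head(x$se, -1) + utils::tail(x$se, -1)) / 2)
}

# Integrate the piecewise-linear curve y(x) over [lo, hi], where x is
# non-decreasing and [lo, hi] is inside [min(x), max(x)].  Boundary values
# are linearly interpolated inside the enclosing non-vertical segment.
clip_trapezoid <- function(x, y, lo, hi) {
  interp <- function(at) {
    i <- max(which(x < at)); j <- min(which(x > at))
    y[i] + (y[j] - y[i]) * (at - x[i]) / (x[j] - x[i])
  }
  inside <- x >= lo & x <= hi
  xx <- x[inside]; yy <- y[inside]
  if (!length(xx) || xx[1] > lo)  { xx <- c(lo, xx); yy <- c(interp(lo), yy) }
  if (xx[length(xx)] < hi)        { xx <- c(xx, hi); yy <- c(yy, interp(hi)) }
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Raw partial AUC over a specificity or sensitivity interval
#'
#' Area under the empirical ROC curve restricted to \code{range} on the
#' chosen axis, with linear interpolation at the interval boundaries.  The
#' sensitivity-axis version integrates specificity over the sensitivity
#' interval via the curve-transposition identity, so a single integrator
#' serves both.
#'
#' @param curve an \code{roc_points} object.
#' @param axis \code{"specificity"} or \code{"sensitivity"}.
#' @param range numeric length-2 sub-interval of [0, 1]; default
#'   \code{c(0.9, 1)}.
#' @return raw partial area (between 0 and \code{diff(range)}).
#' @export
pauc <- function(curve, axis = c("specificity", "sensitivity"),
                 range = c(0.9, 1)) {
  axis <- match.arg(axis)
  stopifnot(length(range) == 2, range[1] < range[2],
            range[1] >= 0, range[2] <= 1)
  if (axis == "specificity") {
    clip_trapezoid(curve$sp, curve$se, range[1], range[2])
  } else {
    # transpose: sensitivity becomes the abscissa
    clip_trapezoid(rev(curve$se), rev(curve$sp), range[1], range[2])
  }
}

#' McClish standardization of a partial AUC
#'
#' Linear rescaling of the raw partial area so chance performance in the
#' region maps to 0.5 and perfect performance to 1:
#' \code{0.5 * (1 + (raw - min) / (max - min))}, where \code{max} is the
#' interval width and \code{min} the area under the chance diagonal inside
#' the interval.  A below-chance raw area yields a value below 0.5, flagged
#' via the \code{"below_chance"} attribute.
#'
#' @param raw raw partial area.
#' @param range the interval it was computed over.
#' @return standardized value (attribute \code{below_chance} is TRUE when
#'   the raw area is below the chance area).
#' @export
standardize_pauc <- function(raw, range = c(0.9, 1)) {
  lo <- range[1]; hi <- range[2]
  max_a <- hi - lo
  min_a <- max_a - (hi^2 - lo^2) / 2        # integral of (1 - t) over [lo, hi]
  stopifnot(raw >= -1e-9, raw <= max_a + 1e-9)
  val <- 0.5 * (1 + (raw - min_a) / (max_a - min_a))
  structure(val, below_chance = raw < min_a - 1e-12)
}

# Standardized pAUC straight from scores (internal convenience).
std_pauc_scores <- function(scores, labels, axis, range) {
  as.numeric(standardize_pauc(pauc(roc_curve(scores, labels), axis, range),
                              range))
}

# ---------------------------------------------------------------------------
# DeLong machinery

# Placement values (structural components) per class for one score vector.
delong_placements <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n            # P(pos_i > random neg)
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m    # P(random pos > neg_j)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single empirical AUC
#'
#' @param scores numeric score vector.
#' @param labels binary labels.
#' @return estimated variance of the empirical AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  y <- as_binary_labels(labels)
  pl <- delong_placements(scores, y)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors computed on the
#' same records, via the covariance of their placement values.
#'
#' @param scores_a,scores_b paired per-record score vectors.
#' @param labels shared binary labels.
#' @return object of class \code{paired_test}: list with \code{statistic}
#'   (z), \code{p_value} (two-sided), \code{estimate} (AUC difference a - b),
#'   \code{auc} (both AUCs), \code{method = "delong"}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop("scores_a, scores_b and labels must be paired (equal length)")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  delta <- pa$auc - pb$auc
  var_d <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  if (var_d <= 0) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(var_d)
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = z, p_value = p, estimate = delta,
                 auc = c(a = pa$auc, b = pb$auc), method = "delong"),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired %s test: estimate %.4f, z = %.3f, p = %.4g\n",
              x$method, x$estimate, x$statistic, x$p_value))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Stratified bootstrap for partial areas

# Index machinery shared by the bootstrap test and CI: resample positives
# and negatives separately (class balance preserved, so no degenerate
# single-class resamples are possible).
boot_indices <- function(y) {
  pos <- which(y == 1L); neg <- which(y == 0L)
  c(pos[sample.int(length(pos), replace = TRUE)],
    neg[sample.int(length(neg), replace = TRUE)])
}

#' Paired bootstrap comparison of standardized partial AUCs
#'
#' Stratified paired bootstrap of records; the statistic is the difference
#' in McClish-standardized partial AUC; the p-value is two-sided normal
#' using the bootstrap standard error of the difference.  Used where the
#' classical DeLong covariance does not apply (partial areas).
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @param axis,range as in \code{\link{pauc}}.
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed (required).
#' @return a \code{paired_test} with \code{method = "bootstrap"} and the
#'   replicate differences in \code{$replicates}.
#' @export
bootstrap_pauc_test <- function(scores_a, scores_b, labels,
                                axis = "specificity", range = c(0.9, 1),
                                reps = 2000L, seed) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop("scores_a, scores_b and labels must be paired (equal length)")
  stopifnot(reps >= 100L)
  d0 <- std_pauc_scores(scores_a, y, axis, range) -
        std_pauc_scores(scores_b, y, axis, range)
  dd <- with_seed(seed, vapply(seq_len(reps), function(i) {
    idx <- boot_indices(y)
    std_pauc_scores(scores_a[idx], y[idx], axis, range) -
      std_pauc_scores(scores_b[idx], y[idx], axis, range)
  }, numeric(1)))
  se <- stats::sd(dd)
  if (se == 0) {
    z <- if (abs(d0) < 1e-12) 0 else sign(d0) * Inf
  } else z <- d0 / se
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = z, p_value = p, estimate = d0,
                 method = "bootstrap", replicates = dd),
            class = "paired_test")
}

#' Percentile bootstrap confidence interval for a standardized partial AUC
#'
#' @param scores,labels score vector and binary labels.
#' @param axis,range as in \code{\link{pauc}}.
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed (required).
#' @param conf confidence level (default 0.95).
#' @return list with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{method = "percentile bootstrap"}.
#' @export
pauc_ci <- function(scores, labels, axis = "specificity", range = c(0.9, 1),
                    reps = 2000L, seed, conf = 0.95) {
  y <- as_binary_labels(labels)
  stopifnot(reps >= 100L)
  est <- std_pauc_scores(scores, y, axis, range)
  vals <- with_seed(seed, vapply(seq_len(reps), function(i) {
    idx <- boot_indices(y)
    std_pauc_scores(scores[idx], y[idx], axis, range)
  }, numeric(1)))
  qs <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(estimate = est, ci_low = qs[1], ci_high = qs[2],
       method = "percentile bootstrap", conf = conf, reps = reps)
}

# Metric dispatcher used by the ranking/selection module.
roc_metric <- function(scores, labels, target = c("full_auc",
                       "pauc_specificity", "pauc_sensitivity"),
                       range = c(0.9, 1)) {
  target <- match.arg(target)
  switch(target,
    full_auc = auc(roc_curve(scores, labels)),
    pauc_specificity = std_pauc_scores(scores, labels, "specificity", range),
    pauc_sensitivity = std_pauc_scores(scores, labels, "sensitivity", range))
}
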