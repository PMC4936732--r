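#' Cramer's V association between two categorical variables
#'
#' Bias-uncorrected Cramer's V from the Pearson chi-squared statistic of
#' the contingency table; 0 = independence, 1 = perfect association.
#'
#' @param x,y factors or vectors coercible to factors, same length.
#' @return scalar in [0, 1].
#' @export
cramers_v <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  k <- min(nrow(tab), ncol(tab)) - 1L
  as.numeric(sqrt(chi2 / (n * k)))
}
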