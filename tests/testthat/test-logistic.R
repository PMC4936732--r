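# Design encoding, logistic fits, cross validation, Nagelkerke, AIC.

make_crash_cohort <- function(n = 1500, seed = 101) {
  sample_cohort(calibrate(default_truth(1), tol = 1e-4), n, seed = seed)
}

# glm-free predictor for the holdout oracle (NA coefficients dropped)
predict_logistic_test <- function(fit, x) {
  beta <- c(fit$intercept, fit$coefficients)
  beta[is.na(beta)] <- 0
  as.vector(plogis(cbind(1, x) %*% beta))
}

test_that("design matrix uses reference coding with the documented width", {
  coh <- make_crash_cohort(400)
  d <- encode_design(coh)
  expect_identical(ncol(d$x), 29L)
  expect_identical(length(d$block_map), 13L)
  d1 <- encode_design(coh, "sex")
  expect_identical(ncol(d1$x), 1L)
  expect_identical(colnames(d1$x), "sex=female")
  # reference category rows are all zero in their block
  ref_rows <- coh$motor == "no response"
  expect_true(any(ref_rows))
  expect_true(all(d$x[ref_rows, d$block_map$motor] == 0))
  # degenerate block is refused
  coh2 <- coh; coh2$sex[] <- "male"
  expect_error(encode_design(coh2, "sex"), "single observed category")
})

test_that("logistic fit reproduces the 2x2 closed form and the intercept-only logit", {
  # 2x2 cell counts: exposed/unexposed x outcome
  counts <- list(c(40, 60), c(70, 30))  # (events, non-events) by x = 0, 1
  x <- c(rep(0, 100), rep(1, 100))
  y <- c(rep(1, 40), rep(0, 60), rep(1, 70), rep(0, 30))
  design <- structure(list(x = matrix(x, ncol = 1,
                                      dimnames = list(NULL, "x=1")), y = y),
                      class = "design_matrix")
  fit <- fit_logistic(design)
  log_or <- log((70 * 60) / (30 * 40))
  expect_equal(unname(fit$coefficients), log_or, tolerance = 1e-6)
  expect_equal(unname(fit$intercept), log(40 / 60), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood)

  null <- structure(list(x = matrix(numeric(0), 200, 0), y = y),
                    class = "design_matrix")
  nf <- fit_logistic(null)
  expect_equal(unname(nf$intercept), qlogis(mean(y)), tolerance = 1e-8)
})

test_that("null-data coefficients are near zero at large n", {
  set.seed(77)
  n <- 4000
  x <- matrix(rbinom(3 * n, 1, 0.5), n, 3,
              dimnames = list(NULL, paste0("v", 1:3, "=1")))
  y <- rbinom(n, 1, 0.4)
  fit <- fit_logistic(structure(list(x = x, y = y), class = "design_matrix"))
  se_approx <- sqrt(1 / (n * 0.25 * 0.4 * 0.6))
  expect_true(all(abs(fit$coefficients) < 4 * se_approx))
})

test_that("cross validation partitions per cycle and pairs splits across subsets", {
  coh <- make_crash_cohort(600)
  cv <- cv_predict(coh, folds = 5, cycles = 2, split_seed = 33)
  # each record predicted exactly once per cycle
  tab <- table(cv$record, cv$cycle)
  expect_true(all(tab == 1))
  expect_true(all(cv$prob > 0 & cv$prob < 1))
  # identical fold memberships for different predictor subsets
  cv2 <- cv_predict(coh, c("age", "motor"), folds = 5, cycles = 2,
                    split_seed = 33)
  expect_identical(attr(cv, "folds_matrix"), attr(cv2, "folds_matrix"))
})

test_that("pooled CV AUC agrees with an independent holdout evaluation", {
  model <- planted_model(n_strong = 2, n_null = 4)
  coh <- sample_cohort(model, 5000, seed = 55)
  cv <- cv_predict(coh, folds = 5, cycles = 2, split_seed = 56)
  cv_auc <- auc(roc_curve(cv$prob, cv$outcome))
  # train once on the full cohort, evaluate on a fresh large holdout
  fit <- fit_logistic(encode_design(coh))
  hold <- sample_cohort(model, 20000, seed = 57)
  dh <- encode_design(hold)
  hold_auc <- auc(roc_curve(predict_logistic_test(fit, dh$x),
                            outcome_binary(hold)))
  expect_lt(abs(cv_auc - hold_auc), 0.02)
})

test_that("Nagelkerke R2 spans [0, 1] with the documented anchors", {
  coh <- make_crash_cohort(500)
  null <- tbirank:::fit_null(coh)
  expect_equal(nagelkerke_r2(null, null), 0)
  # perfect separation limit: ll_full -> 0 gives R2 -> 1
  perfect <- structure(list(log_likelihood = 0, n = null$n), class = "fitted_logistic")
  expect_equal(nagelkerke_r2(perfect, null), 1)
  # toy data (non-separable): direct evaluation of both likelihoods via optim
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  x <- c(2, 1, 3, 0, 1, 2, 4, 0)
  d <- structure(list(x = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                      y = y), class = "design_matrix")
  full <- fit_logistic(d)
  nl <- fit_logistic(structure(list(x = matrix(numeric(0), 8, 0), y = y),
                               class = "design_matrix"))
  nll <- function(b) -sum(dbinom(y, 1, plogis(b[1] + b[2] * x), log = TRUE))
  ll_full <- -optim(c(0, 0), nll, method = "BFGS")$value
  ll_null <- -optimize(function(b) -sum(dbinom(y, 1, plogis(b), log = TRUE)),
                       c(-5, 5))$objective
  r2_oracle <- (1 - exp(2 * (ll_null - ll_full) / 8)) /
               (1 - exp(2 * ll_null / 8))
  expect_equal(nagelkerke_r2(full, nl), r2_oracle, tolerance = 1e-4)
  # monotone non-decreasing as predictors are added
  coh2 <- sample_cohort(planted_model(2, 3), 2000, seed = 60)
  nul2 <- tbirank:::fit_null(coh2)
  r2 <- vapply(list("s1", c("s1", "s2"), c("s1", "s2", "n1")), function(p)
    nagelkerke_r2(fit_logistic(encode_design(coh2, p)), nul2), numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("Nagelkerke drop ranking surfaces planted signal and zeroes nulls", {
  coh <- sample_cohort(planted_model(1, 5, beta = 2.8), 4000, seed = 70)
  rk <- nagelkerke_drop_ranking(coh)
  expect_identical(rk$predictor[1], "s1")
  expect_true(all(abs(rk$drop[rk$predictor != "s1"]) < 0.01))
  expect_identical(rk$rank, seq_len(nrow(rk)))
})

test_that("AIC backward elimination prunes noise, keeps signal, and stops at a local optimum", {
  coh <- sample_cohort(planted_model(2, 4, beta = 2.6), 3000, seed = 80)
  res <- aic_backward_eliminate(coh)
  expect_true(all(c("s1", "s2") %in% res$final_predictors))
  expect_true(length(res$final_predictors) < 6)  # some nulls eliminated
  # stopping contract: no single removal improves the final AIC
  for (v in res$final_predictors) {
    alt <- fit_logistic(encode_design(coh, setdiff(res$final_predictors, v)))$aic
    expect_gte(alt, res$final_aic)
  }
  # strongly informative-only model keeps everything
  coh2 <- sample_cohort(planted_model(3, 0, beta = 2.5), 3000, seed = 81)
  res2 <- aic_backward_eliminate(coh2)
  expect_setequal(res2$final_predictors, c("s1", "s2", "s3"))
})
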