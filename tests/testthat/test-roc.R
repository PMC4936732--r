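# ROC curves, AUC, partial AUC, standardization, DeLong, bootstrap.

test_that("ROC curve handles ties, perfection and the worked example", {
  # all scores tied: two-point diagonal, AUC 0.5
  rc <- roc_curve(rep(0.3, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(auc(rc), 0.5)
  # scores equal to labels: perfect
  y <- c(0, 0, 1, 1)
  expect_equal(auc(roc_curve(y, y)), 1)
  # classic 4-record example: pair counting gives 0.75
  sc <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(auc(roc_curve(sc, y)), 0.75)
  expect_equal(oracle_auc_paircount(sc, y), 0.75)
  # endpoints present, monotone ordering
  expect_equal(rc$sp[1], 0); expect_equal(rc$se[1], 1)
  expect_equal(rc$sp[length(rc$sp)], 1); expect_equal(rc$se[length(rc$se)], 0)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting to 1e-12", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    sc <- round(rnorm(n, mean = 0.5 * y), sample(c(1, 2, 8), 1)) # force ties
    expect_equal(auc(roc_curve(sc, y)), oracle_auc_paircount(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("flipping scores mirrors the AUC and random scores sit at chance", {
  set.seed(7)
  y <- rbinom(300, 1, 0.5); sc <- rnorm(300, y)
  expect_equal(auc(roc_curve(-sc, y)), 1 - auc(roc_curve(sc, y)),
               tolerance = 1e-12)
  n <- 2000
  y2 <- rbinom(n, 1, 0.5); sc2 <- rnorm(n)
  se <- sqrt(1 / 12 * (1 / sum(y2 == 1) + 1 / sum(y2 == 0)))  # null AUC SE
  expect_lt(abs(auc(roc_curve(sc2, y2)) - 0.5), 3 * se)
})

test_that("partial AUC matches fine-grid integration and analytic anchors", {
  # perfect classifier: rectangle of height 1
  y <- c(rep(0, 30), rep(1, 30))
  perfect <- roc_curve(as.numeric(y), y)
  expect_equal(pauc(perfect, "specificity", c(0.9, 1)), 0.1, tolerance = 1e-12)
  # chance diagonal: analytic 0.005 over [0.9, 1]
  chance <- roc_curve(rep(1, 60), y)
  expect_equal(pauc(chance, "specificity", c(0.9, 1)), 0.005,
               tolerance = 1e-12)
  # arbitrary empirical curves vs the grid oracle, both axes
  set.seed(11)
  for (i in 1:20) {
    yy <- rbinom(150, 1, 0.45)
    if (length(unique(yy)) < 2) next
    sc <- round(rnorm(150, 0.8 * yy), 2)
    rc <- roc_curve(sc, yy)
    for (axis in c("specificity", "sensitivity")) {
      for (rg in list(c(0.9, 1), c(0.75, 0.95), c(0, 1))) {
        expect_equal(pauc(rc, axis, rg),
                     oracle_pauc_grid(sc, yy, axis, rg),
                     tolerance = 1e-9,
                     label = sprintf("pauc %s [%g,%g] rep %d", axis,
                                     rg[1], rg[2], i))
      }
    }
    # pauc over the whole interval is exactly the AUC
    expect_equal(pauc(rc, "specificity", c(0, 1)), auc(rc),
                 tolerance = 1e-12)
    # transposition identity
    expect_equal(pauc(rc, "sensitivity", c(0.9, 1)),
                 pauc(roc_curve(-sc, 1 - yy), "specificity", c(0.9, 1)),
                 tolerance = 1e-12)
  }
})

test_that("partial AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(400, 1, 0.4); sc <- rnorm(400, y)
  pr <- pROC::roc(y, sc, quiet = TRUE)
  expect_equal(auc(roc_curve(sc, y)), as.numeric(pROC::auc(pr)),
               tolerance = 1e-10)
  expect_equal(pauc(roc_curve(sc, y), "specificity", c(0.9, 1)),
               as.numeric(pROC::auc(pr, partial.auc = c(1, 0.9),
                                    partial.auc.focus = "specificity")),
               tolerance = 1e-10)
  expect_equal(std_pauc <- as.numeric(standardize_pauc(
                 pauc(roc_curve(sc, y), "sensitivity", c(0.9, 1)), c(0.9, 1))),
               as.numeric(pROC::auc(pr, partial.auc = c(1, 0.9),
                                    partial.auc.focus = "sensitivity",
                                    partial.auc.correct = TRUE)),
               tolerance = 1e-10)
})

test_that("McClish standardization maps chance to 0.5, perfection to 1, linearly", {
  for (rg in list(c(0.9, 1), c(0.5, 0.8), c(0, 1))) {
    width <- diff(rg)
    min_a <- width - (rg[2]^2 - rg[1]^2) / 2
    expect_equal(as.numeric(standardize_pauc(min_a, rg)), 0.5)
    expect_equal(as.numeric(standardize_pauc(width, rg)), 1)
    expect_equal(as.numeric(standardize_pauc((min_a + width) / 2, rg)), 0.75)
    # strictly increasing in the raw area
    raws <- seq(min_a * 0.5, width, length.out = 9)
    vals <- vapply(raws, function(r) as.numeric(standardize_pauc(r, rg)),
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  below <- standardize_pauc(0.001, c(0.9, 1))
  expect_lt(as.numeric(below), 0.5)
  expect_true(attr(below, "below_chance"))
})

test_that("DeLong test matches its reference implementation and self-comparison is null", {
  set.seed(5)
  y <- rbinom(250, 1, 0.4)
  a <- rnorm(250, y); b <- 0.5 * a + rnorm(250, 0.6 * y)
  self <- delong_test(a, a, y)
  expect_equal(self$estimate, 0)
  expect_equal(self$p_value, 1)
  expect_error(delong_test(a, b[-1], y), "paired")

  skip_if_not_installed("pROC")
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$statistic, as.numeric(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(sqrt(delong_auc_variance(a, y)),
               sqrt(pROC::var(pROC::roc(y, a, quiet = TRUE), method = "delong")),
               tolerance = 1e-8)
})

test_that("DeLong single-AUC variance shrinks with sample size", {
  set.seed(9)
  v <- vapply(c(100, 1000, 10000), function(n) {
    y <- rbinom(n, 1, 0.5); sc <- rnorm(n, y)
    delong_auc_variance(sc, y)
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[3], 1e-4)
})

test_that("bootstrap pAUC comparison is null for identical models and powered for real gaps", {
  set.seed(15)
  y <- rbinom(600, 1, 0.45); a <- rnorm(600, y)
  same <- bootstrap_pauc_test(a, a, y, reps = 200, seed = 31)
  expect_equal(same$p_value, 1)
  # planted difference: strong vs weak model
  n <- 2000
  y2 <- rbinom(n, 1, 0.45)
  strong <- rnorm(n, 1.65 * y2)   # AUC about 0.88
  weak <- rnorm(n, 0.35 * y2)     # AUC about 0.60
  pw <- bootstrap_pauc_test(strong, weak, y2, "specificity", c(0.9, 1),
                            reps = 400, seed = 32)
  expect_lt(pw$p_value, 0.01)
  expect_identical(bootstrap_pauc_test(strong, weak, y2, reps = 150, seed = 7)$p_value,
                   bootstrap_pauc_test(strong, weak, y2, reps = 150, seed = 7)$p_value)
})

test_that("percentile bootstrap CI brackets the estimate and is seed-stable", {
  set.seed(20)
  y <- rbinom(500, 1, 0.4); sc <- rnorm(500, y)
  ci <- pauc_ci(sc, y, "specificity", c(0.9, 1), reps = 300, seed = 44)
  expect_lte(ci$ci_low, ci$estimate)
  expect_gte(ci$ci_high, ci$estimate)
  ci2 <- pauc_ci(sc, y, "specificity", c(0.9, 1), reps = 300, seed = 44)
  expect_identical(ci, ci2)
})
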