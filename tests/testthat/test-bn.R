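# Bayesian networks: scoring, structure search, CPTs, inference, sampling.

test_that("DAG construction enforces acyclicity and edge uniqueness", {
  expect_no_error(dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))))
  expect_error(dag(c("A", "B"), rbind(c("A", "B"), c("B", "A"))), "cyclic")
  expect_error(dag(c("A", "B"), rbind(c("A", "B"), c("A", "B"))), "duplicate")
  expect_error(dag(c("A", "B"), rbind(c("A", "A"))))
})

test_that("BIC prefers the empty graph on independent data and is score-equivalent", {
  set.seed(30)
  d <- data.frame(A = factor(sample(c("a1", "a2"), 800, TRUE)),
                  B = factor(sample(c("b1", "b2"), 800, TRUE)),
                  C = factor(sample(c("c1", "c2"), 800, TRUE)))
  dags <- oracle_all_3node_dags(names(d))
  expect_length(dags, 25)
  scores <- vapply(dags, bic_score, numeric(1), data = d)
  empty <- which(vapply(dags, function(g) nrow(g$edges) == 0, logical(1)))
  expect_identical(which.max(scores), empty)
  # likelihood term never decreases with an extra parent
  fb <- function(v, pa) tbirank:::family_bic(v, pa, d) +
    0.5 * (nlevels(d[[v]]) - 1) *
      prod(vapply(pa, function(p) nlevels(d[[p]]), numeric(1)), 1) *
      log(nrow(d))
  expect_gte(fb("B", "A"), fb("B", character(0)))
  # A -> B scores identically to B -> A (same equivalence class)
  gab <- dag(names(d), rbind(c("A", "B")))
  gba <- dag(names(d), rbind(c("B", "A")))
  expect_equal(bic_score(gab, d), bic_score(gba, d), tolerance = 1e-9)
})

test_that("hill climbing recovers a planted chain's equivalence class", {
  m <- chain_model()
  d <- sample_bn(as_bn(m), 10000, seed = 40)
  learned <- hill_climb(d, seed = 41)
  # oracle: exhaustively score all 25 three-node DAGs
  dags <- oracle_all_3node_dags(names(d))
  scores <- vapply(dags, bic_score, numeric(1), data = d)
  best <- dags[[which.max(scores)]]
  expect_equal(attr(learned, "score"), max(scores), tolerance = 1e-9)
  expect_equal(equiv_class_of(learned), equiv_class_of(best))
  expect_equal(equiv_class_of(learned),
               equiv_class_of(dag(names(d), rbind(c("A", "B"), c("B", "C")))))
})

test_that("constraints are honored and independence yields the bare whitelist", {
  set.seed(52)
  d <- data.frame(A = factor(sample(c("a1", "a2"), 1500, TRUE)),
                  B = factor(sample(c("b1", "b2"), 1500, TRUE)),
                  C = factor(sample(c("c1", "c2"), 1500, TRUE)))
  wl <- rbind(c("B", "C"))
  g <- hill_climb(d, constraints = edge_constraints(whitelist = wl), seed = 51)
  expect_true(any(g$edges[, 1] == "B" & g$edges[, 2] == "C"))
  expect_identical(nrow(g$edges), 1L)  # nothing beyond the whitelist
  g0 <- hill_climb(d, seed = 51)
  # unconstrained search agrees with exhaustive scoring, here the empty graph
  dags <- oracle_all_3node_dags(names(d))
  expect_equal(attr(g0, "score"),
               max(vapply(dags, bic_score, numeric(1), data = d)),
               tolerance = 1e-9)
  expect_identical(nrow(g0$edges), 0L)
  expect_error(edge_constraints(whitelist = wl, blacklist = wl), "overlap")
  expect_error(hill_climb(d, constraints = edge_constraints(
    whitelist = rbind(c("A", "B"), c("B", "A"))), seed = 1), "cyclic")
  # final score never below the whitelist-only graph's score
  expect_gte(attr(g, "score"), bic_score(dag(names(d), wl), d))
})

test_that("CPT estimation matches frequencies, smoothing, and recovers parameters", {
  d1 <- data.frame(X = factor(rep(c("x1", "x2", "x3"), c(2, 3, 5))))
  bn1 <- fit_cpts(dag("X"), d1)
  expect_equal(as.numeric(bn1$cpts$X), c(0.2, 0.3, 0.5))
  # unseen parent configuration with Laplace smoothing -> uniform
  d2 <- data.frame(P = factor(c("p1", "p1"), levels = c("p1", "p2")),
                   X = factor(c("x1", "x2"), levels = paste0("x", 1:4)))
  bn2 <- fit_cpts(dag(c("P", "X"), rbind(c("P", "X"))), d2, smoothing = 1)
  expect_equal(as.numeric(bn2$cpts$X[, "p2"]), rep(0.25, 4))
  # unseen configuration without smoothing -> flagged uniform
  bn3 <- fit_cpts(dag(c("P", "X"), rbind(c("P", "X"))), d2)
  expect_equal(as.numeric(bn3$cpts$X[, "p2"]), rep(0.25, 4))
  expect_identical(attr(bn3$cpts$X, "uniform_configs"), 1L)
  # parameter recovery at n = 1e5
  truth <- as_bn(chain_model(p_root = 0.62, p_stay = 0.8))
  d3 <- sample_bn(truth, 1e5, seed = 61)
  est <- fit_cpts(truth$dag, d3)
  err <- max(vapply(truth$dag$nodes, function(v)
    max(abs(est$cpts[[v]] - truth$cpts[[v]])), numeric(1)))
  expect_lt(err, 0.01)
})

test_that("variable elimination matches brute-force enumeration", {
  # hand cases on a chain
  truth <- as_bn(chain_model())
  expect_equal(unname(query(truth, "A")), as.numeric(truth$cpts$A))
  expect_equal(unname(query(truth, "B", list(A = "a1"))),
               as.numeric(truth$cpts$B[, "a1"]))
  # a 6-node network with a collider, random CPTs
  set.seed(70)
  nodes <- paste0("V", 1:6)
  g <- dag(nodes, rbind(c("V1", "V3"), c("V2", "V3"), c("V3", "V4"),
                        c("V4", "V5"), c("V2", "V6")))
  lv <- setNames(lapply(c(2, 3, 2, 3, 2, 2), function(k) paste0("l", 1:k)),
                 nodes)
  cpts <- lapply(nodes, function(v) {
    pa <- parents_of_test(g, v)
    dims <- c(length(lv[[v]]), vapply(pa, function(p) length(lv[[p]]),
                                      integer(1)))
    val <- array(runif(prod(dims)) + 0.1, dim = dims,
                 dimnames = c(setNames(list(lv[[v]]), v), lv[pa]))
    m <- matrix(val, nrow = dims[1])
    m <- sweep(m, 2, colSums(m), `/`)
    array(m, dim = dims, dimnames = dimnames(val))
  })
  names(cpts) <- nodes
  bn <- structure(list(dag = g, cpts = cpts, levels = lv, n_fit = NA),
                  class = "param_bn")
  cases <- list(list(t = "V5", e = list()),
                list(t = "V1", e = list(V5 = "l2")),
                list(t = "V3", e = list(V1 = "l1", V6 = "l2")),
                list(t = "V6", e = list(V3 = "l2", V5 = "l1", V1 = "l2")))
  for (cs in cases) {
    expect_equal(unname(query(bn, cs$t, cs$e)),
                 oracle_bn_query(bn, cs$t, cs$e), tolerance = 1e-12)
  }
  expect_error(query(bn, "V3", list(V1 = "nope")), "invalid evidence")
})

test_that("forward sampling is seed-stable and consistent with exact queries", {
  truth <- as_bn(chain_model(p_root = 0.7, p_stay = 0.85))
  expect_identical(sample_bn(truth, 40, seed = 80),
                   sample_bn(truth, 40, seed = 80))
  n <- 1e5
  d <- sample_bn(truth, n, seed = 81)
  for (v in truth$dag$nodes) {
    p <- unname(query(truth, v))
    phat <- as.numeric(prop.table(table(d[[v]])))
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(phat - p) <= 3 * se + 1e-12))
  }
  # single-node network: iid categorical draws
  one <- structure(list(dag = dag("X"),
                        cpts = list(X = array(c(0.3, 0.7), 2,
                                              dimnames = list(X = c("x1", "x2")))),
                        levels = list(X = c("x1", "x2")), n_fit = NA),
                   class = "param_bn")
  s <- sample_bn(one, 5000, seed = 82)
  expect_lt(abs(mean(s$X == "x1") - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("every accepted hill-climbing move strictly improves the score", {
  m <- chain_model()
  d <- sample_bn(as_bn(m), 3000, seed = 90)
  g <- hill_climb(d, seed = 91, restarts = 1)
  # removing or reversing any learned edge lowers the score
  for (i in seq_len(nrow(g$edges))) {
    del <- g$edges[-i, , drop = FALSE]
    expect_lt(bic_score(dag(g$nodes, del), d), attr(g, "score"))
  }
})
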