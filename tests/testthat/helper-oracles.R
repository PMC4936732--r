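# Independent oracles used across test files.  These deliberately take the
# brute-force / enumeration route and never call the implementation paths
# they are checking.

# Mann-Whitney pair counting with half credit for ties.
oracle_auc_paircount <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Partial area by midpoint-rule integration on a fine grid (split at the
# curve's knots, so the rule is exact on each linear piece) of the
# empirical ROC path, built directly from threshold sweeps rather than
# from the package's roc_points representation.  At a vertical run the
# path leaves from the run's bottom and arrives at the next run's top.
oracle_pauc_grid <- function(scores, y, axis = "specificity",
                             range = c(0.9, 1), grid_n = 1e5) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  th <- sort(unique(scores))
  se <- c(1, vapply(th, function(t) mean(pos > t) + 0, numeric(1)))
  sp <- c(0, vapply(th, function(t) mean(neg <= t) + 0, numeric(1)))
  if (axis == "specificity") { xs <- sp; ys <- se } else { xs <- se; ys <- sp }
  ux <- sort(unique(xs))
  ytop <- vapply(ux, function(x) max(ys[xs == x]), numeric(1))
  ybot <- vapply(ux, function(x) min(ys[xs == x]), numeric(1))
  f <- function(x) { # x strictly between knots
    i <- findInterval(x, ux)
    ybot[i] + (ytop[i + 1] - ybot[i]) * (x - ux[i]) / (ux[i + 1] - ux[i])
  }
  breaks <- sort(unique(c(seq(range[1], range[2], length.out = grid_n),
                          ux[ux > range[1] & ux < range[2]])))
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  sum(diff(breaks) * f(mids))
}

# Full joint distribution of a param_bn by enumeration.
oracle_bn_joint <- function(bn) {
  grid <- expand.grid(bn$levels[bn$dag$nodes], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    vars <- names(dimnames(cpt))
    idx <- mapply(function(w) match(grid[[w]], bn$levels[[w]]), vars)
    if (!is.matrix(idx)) idx <- matrix(idx, ncol = length(vars))
    lin <- 1 + (idx - 1) %*% cumprod(c(1, head(dim(cpt), -1)))
    p <- p * as.vector(cpt)[lin]
  }
  cbind(grid, prob = p)
}

# Conditional query by enumeration.
oracle_bn_query <- function(bn, target, evidence = list()) {
  jt <- oracle_bn_joint(bn)
  for (v in names(evidence)) jt <- jt[jt[[v]] == evidence[[v]], ]
  p <- tapply(jt$prob, factor(jt[[target]], levels = bn$levels[[target]]), sum)
  p[is.na(p)] <- 0
  as.numeric(p / sum(p))
}

# All DAGs on the given 3 nodes (there are 25), as edge matrices.
oracle_all_3node_dags <- function(nodes) {
  stopifnot(length(nodes) == 3)
  pairs <- t(combn(nodes, 2))
  states <- expand.grid(e1 = 0:2, e2 = 0:2, e3 = 0:2)  # 0 none, 1 fwd, 2 rev
  out <- list()
  for (i in seq_len(nrow(states))) {
    edges <- NULL
    for (j in 1:3) {
      s <- states[i, j]
      if (s == 1) edges <- rbind(edges, pairs[j, ])
      if (s == 2) edges <- rbind(edges, rev(pairs[j, ]))
    }
    g <- tryCatch(dag(nodes, edges), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# Markov-equivalence fingerprint: skeleton + v-structures.
equiv_class_of <- function(g) {
  e <- g$edges
  skel <- if (nrow(e)) sort(paste(pmin(e[, 1], e[, 2]),
                                  pmax(e[, 1], e[, 2]))) else character(0)
  vs <- character(0)
  for (v in g$nodes) {
    pa <- sort(parents_of_test(g, v))
    if (length(pa) >= 2) {
      cmb <- t(combn(pa, 2))
      for (i in seq_len(nrow(cmb))) {
        a <- cmb[i, 1]; b <- cmb[i, 2]
        adj <- paste(pmin(a, b), pmax(a, b)) %in% skel
        if (!adj) vs <- c(vs, paste(a, "->", v, "<-", b))
      }
    }
  }
  list(skeleton = skel, v_structures = sort(vs))
}

parents_of_test <- function(g, v) g$edges[g$edges[, 2] == v, 1]
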