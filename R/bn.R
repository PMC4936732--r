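# Discrete Bayesian networks: structure scoring and search, parameter
# estimation, exact inference, forward sampling.

#' Directed acyclic graph
#'
#' @param nodes character vector of variable names.
#' @param edges two-column character matrix (from, to); may have zero rows.
#' @return object of class \code{dag}.
#' @export
dag <- function(nodes, edges = matrix(character(), 0, 2)) {
  edges <- as_edge_matrix(edges)
  stopifnot(all(edges %in% nodes), !any(edges[, 1] == edges[, 2]))
  if (anyDuplicated(paste(edges[, 1], edges[, 2])))
    stop("duplicate edges")
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  if (is.null(topo_sort(g))) stop("graph is cyclic")
  g
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0) return(matrix(character(), 0, 2))
  m <- matrix(as.character(edges), ncol = 2)
  colnames(m) <- c("from", "to")
  m
}

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  invisible(x)
}

parents_of <- function(g, v) g$edges[g$edges[, 2] == v, 1]

# Kahn's algorithm; NULL when cyclic.
topo_sort <- function(g) {
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(g$edges))) {
    to <- g$edges[i, 2]
    indeg[to] <- indeg[to] + 1L
  }
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    ch <- g$edges[g$edges[, 1] == v, 2]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

# Is there a directed path from `from` to `to`?
has_path <- function(g, from, to) {
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    v <- frontier[1L]; frontier <- frontier[-1L]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, g$edges[g$edges[, 1] == v, 2])
  }
  FALSE
}

#' Edge constraints for constrained structure search
#'
#' @param whitelist edges that must be present (two-column matrix or vector
#'   pairs), e.g. pre-fixed predictor-to-outcome edges.
#' @param blacklist directed edges that may never be added.
#' @return object of class \code{edge_constraints}.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL) {
  wl <- as_edge_matrix(whitelist); bl <- as_edge_matrix(blacklist)
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  if (length(intersect(key(wl), key(bl))))
    stop("whitelist and blacklist overlap")
  structure(list(whitelist = wl, blacklist = bl), class = "edge_constraints")
}

# ---------------------------------------------------------------------------
# Scoring

# Per-family BIC component: max log-likelihood of `node` given `parents`
# minus 0.5 * free-parameters * log(N).  Decomposable; larger is better.
family_bic <- function(node, parents, data) {
  n_total <- nrow(data)
  k <- nlevels(data[[node]])
  if (!length(parents)) {
    cnt <- tabulate(as.integer(data[[node]]), nbins = k)
    nz <- cnt > 0
    ll <- sum(cnt[nz] * log(cnt[nz] / n_total))
    q <- 1L
  } else {
    cfg <- config_index(data, parents)
    q <- attr(cfg, "n_config")
    tab <- table(factor(cfg, levels = seq_len(q)), data[[node]])
    rs <- rowSums(tab)
    nz <- tab > 0
    ll <- sum(tab[nz] * log(tab[nz] / rs[row(tab)[nz]]))
  }
  ll - 0.5 * (k - 1) * q * log(n_total)
}

# Linear index of each record's parent configuration.
config_index <- function(data, parents) {
  idx <- rep(1L, nrow(data))
  stride <- 1L
  for (p in parents) {
    idx <- idx + (as.integer(data[[p]]) - 1L) * stride
    stride <- stride * nlevels(data[[p]])
  }
  structure(idx, n_config = stride)
}

#' BIC network score of a DAG for categorical data
#'
#' Sum over nodes of the family log-likelihood minus half the number of
#' free parameters times log(n).  Decomposable per node; larger is better.
#'
#' @param g a \code{dag} whose nodes are all columns of \code{data}.
#' @param data data.frame of factors.
#' @return scalar score.
#' @export
bic_score <- function(g, data) {
  stopifnot(all(g$nodes %in% names(data)))
  sum(vapply(g$nodes, function(v) family_bic(v, parents_of(g, v), data),
             numeric(1)))
}

# ---------------------------------------------------------------------------
# Hill-climbing search

#' Constrained hill-climbing structure search
#'
#' Greedy search over single-edge additions, deletions and reversals under
#' the BIC score, respecting acyclicity and edge constraints (whitelisted
#' edges are always present and are never deleted or reversed; blacklisted
#' edges are never added).  Only strictly improving moves are accepted; the
#' search stops at a local optimum.  With \code{restarts > 1} additional
#' searches start from random whitelist-consistent graphs and the best
#' final network is returned.  Deterministic given \code{seed}.
#'
#' @param data data.frame of factors.
#' @param nodes nodes to include; default all columns.
#' @param constraints an \code{\link{edge_constraints}} (or NULL).
#' @param restarts number of randomized restarts (>= 1); default 5.
#' @param seed integer seed (required).
#' @return the highest-scoring \code{dag} found, with attributes
#'   \code{score} and \code{moves} (accepted-move count of the winning run).
#' @export
hill_climb <- function(data, nodes = names(data), constraints = NULL,
                       restarts = 5L, seed) {
  constraints <- constraints %||% edge_constraints()
  wl <- constraints$whitelist; bl <- constraints$blacklist
  stopifnot(all(wl %in% nodes), all(bl %in% nodes))
  base <- dag(nodes, wl)  # errors if whitelist alone is cyclic
  blk <- paste(bl[, 1], bl[, 2], sep = "\r")
  wlk <- paste(wl[, 1], wl[, 2], sep = "\r")

  cache <- new.env(parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- family_bic(v, pa, data)
      cache[[key]] <- got
    }
    got
  }
  climb <- function(g) {
    fs <- stats::setNames(vapply(nodes, function(v) fam(v, parents_of(g, v)),
                                 numeric(1)), nodes)
    moves <- 0L
    repeat {
      best_delta <- 0; best <- NULL
      ek <- paste(g$edges[, 1], g$edges[, 2], sep = "\r")
      for (u in nodes) for (v in nodes) {
        if (u == v) next
        k <- paste(u, v, sep = "\r")
        present <- k %in% ek
        if (!present && !(k %in% blk) && !has_path(g, v, u)) {
          d <- fam(v, c(parents_of(g, v), u)) - fs[[v]]
          if (d > best_delta + 1e-9) { best_delta <- d; best <- list("add", u, v) }
        }
        if (present && !(k %in% wlk)) {
          d <- fam(v, setdiff(parents_of(g, v), u)) - fs[[v]]
          if (d > best_delta + 1e-9) { best_delta <- d; best <- list("del", u, v) }
          # reversal: u->v becomes v->u
          rk <- paste(v, u, sep = "\r")
          if (!(rk %in% blk)) {
            g2 <- g; g2$edges <- g2$edges[ek != k, , drop = FALSE]
            if (!has_path(g2, u, v)) {
              d <- (fam(v, setdiff(parents_of(g, v), u)) - fs[[v]]) +
                   (fam(u, c(parents_of(g, u), v)) - fs[[u]])
              if (d > best_delta + 1e-9) { best_delta <- d; best <- list("rev", u, v) }
            }
          }
        }
      }
      if (is.null(best)) break
      u <- best[[2]]; v <- best[[3]]
      ek <- paste(g$edges[, 1], g$edges[, 2], sep = "\r")
      if (best[[1]] == "add") {
        g$edges <- rbind(g$edges, c(u, v))
      } else if (best[[1]] == "del") {
        g$edges <- g$edges[ek != paste(u, v, sep = "\r"), , drop = FALSE]
      } else {
        g$edges <- rbind(g$edges[ek != paste(u, v, sep = "\r"), , drop = FALSE],
                         c(v, u))
      }
      fs[v] <- fam(v, parents_of(g, v))
      fs[u] <- fam(u, parents_of(g, u))
      moves <- moves + 1L
    }
    list(g = g, score = sum(fs), moves = moves)
  }

  random_start <- function() {
    g <- base
    pairs <- expand.grid(u = nodes, v = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$u != pairs$v, ]
    pairs <- pairs[sample.int(nrow(pairs)), ]
    for (i in seq_len(nrow(pairs))) {
      if (stats::runif(1) > 0.15) next
      u <- pairs$u[i]; v <- pairs$v[i]
      k <- paste(u, v, sep = "\r")
      ek <- paste(g$edges[, 1], g$edges[, 2], sep = "\r")
      if (k %in% ek || k %in% blk || has_path(g, v, u)) next
      g$edges <- rbind(g$edges, c(u, v))
    }
    g
  }

  with_seed(seed, {
    best <- climb(base)
    if (restarts > 1L) for (r in seq_len(restarts - 1L)) {
      res <- climb(random_start())
      if (res$score > best$score + 1e-9) best <- res
    }
    structure(best$g, score = best$score, moves = best$moves)
  })
}

# ---------------------------------------------------------------------------
# Parameters

#' Estimate conditional probability tables for a DAG
#'
#' Per-node conditional frequencies with an optional uniform pseudo-count.
#' Parent configurations unseen in the data (with zero smoothing) get the
#' uniform distribution and are counted in the \code{uniform_configs}
#' attribute of the table.
#'
#' @param g a \code{dag}.
#' @param data data.frame of factors covering the nodes.
#' @param smoothing pseudo-count added to every cell; default 0.
#' @return object of class \code{param_bn}: \code{dag}, \code{cpts} (per
#'   node, array with the node's categories as the first dimension and one
#'   dimension per parent), \code{levels}, \code{n_fit}.
#' @export
fit_cpts <- function(g, data, smoothing = 0) {
  lv <- lapply(data[g$nodes], levels)
  cpts <- lapply(g$nodes, function(v) {
    pa <- parents_of(g, v)
    k <- length(lv[[v]])
    if (!length(pa)) {
      cnt <- tabulate(as.integer(data[[v]]), nbins = k) + smoothing
      p <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(1 / k, k)
      array(p, dim = k, dimnames = stats::setNames(list(lv[[v]]), v))
    } else {
      dims <- c(k, lengths(lv[pa]))
      cnt <- array(smoothing, dim = dims,
                   dimnames = c(stats::setNames(list(lv[[v]]), v), lv[pa]))
      tab <- table(data[c(v, pa)])
      cnt <- cnt + as.numeric(tab)
      m <- matrix(cnt, nrow = k)
      cs <- colSums(m)
      empty <- cs == 0
      m[, empty] <- 1 / k
      m[, !empty] <- sweep(m[, !empty, drop = FALSE], 2, cs[!empty], `/`)
      structure(array(m, dim = dims, dimnames = dimnames(cnt)),
                uniform_configs = sum(empty))
    }
  })
  names(cpts) <- g$nodes
  structure(list(dag = g, cpts = cpts, levels = lv, n_fit = nrow(data)),
            class = "param_bn")
}

#' @export
print.param_bn <- function(x, ...) {
  cat(sprintf("Parameterized Bayesian network: %d nodes, %d edges, fitted on %s records\n",
              length(x$dag$nodes), nrow(x$dag$edges),
              if (is.na(x$n_fit %||% NA)) "?" else x$n_fit))
  invisible(x)
}

# Convert a forest-structured gen_model into a param_bn (shared engine).
#' Convert a generative model to a parameterized Bayesian network
#'
#' @param model a \code{gen_model}.
#' @return a \code{param_bn} over the model's predictors.
#' @export
as_bn <- function(model) {
  stopifnot(inherits(model, "gen_model"))
  nodes <- names(model$levels)
  edges <- do.call(rbind, lapply(nodes, function(v) {
    p <- model$parents[[v]]
    if (is.na(p)) NULL else c(p, v)
  }))
  g <- dag(nodes, edges %||% matrix(character(), 0, 2))
  cpts <- lapply(nodes, function(v) {
    p <- model$parents[[v]]
    if (is.na(p)) {
      array(model$cpts[[v]], dim = length(model$levels[[v]]),
            dimnames = stats::setNames(list(model$levels[[v]]), v))
    } else {
      array(t(model$cpts[[v]]),
            dim = c(length(model$levels[[v]]), length(model$levels[[p]])),
            dimnames = stats::setNames(list(model$levels[[v]],
                                            model$levels[[p]]), c(v, p)))
    }
  })
  names(cpts) <- nodes
  structure(list(dag = g, cpts = cpts, levels = model$levels, n_fit = NA),
            class = "param_bn")
}

# ---------------------------------------------------------------------------
# Exact inference by variable elimination

# factor representation: list(vars, val) with val an array, dim names = vars
factor_from_cpt <- function(bn, v) {
  cpt <- bn$cpts[[v]]
  list(vars = names(dimnames(cpt)), val = cpt)
}

factor_reduce <- function(f, var, value_idx) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- value_idx
  val <- do.call(`[`, c(list(f$val), idx, list(drop = FALSE)))
  newdim <- dim(val)[-pos]
  dn <- dimnames(val)[-pos]
  if (!length(newdim)) return(list(vars = character(0), val = as.numeric(val)))
  list(vars = f$vars[-pos], val = array(as.vector(val), newdim, dn))
}

factor_product <- function(f1, f2, levels) {
  if (!length(f1$vars)) return(list(vars = f2$vars, val = f2$val * as.numeric(f1$val)))
  if (!length(f2$vars)) return(list(vars = f1$vars, val = f1$val * as.numeric(f2$val)))
  vars <- union(f1$vars, f2$vars)
  lens <- vapply(levels[vars], length, integer(1))
  grid <- as.matrix(expand.grid(lapply(lens, seq_len), KEEP.OUT.ATTRS = FALSE))
  lin <- function(f) {
    sub <- grid[, match(f$vars, vars), drop = FALSE]
    stride <- cumprod(c(1, utils::head(dim(f$val), -1)))
    as.vector(1 + (sub - 1) %*% stride)
  }
  val <- array(as.vector(f1$val)[lin(f1)] * as.vector(f2$val)[lin(f2)],
               dim = lens, dimnames = stats::setNames(levels[vars], vars))
  list(vars = vars, val = val)
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (length(f$vars) == 1L)
    return(list(vars = character(0), val = sum(f$val)))
  val <- apply(f$val, seq_along(f$vars)[-pos], sum)
  if (!is.array(val))
    val <- array(val, dim = length(val),
                 dimnames = dimnames(f$val)[-pos])
  list(vars = f$vars[-pos], val = val)
}

#' Exact probability query by variable elimination
#'
#' Conditional distribution of a target variable given evidence, computed
#' by sum-product variable elimination over the network's CPT factors.
#'
#' @param bn a \code{param_bn}.
#' @param target variable name.
#' @param evidence named list/vector of category labels.
#' @return named probability vector over the target's categories.
#' @export
query <- function(bn, target, evidence = list()) {
  stopifnot(target %in% bn$dag$nodes, all(names(evidence) %in% bn$dag$nodes))
  evidence <- as.list(evidence)
  for (v in names(evidence)) {
    if (!(evidence[[v]] %in% bn$levels[[v]]))
      stop(sprintf("invalid evidence value '%s' for '%s'", evidence[[v]], v))
  }
  facs <- lapply(bn$dag$nodes, factor_from_cpt, bn = bn)
  for (v in names(evidence)) {
    k <- match(evidence[[v]], bn$levels[[v]])
    facs <- lapply(facs, factor_reduce, var = v, value_idx = k)
  }
  hidden <- setdiff(bn$dag$nodes, c(target, names(evidence)))
  hidden <- hidden[order(vapply(bn$levels[hidden], length, integer(1)))]
  for (h in hidden) {
    touch <- vapply(facs, function(f) h %in% f$vars, logical(1))
    if (!any(touch)) next
    prod <- Reduce(function(a, b) factor_product(a, b, bn$levels),
                   facs[touch])
    facs <- c(facs[!touch], list(factor_marginalize(prod, h)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, bn$levels), facs)
  if (!identical(res$vars, target)) {
    # reorder (target must be the only remaining variable)
    stopifnot(setequal(res$vars, target))
  }
  p <- as.numeric(res$val)
  if (sum(p) <= 0)
    stop("evidence has zero probability under the network: ",
         paste(names(evidence), unlist(evidence), sep = "=", collapse = ", "))
  stats::setNames(p / sum(p), bn$levels[[target]])
}

# ---------------------------------------------------------------------------
# Sampling

#' Forward (ancestral) sampling from a parameterized network
#'
#' @param bn a \code{param_bn}.
#' @param n number of records (>= 1).
#' @param seed integer seed (required).
#' @return data.frame of factors, one column per node.
#' @export
sample_bn <- function(bn, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, sample_bn_impl(bn, n))
}

sample_bn_impl <- function(bn, n) {
  ord <- topo_sort(bn$dag)
  df <- vector("list", length(ord)); names(df) <- ord
  for (v in ord) {
    pa <- parents_of(bn$dag, v)
    k <- length(bn$levels[[v]])
    cpt <- bn$cpts[[v]]
    if (!length(pa)) {
      pm <- matrix(as.vector(cpt), n, k, byrow = TRUE)
    } else {
      # CPT dims: (node, parents in dimnames order)
      pa_ord <- names(dimnames(cpt))[-1]
      cfg <- rep(1L, n); stride <- 1L
      for (p in pa_ord) {
        cfg <- cfg + (as.integer(df[[p]]) - 1L) * stride
        stride <- stride * length(bn$levels[[p]])
      }
      m <- matrix(as.vector(cpt), nrow = k)  # k x n_config
      pm <- t(m)[cfg, , drop = FALSE]
    }
    u <- stats::runif(n)
    cum <- pm %*% upper.tri(diag(k), diag = TRUE)
    cat_idx <- rowSums(u > cum) + 1L
    cat_idx[cat_idx > k] <- k
    df[[v]] <- factor(bn$levels[[v]][cat_idx], levels = bn$levels[[v]])
  }
  as.data.frame(df, stringsAsFactors = FALSE)[names(bn$levels)]
}

#' Export a DAG as DOT text
#'
#' @param g a \code{dag}.
#' @param highlight nodes to render with emphasis (e.g. key predictors).
#' @return character scalar of DOT source.
#' @export
dag_to_dot <- function(g, highlight = character()) {
  lines <- c("digraph bn {",
             paste0('  "', g$nodes, '"',
                    ifelse(g$nodes %in% highlight,
                           " [style=filled, fillcolor=salmon]", ""), ";"),
             if (nrow(g$edges))
               paste0('  "', g$edges[, 1], '" -> "', g$edges[, 2], '";'),
             "}")
  paste(lines, collapse = "\n")
}
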