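#' Generative model for synthetic admission cohorts
#'
#' A \code{gen_model} is a forest-structured discrete Bayesian network over
#' the predictor variables (each node has at most one parent) plus a
#' logistic outcome mechanism: the log-odds of poor outcome is an intercept
#' plus one additive per-category offset per predictor.  The restriction to
#' one parent keeps exact marginalization and calibration closed-form while
#' still planting recoverable dependence for the downstream structure
#' learner.
#'
#' @param levels named list: variable -> ordered character vector of
#'   categories.
#' @param parents named list: variable -> parent variable name or \code{NA}.
#' @param cpts named list: for a root, a probability vector over its
#'   categories; for a child, a matrix with one row per parent category and
#'   one column per own category (rows sum to 1).
#' @param outcome_coefficients named list: variable -> numeric vector of
#'   per-category log-odds offsets (same order as \code{levels}).
#' @param outcome_intercept scalar log-odds.
#' @return object of class \code{gen_model}.
#' @export
gen_model <- function(levels, parents, cpts, outcome_coefficients,
                      outcome_intercept = 0) {
  vars <- names(levels)
  stopifnot(setequal(vars, names(parents)), setequal(vars, names(cpts)),
            setequal(vars, names(outcome_coefficients)))
  ord <- topo_order_forest(parents)
  for (v in vars) {
    k <- length(levels[[v]])
    cpt <- cpts[[v]]
    if (is.na(parents[[v]])) {
      stopifnot(length(cpt) == k, abs(sum(cpt) - 1) < 1e-9)
    } else {
      p <- parents[[v]]
      stopifnot(is.matrix(cpt), ncol(cpt) == k,
                nrow(cpt) == length(levels[[p]]),
                all(abs(rowSums(cpt) - 1) < 1e-9))
    }
    stopifnot(length(outcome_coefficients[[v]]) == k)
  }
  structure(list(levels = levels, parents = parents, order = ord,
                 cpts = cpts, outcome_coefficients = outcome_coefficients,
                 outcome_intercept = outcome_intercept),
            class = "gen_model")
}

# Topological order of a forest given parent pointers; errors on cycles.
topo_order_forest <- function(parents) {
  vars <- names(parents)
  placed <- character()
  remaining <- vars
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      p <- parents[[v]]
      is.na(p) || p %in% placed
    }, logical(1))]
    if (!length(ready)) stop("parent structure is cyclic")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' @export
print.gen_model <- function(x, ...) {
  ne <- sum(!vapply(x$parents, is.na, logical(1)))
  cat(sprintf("Generative model: %d variables, %d edges, outcome intercept %.4f\n",
              length(x$levels), ne, x$outcome_intercept))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Calibration targets

#' Calibration targets from the published complete-case frequency table
#'
#' Target marginal distributions for the 13 predictors and the poor-outcome
#' rate.  Each non-reference category is pinned at its published
#' complete-case percentage; because the source table's within-variable
#' percentages sum to slightly under 100, the shortfall (about 0.4%) is
#' absorbed by the last listed category of each variable.
#'
#' @return list with elements \code{marginals} (named list of probability
#'   vectors) and \code{poor_rate} (scalar).
#' @export
table1_targets <- function() {
  pin <- function(p) c(p, 1 - sum(p)) # residual to last category
  marginals <- list(
    sex    = pin(0.8181),
    age    = pin(c(0.1279, 0.1708, 0.1233, 0.1081, 0.1719, 0.1289)),
    cause  = pin(c(0.6853, 0.1319)),
    ec     = pin(0.2348),
    eye    = pin(c(0.3842, 0.1808, 0.2529)),
    motor  = pin(c(0.0862, 0.0584, 0.0738, 0.1338, 0.3904)),
    verbal = pin(c(0.3785, 0.1611, 0.1177, 0.2876)),
    pupils = pin(c(0.8303, 0.0711)),
    phm    = pin(0.2830),
    sah    = pin(0.3163),
    oblt   = pin(0.2384),
    mdls   = pin(0.1464),
    hmt    = pin(0.3897)
  )
  sch <- crash_schema()
  for (v in names(marginals)) names(marginals[[v]]) <- sch[[v]]$categories
  list(marginals = marginals, poor_rate = 0.3961)
}

# ---------------------------------------------------------------------------
# Default planted truth

#' Default generative model for the admission cohort
#'
#' Structure: \code{sex} and \code{age} are roots; \code{age -> cause ->
#' ec}; the nine severity-linked variables (GCS components, pupils and the
#' five CT findings) form a chain whose conditional tables are obtained by
#' collapsing a latent four-level ordinal injury-severity driver, so that
#' clinically co-occurring findings are positively associated.  Outcome
#' coefficients are monotone in GCS component ordering and positive for
#' pupil abnormality, CT mass-effect signs, older age bands and extracranial
#' injury.  The model is deterministic; \code{seed} is retained for
#' provenance in run manifests.
#'
#' @param seed integer, stored as an attribute.
#' @return a \code{gen_model} over the 13 predictors.
#' @export
default_truth <- function(seed = 1L) {
  sch <- crash_schema()
  tg <- table1_targets()$marginals
  levels <- lapply(sch[predictor_names(sch)], `[[`, "categories")

  # latent severity: 4 ordinal levels, centered scores
  pi_s <- c(0.35, 0.30, 0.20, 0.15)
  u_s <- c(-1, -1/3, 1/3, 1)
  # category severity scores: +1 = most severe category
  sev_scores <- function(k, worst_first = TRUE) {
    z <- seq(1, -1, length.out = k)
    if (worst_first) z else rev(z)
  }
  zmap <- list(
    eye = sev_scores(4), motor = sev_scores(6), verbal = sev_scores(5),
    pupils = sev_scores(3, worst_first = FALSE),    # both reactive listed first
    phm = c(1, -1), sah = c(1, -1), oblt = c(1, -1),
    mdls = c(1, -1), hmt = c(1, -1))
  lambda <- c(eye = 1.6, motor = 1.8, verbal = 1.6, pupils = 1.6,
              phm = 0.9, sah = 0.9, oblt = 1.2, mdls = 1.2, hmt = 1.0)
  cond_on_s <- function(v) { # K x 4 matrix P(v = k | s)
    base <- tg[[v]]
    m <- vapply(seq_along(pi_s), function(s) {
      w <- base * exp(lambda[[v]] * zmap[[v]] * u_s[s])
      w / sum(w)
    }, numeric(length(base)))
    m
  }
  chain <- c("eye", "motor", "verbal", "pupils", "phm", "sah", "oblt",
             "mdls", "hmt")
  parents <- as.list(c(sex = NA, age = NA, cause = "age", ec = "cause",
                       stats::setNames(c(NA, chain[-length(chain)]), chain)))
  parents[["eye"]] <- NA

  cpts <- list(sex = tg$sex, age = tg$age)
  # age -> cause: older age shifts road-traffic accidents toward falls/other
  w_age <- seq(-1, 1, length.out = length(levels$age))
  theta_cause <- c(-0.5, 0.6, 0.25)
  cpts$cause <- t(vapply(w_age, function(w) {
    p <- tg$cause * exp(theta_cause * w); p / sum(p)
  }, numeric(3)))
  # cause -> ec: high-energy mechanisms carry more extracranial injury
  p_ec_yes <- c(0.272, 0.222, 0.104)
  cpts$ec <- cbind(yes = p_ec_yes, no = 1 - p_ec_yes)

  # severity chain collapsed from the latent driver
  prev <- NULL
  for (v in chain) {
    pv_s <- cond_on_s(v)                      # K_v x 4
    if (is.null(prev)) {
      cpts[[v]] <- as.vector(pv_s %*% pi_s)
    } else {
      pp_s <- cond_on_s(prev)                 # K_prev x 4
      post <- sweep(pp_s, 2, pi_s, `*`)       # P(prev, s)
      post <- post / rowSums(post)            # P(s | prev)
      cpts[[v]] <- post %*% t(pv_s)           # K_prev x K_v
    }
    prev <- v
  }
  for (v in names(cpts)) {
    if (is.matrix(cpts[[v]]))
      dimnames(cpts[[v]]) <- list(levels[[parents[[v]]]], levels[[v]])
    else names(cpts[[v]]) <- levels[[v]]
  }

  coefs <- list(
    sex    = c(0, 0),
    age    = c(0, 0.10, 0.20, 0.35, 0.55, 0.80, 1.20),
    cause  = c(0, 0, 0),
    ec     = c(0.60, 0),
    eye    = c(0.50, 0.35, 0.15, 0),
    motor  = c(1.80, 1.50, 1.10, 0.70, 0.30, 0),
    verbal = c(0.90, 0.60, 0.40, 0.15, 0),
    pupils = c(0, 0.70, 1.30),
    phm    = c(0.20, 0),
    sah    = c(0.25, 0),
    oblt   = c(0.60, 0),
    mdls   = c(0.50, 0),
    hmt    = c(0.40, 0))
  for (v in names(coefs)) names(coefs[[v]]) <- levels[[v]]

  m <- gen_model(levels, parents, cpts, coefs, outcome_intercept = -1.5)
  attr(m, "seed") <- as.integer(seed)
  m
}

# ---------------------------------------------------------------------------
# Exact marginalization

#' Exact marginal distributions of a generative model
#'
#' Forward pass in topological order; exact because every node has at most
#' one parent.
#'
#' @param model a \code{gen_model}.
#' @return named list of probability vectors.
#' @export
exact_marginals <- function(model) {
  marg <- list()
  for (v in model$order) {
    p <- model$parents[[v]]
    marg[[v]] <- if (is.na(p)) model$cpts[[v]]
                 else as.vector(marg[[p]] %*% model$cpts[[v]])
    names(marg[[v]]) <- model$levels[[v]]
  }
  marg[names(model$levels)]
}

# Exact distribution of the outcome linear predictor (excluding intercept):
# enumerate each connected component of the forest, then convolve.
exact_lp_distribution <- function(model, max_atoms = 2e7) {
  comp_of <- stats::setNames(seq_along(model$levels), names(model$levels))
  for (v in model$order) {
    p <- model$parents[[v]]
    if (!is.na(p)) comp_of[v] <- comp_of[[p]]
  }
  lp <- 0; pr <- 1
  for (cid in unique(comp_of)) {
    nodes <- model$order[model$order %in% names(comp_of)[comp_of == cid]]
    # DP over the component: rows = joint configurations
    cl <- 0; cp <- 1; idx <- list()
    for (v in nodes) {
      k <- length(model$levels[[v]])
      coef <- model$outcome_coefficients[[v]]
      p <- model$parents[[v]]
      nrep <- length(cp)
      if (is.na(p)) {
        cl <- rep(cl, times = k) + rep(coef, each = nrep)
        cp <- rep(cp, times = k) * rep(model$cpts[[v]], each = nrep)
        for (w in names(idx)) idx[[w]] <- rep(idx[[w]], times = k)
        idx[[v]] <- rep(seq_len(k), each = nrep)
      } else {
        pidx <- idx[[p]]
        cl <- rep(cl, times = k) + rep(coef, each = nrep)
        cp <- rep(cp, times = k) *
          as.vector(model$cpts[[v]][cbind(rep(pidx, times = k),
                                          rep(seq_len(k), each = nrep))])
        for (w in names(idx)) idx[[w]] <- rep(idx[[w]], times = k)
        idx[[v]] <- rep(seq_len(k), each = nrep)
      }
    }
    if (length(lp) * length(cl) > max_atoms)
      stop("linear-predictor enumeration exceeds max_atoms")
    lp <- rep(lp, times = length(cl)) + rep(cl, each = length(lp))
    pr <- rep(pr, times = length(cp)) * rep(cp, each = length(pr))
  }
  list(lp = lp, prob = pr)
}

#' Exact poor-outcome rate of a generative model
#'
#' @param model a \code{gen_model}.
#' @return scalar probability of the positive (poor) outcome class.
#' @export
exact_poor_rate <- function(model) {
  d <- exact_lp_distribution(model)
  sum(d$prob * stats::plogis(model$outcome_intercept + d$lp))
}

# ---------------------------------------------------------------------------
# Calibration

#' Calibrate a generative model to target marginals and outcome rate
#'
#' In topological order, each variable's conditional table is tilted by a
#' per-category log-odds shift (iterative proportional fitting against the
#' exactly-marginalized distribution) until the model's exact marginal
#' matches the target within \code{tol} per category.  The outcome intercept
#' is then root-found against the exact poor-outcome rate.
#'
#' @param model a \code{gen_model}.
#' @param targets as returned by \code{\link{table1_targets}}; variables
#'   absent from \code{targets$marginals} are left untouched, and a
#'   \code{NULL} \code{poor_rate} skips intercept calibration.
#' @param tol absolute per-category tolerance (default 1e-6).
#' @param max_iter iteration cap per variable.
#' @return the calibrated \code{gen_model}.
#' @export
calibrate <- function(model, targets = table1_targets(), tol = 1e-6,
                      max_iter = 500L) {
  stopifnot(tol > 0)
  for (v in model$order) {
    tgt <- targets$marginals[[v]]
    if (is.null(tgt)) next
    stopifnot(abs(sum(tgt) - 1) < 1e-6,
              length(tgt) == length(model$levels[[v]]))
    p <- model$parents[[v]]
    pm <- if (is.na(p)) NULL else exact_marginals(model)[[p]]
    cpt <- model$cpts[[v]]
    for (it in seq_len(max_iter)) {
      cur <- if (is.na(p)) cpt else as.vector(pm %*% cpt)
      if (max(abs(cur - tgt)) < tol) break
      adj <- tgt / pmax(cur, 1e-300)
      if (is.na(p)) {
        cpt <- cpt * adj; cpt <- cpt / sum(cpt)
      } else {
        cpt <- sweep(cpt, 2, adj, `*`); cpt <- cpt / rowSums(cpt)
      }
      if (it == max_iter)
        stop(sprintf("calibration did not converge for '%s' (worst error %.2e)",
                     v, max(abs(cur - tgt))))
    }
    model$cpts[[v]] <- cpt
  }
  if (!is.null(targets$poor_rate)) {
    d <- exact_lp_distribution(model)
    f <- function(b) sum(d$prob * stats::plogis(b + d$lp)) - targets$poor_rate
    model$outcome_intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  model
}

# ---------------------------------------------------------------------------
# Sampling

#' Sample a complete synthetic cohort
#'
#' Ancestral sampling through the shared Bayesian-network engine
#' (\code{\link{sample_bn}} on \code{\link{as_bn}(model)}), then the binary
#' outcome from the logistic mechanism.  Deterministic given \code{seed}.
#'
#' @param model a \code{gen_model}.
#' @param n number of records (>= 1).
#' @param seed integer seed (required).
#' @return a \code{cohort}: factor predictors plus an \code{outcome} column.
#' @export
sample_cohort <- function(model, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    df <- sample_bn_impl(as_bn(model), n)
    lp <- rep(model$outcome_intercept, n)
    for (v in names(model$levels))
      lp <- lp + model$outcome_coefficients[[v]][as.integer(df[[v]])]
    poor <- stats::runif(n) < stats::plogis(lp)
    df$outcome <- factor(ifelse(poor, poor_label(),
                                "moderate disability or good recovery"),
                         levels = c(poor_label(),
                                    "moderate disability or good recovery"))
    as_cohort(df, gen_schema(model))
  })
}

# Schema matching a gen_model: the full CRASH schema when the model covers
# it (so missing-data codes are available), else a minimal generated one.
gen_schema <- function(model) {
  crash <- crash_schema()
  crash_lv <- lapply(crash[predictor_names(crash)], `[[`, "categories")
  if (identical(model$levels[names(crash_lv)], crash_lv)) return(crash)
  sch <- lapply(names(model$levels), function(v)
    list(name = v, group = "predictor", categories = model$levels[[v]],
         missing_codes = character()))
  names(sch) <- names(model$levels)
  sch$outcome <- list(name = "outcome", group = "outcome",
                      categories = c(poor_label(),
                                     "moderate disability or good recovery"),
                      missing_codes = c("alive disability unknown", "no data"))
  structure(sch, class = "tbi_schema")
}

# ---------------------------------------------------------------------------
# Missingness

#' Default missing-data configuration
#'
#' Rates pinned to the entire-dataset missing-data frequencies of the
#' published characteristics table: the scan-not-done code is applied
#' jointly to all five CT variables (the scan either happened or it did
#' not), a smaller joint "no data" event covers CT findings recorded as
#' missing despite a scan, and the remaining codes are independent
#' missing-completely-at-random events.
#'
#' @return a named list of probabilities (class \code{missingness_config}).
#' @export
default_missingness <- function() {
  structure(list(
    p_scan_not_done = 0.2061,
    p_ct_no_data = 0.0128,
    p_cause_no_data = 0.0143,
    p_ec_no_data = 0.0238,
    p_pupils_unassessable = 0.0538,
    p_outcome_alive_unknown = 0.0120,
    p_outcome_no_data = 0.0333
  ), class = "missingness_config")
}

#' Expected complete-case retention probability of a missingness config
#'
#' @param cfg a \code{missingness_config}.
#' @return probability a record survives \code{\link{complete_case_filter}}.
#' @export
expected_retention <- function(cfg = default_missingness()) {
  (1 - cfg$p_scan_not_done - cfg$p_ct_no_data) *
    (1 - cfg$p_cause_no_data) * (1 - cfg$p_ec_no_data) *
    (1 - cfg$p_pupils_unassessable) *
    (1 - cfg$p_outcome_alive_unknown - cfg$p_outcome_no_data)
}

#' Overlay missing-data codes on a complete cohort
#'
#' @param cohort a \code{cohort} over the CRASH schema.
#' @param cfg a \code{missingness_config}.
#' @param seed integer seed (required).
#' @return a \code{raw_cohort} with missing codes injected.
#' @export
apply_missingness <- function(cohort, cfg = default_missingness(), seed) {
  stopifnot(inherits(cfg, "missingness_config"))
  schema <- attr(cohort, "schema") %||% crash_schema()
  n <- nrow(cohort)
  df <- as.data.frame(lapply(cohort, as.character), stringsAsFactors = FALSE)
  ct_vars <- c("phm", "sah", "oblt", "mdls", "hmt")
  with_seed(seed, {
    u_ct <- stats::runif(n)
    not_done <- u_ct < cfg$p_scan_not_done
    ct_nodata <- !not_done & u_ct < cfg$p_scan_not_done + cfg$p_ct_no_data
    for (v in ct_vars) {
      df[[v]][not_done] <- "scan not done"
      df[[v]][ct_nodata] <- "no data"
    }
    df$cause[stats::runif(n) < cfg$p_cause_no_data] <- "no data"
    df$ec[stats::runif(n) < cfg$p_ec_no_data] <- "no data"
    df$pupils[stats::runif(n) < cfg$p_pupils_unassessable] <- "unable to assess"
    u_out <- stats::runif(n)
    df$outcome[u_out < cfg$p_outcome_alive_unknown] <- "alive disability unknown"
    df$outcome[u_out >= cfg$p_outcome_alive_unknown &
               u_out < cfg$p_outcome_alive_unknown + cfg$p_outcome_no_data] <-
      "no data"
  })
  raw_cohort(df, schema)
}
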