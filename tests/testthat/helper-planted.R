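# Planted-truth generative models used by the recovery tests.

# `n_strong` informative predictors (monotone per-category log-odds up to
# `beta`) among `n_null` pure-noise predictors, all independent with three
# categories.  Strong predictors are named s1, s2, ...; nulls n1, n2, ...
planted_model <- function(n_strong = 2, n_null = 8, beta = 2.4,
                          intercept = -1.6) {
  nm <- c(paste0("s", seq_len(n_strong)), paste0("n", seq_len(n_null)))
  lv <- stats::setNames(rep(list(c("low", "mid", "high")), length(nm)), nm)
  parents <- stats::setNames(rep(list(NA), length(nm)), nm)
  cpts <- stats::setNames(rep(list(c(0.4, 0.35, 0.25)), length(nm)), nm)
  coefs <- lapply(nm, function(v)
    if (startsWith(v, "s")) c(0, beta / 2, beta) else c(0, 0, 0))
  names(coefs) <- nm
  gen_model(lv, parents, cpts, coefs, outcome_intercept = intercept)
}

# Tiny chain model over arbitrary binary nodes (for BN recovery tests).
chain_model <- function(nodes = c("A", "B", "C"), p_root = 0.6,
                        p_stay = 0.85) {
  lv <- stats::setNames(lapply(nodes, function(v) paste0(tolower(v), 1:2)),
                        nodes)
  parents <- stats::setNames(c(list(NA), as.list(nodes[-length(nodes)])),
                             nodes)
  cpts <- list()
  cpts[[nodes[1]]] <- c(p_root, 1 - p_root)
  for (v in nodes[-1])
    cpts[[v]] <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay),
                        2, 2, byrow = TRUE)
  coefs <- stats::setNames(rep(list(c(0, 0)), length(nodes)), nodes)
  gen_model(lv, parents, cpts, coefs, 0)
}
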