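# Independent brute-force oracles. Each re-derives a quantity from first
# principles (the printed formula, full enumeration, or grid search) and is
# kept free of the package code paths it checks.

# Reflection exactly as printed: min + (max - min) * (max - x) / (max - min).
oracle_reflect <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) return(x)
  mn + (mx - mn) * (mx - x) / (mx - mn)
}

# Reflected-median score, gene by gene, straight off the definition.
oracle_reflected_median <- function(expr, up_genes, down_genes) {
  m <- as.matrix(expr[, -1]); rownames(m) <- expr$gene
  for (g in up_genes) m[g, ] <- oracle_reflect(m[g, ])
  apply(m[c(up_genes, down_genes), , drop = FALSE], 2, median)
}

# Product-limit estimator computed by explicit risk-set bookkeeping.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Log-rank O/E/V sums from the hypergeometric moments at each event time.
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Exact permutation p for the log-rank statistic: enumerate every way of
# relabelling the subjects into groups of the observed sizes.
oracle_logrank_permutation_p <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  n1 <- sum(group == g1)
  obs <- oracle_logrank_chisq(time, event, group)
  combos <- utils::combn(length(time), n1)
  stats <- apply(combos, 2, function(idx) {
    g <- rep("B", length(time)); g[idx] <- "A"
    oracle_logrank_chisq(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}

# Explicit Cox partial likelihood for a binary covariate, Breslow ties.
oracle_cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    at_risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_cox_partial_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# the pooled values to the two groups (distinct values assumed).
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, u_of)
  mu <- nx * (length(y)) / 2
  # two-sided: as or more extreme in |U - E[U]|
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Rejection rate of the median-split log-rank test on freshly simulated
# cohorts (shared by the type-I-error and power suites).
simulate_logrank_pvalues <- function(config_fn, seeds, signature = "RESIST-M") {
  vapply(seeds, function(s) {
    cohort <- simulate_cohort(config_fn(s))
    rep <- suppressWarnings(
      stratified_km_report(cohort$expression, cohort$clinical, signature))
    rep$logrank$p_value
  }, numeric(1))
}
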