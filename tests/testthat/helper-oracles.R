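# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm/wilcox.test/kruskal.test) so agreement
# is a real cross-check, not a tautology.

# Brute-force OLS via the normal equations: slope, intercept, se of slope
# (residual df = n - 2), t, one-sided p for slope > 0, and R^2.
ols_oracle <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  resid <- y - intercept - slope * t
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  syy <- sum((y - mean(y))^2)
  list(slope = slope, se = se, t = tstat,
       p = stats::pt(tstat, n - 2, lower.tail = FALSE),
       r2 = 1 - sum(resid^2) / syy)
}

# Exact one-sided Mann-Whitney p (P[rank sum of group 1 <= / >= observed])
# by full enumeration of all choose(n1+n2, n1) assignments. No ties.
wilcoxon_enum_oracle <- function(g1, g2, alternative = "less") {
  pooled <- c(g1, g2)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(g1)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  r_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  if (alternative == "less") mean(r_all <= r_obs) else mean(r_all >= r_obs)
}

# Exact permutation p of the (tie-corrected) Kruskal-Wallis H by full
# enumeration over all permutations of the pooled values, generated here
# with sample-space recursion distinct from the package's generator.
kw_enum_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  h_of <- function(vals) {
    n <- length(vals)
    r <- rank(vals)
    g <- rep(seq_along(sizes), sizes)
    rs <- tapply(r, g, sum)
    H <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
    ties <- table(vals)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  H_obs <- h_of(x)
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  Hs <- vapply(perm_list(x), h_of, 1)
  list(H = H_obs, p = mean(Hs >= H_obs - 1e-9))
}

# A default noise-free linear incubation record for tracer tests.
make_linear_record <- function(rate = 0.4, k_h = 0.032, noise = 0,
                               schedule = c(0, 6, 12, 24, 48), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- simulation_config(
    true_rate = rate, noise_sd_excess = noise, scenario = "linear",
    geometry = vessel_geometry(partition_coefficient = k_h),
    schedule = schedule)
  simulate_incubation(cfg)
}
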