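# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::median/mad) so agreement is a genuine cross-check.

brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# MATH = 100 * 1.4826 * median(|v - median(v)|) / median(v), by explicit loops
brute_math <- function(vafs) {
  m <- brute_median(vafs)
  dev <- numeric(length(vafs))
  for (i in seq_along(vafs)) dev[i] <- abs(vafs[i] - m)
  100 * 1.4826 * brute_median(dev) / m
}

# Exhaustive cutpoint scan using survival::survdiff at every admissible
# midpoint split; returns the smallest threshold attaining the maximal
# standardized statistic.
oracle_cutpoint <- function(marker, time, event, minprop = 0.1) {
  n <- length(marker)
  sv <- sort(unique(marker))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  min_size <- ceiling(minprop * n)
  best_stat <- -Inf
  best_thr <- NA_real_
  for (thr in cand) {
    hi <- marker > thr
    if (sum(hi) < min_size || (n - sum(hi)) < min_size) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    stat <- sqrt(sd$chisq)
    if (stat > best_stat + 1e-12) {
      best_stat <- stat
      best_thr <- thr
    }
  }
  list(threshold = best_thr, statistic = best_stat)
}

# Permutation p-value for the two-group log-rank test, computed from first
# principles on tie-free data: at the i-th smallest time the risk set has
# n - i + 1 subjects, and the statistic is U^2/V with U = sum over event
# times of (z_i - n1_i/n_i), V = sum of (n1_i/n_i)(1 - n1_i/n_i).
perm_logrank_p <- function(time, event, in_a, B, seed) {
  stopifnot(!any(duplicated(time)))
  o <- order(time)
  ev <- event[o]
  za <- in_a[o]
  n <- length(time)
  nr <- n:1
  stat_of <- function(z) {
    n1 <- rev(cumsum(rev(z)))
    u <- sum(ev * (z - n1 / nr))
    v <- sum(ev * (n1 / nr) * (1 - n1 / nr))
    u^2 / v
  }
  s0 <- stat_of(za)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    if (stat_of(sample(za)) >= s0 - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# Permutation p-value for the rank-sum test (two-sided, via the
# permutation distribution of the group-A rank sum).
perm_ranksum_p <- function(x, y, B, seed) {
  r <- rank(c(x, y))
  na <- length(x)
  s0 <- sum(r[seq_len(na)])
  mu <- na * (length(r) + 1) / 2
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    sb <- sum(r[sample.int(length(r), na)])
    if (abs(sb - mu) >= abs(s0 - mu) - 1e-12) hits <- hits + 1L
  }
  hits / B
}
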