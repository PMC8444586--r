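# Independent brute-force oracles for the statistical primitives, and small
# fixture builders shared across test files.

# Exact two-tailed rank-sum p by enumerating every assignment of the pooled
# values to the two groups (tie-free inputs only).
oracle_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  idx <- utils::combn(length(pooled), n)
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-tailed signed-rank p by enumerating all 2^n sign assignments of
# the observed midranks (valid under ties).
oracle_signed_rank_p <- function(x) {
  d <- x[x != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Quadratic-time reference Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ge <- which(p >= p[i] - 1e-15)
    cands <- vapply(ge, function(j) m * p[j] / sum(p <= p[j] + 1e-15),
                    numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# A tiny two-module hierarchy with one shared KO, for hand-checkable
# support-based allocation.
toy_hierarchy <- function() {
  functional_hierarchy(data.frame(
    ko_id = c("K1", "K2", "K3", "K4", "K5", "K1", "K1", "K2", "K3", "K4", "K5"),
    group_id = c("M1", "M1", "M1", "M1", "M1",
                 "M2", "P1", "P1", "P1", "P1", "P1"),
    level = c(rep("module", 6), rep("pathway", 5)),
    stringsAsFactors = FALSE
  ))
}

# Small synthetic configuration for fast unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_cohort = 8, n_features_ko = 40, seed = 11), list(...))
  do.call(synthetic_config, args)
}

# Minimal metadata frame: one cohort, n subjects at each time point.
flat_meta <- function(timepoints, n, cohort = "A") {
  do.call(rbind, lapply(timepoints, function(t) {
    data.frame(sample_id = sprintf("%s%02d_m%g", cohort, seq_len(n), t),
               subject_id = sprintf("%s%02d", cohort, seq_len(n)),
               age_months = t, cohort = cohort, stringsAsFactors = FALSE)
  }))
}
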