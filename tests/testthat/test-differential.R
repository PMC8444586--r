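make_two_group_table <- function(n_feat = 20, n = 10, shift_feature = NULL,
                                 shift = 4, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("A%02d_m4", 1:n), sprintf("B%02d_m4", 1:n))
  m <- matrix(rlnorm(n_feat * 2 * n, 0, 0.3), n_feat,
              dimnames = list(sprintf("M%03d", 1:n_feat), ids))
  if (!is.null(shift_feature)) m[shift_feature, 1:n] <- m[shift_feature, 1:n] * shift
  meta <- data.frame(sample_id = ids,
                     subject_id = sub("_m4", "", ids),
                     age_months = 4,
                     cohort = rep(c("A", "B"), each = n),
                     stringsAsFactors = FALSE)
  list(table = feature_table(m, "module", normalized = TRUE), meta = meta)
}

test_that("a strongly shifted feature is flagged with the right direction", {
  d <- make_two_group_table(n = 20, shift_feature = "M003", seed = 7)
  res <- compare_cohorts(d$table, d$meta, timepoint = 4, q_threshold = 0.01)
  hit <- res[res$feature_id == "M003", ]
  expect_equal(hit$direction, "up_in_ref")
  expect_lt(hit$q_value, 0.01)
  expect_gt(hit$log10_median_ratio, 0)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_equal(res$n_ref, rep(20, nrow(res)))
})

test_that("identical cohorts yield no significant features", {
  d <- make_two_group_table(n = 10, seed = 8)
  m <- as.matrix(d$table)
  m[, 11:20] <- m[, 1:10]  # copy group A into group B
  res <- compare_cohorts(feature_table(m, "module", TRUE), d$meta, 4)
  expect_true(all(res$direction == "ns"))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$log10_median_ratio == 0))
})

test_that("small groups are rejected with a named error", {
  d <- make_two_group_table(n = 10)
  meta <- d$meta[-(11:19), ]  # cohort B down to one sample
  expect_error(compare_cohorts(d$table, meta, 4), "B.*month 4")
})

test_that("results are invariant to sample and feature order", {
  d <- make_two_group_table(n = 8, shift_feature = "M001", seed = 9)
  res <- compare_cohorts(d$table, d$meta, 4)
  m <- as.matrix(d$table)
  perm <- feature_table(m[sample(nrow(m)), sample(ncol(m))], "module", TRUE)
  res_p <- compare_cohorts(perm, d$meta[sample(nrow(d$meta)), ], 4)
  res_p <- res_p[match(res$feature_id, res_p$feature_id), ]
  expect_equal(res_p$p_value, res$p_value)
  expect_equal(res_p$log10_median_ratio, res$log10_median_ratio)
})

test_that("temporal patterns collapse per-time-point calls with flags", {
  base <- data.frame(feature_id = c("f1", "f2", "f3"), level = "module",
                     stringsAsFactors = FALSE)
  res <- rbind(
    cbind(base, timepoint = 4, p_value = 0.001, q_value = c(0.001, 0.5, 0.001),
          log10_median_ratio = c(0.4, 0.1, 0.5),
          direction = c("up_in_ref", "ns", "up_in_ref"), n_ref = 10, n_cmp = 10),
    cbind(base, timepoint = 6, p_value = 0.5, q_value = 0.5,
          log10_median_ratio = c(0.1, 0.0, -0.2),
          direction = "ns", n_ref = 10, n_cmp = 10),
    cbind(base, timepoint = 12, p_value = 0.001, q_value = c(0.001, 0.5, 0.001),
          log10_median_ratio = c(0.6, 0.05, -0.6),
          direction = c("up_in_ref", "ns", "up_in_cmp"), n_ref = 10, n_cmp = 10))
  pat <- classify_patterns(res)
  f1 <- pat[pat$feature_id == "f1", ]
  expect_equal(f1$pattern, "up_in_ref,ns,up_in_ref")
  expect_true(f1$consistent)
  expect_true(f1$expanding)      # |0.6| > |0.4|
  f2 <- pat[pat$feature_id == "f2", ]
  expect_equal(f2$pattern, "ns,ns,ns")
  expect_true(f2$consistent)
  f3 <- pat[pat$feature_id == "f3", ]
  expect_false(f3$consistent)    # sign flip between significant calls

  expect_error(classify_patterns(res[-1, ]), "same feature universe")
})

test_that("expansion counting uses a strict inequality", {
  r1 <- data.frame(feature_id = c("f1", "f2", "f3"),
                   log10_median_ratio = c(0.1, 0.3, -0.2))
  r2 <- data.frame(feature_id = c("f1", "f2", "f3"),
                   log10_median_ratio = c(0.3, 0.3, -0.1))
  out <- count_expansion(r1, r2, c("f1", "f2", "f3"))
  expect_equal(out$n_expanding, 1)  # f2 tied, f3 shrinking
  expect_equal(out$n_total, 3)
  expect_error(count_expansion(r1, r2, "f9"), "f9")
})

test_that("delta-induced gaps make trending features expand over time", {
  cfg <- synthetic_config(n_subjects_per_cohort = 20, n_features_ko = 60,
                          delay_months = 2, frac_cohort_shifted = 0, seed = 17)
  sim <- generate_profiles(cfg)
  r4 <- compare_cohorts(sim$table, sim$metadata, 4)
  r12 <- compare_cohorts(sim$table, sim$metadata, 12)
  trending <- sim$truth$feature_id[sim$truth$type == "trending"]
  out <- count_expansion(r4, r12, trending)
  expect_gt(out$n_expanding / out$n_total, 0.5)
})

test_that("false discoveries are controlled under the synthetic null", {
  set.seed(909)
  n_reps <- 200
  any_fd <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    m <- matrix(rlnorm(40 * 16, 0, 0.3), 40,
                dimnames = list(sprintf("M%03d", 1:40),
                                c(sprintf("A%02d_m4", 1:8), sprintf("B%02d_m4", 1:8))))
    meta <- data.frame(sample_id = colnames(m),
                       subject_id = sub("_m4", "", colnames(m)),
                       age_months = 4, cohort = rep(c("A", "B"), each = 8),
                       stringsAsFactors = FALSE)
    res <- compare_cohorts(feature_table(m, "module", TRUE), meta, 4,
                           q_threshold = 0.05)
    any_fd[i] <- any(res$q_value < 0.05)
  }
  # under the global null, FDR = P(any rejection) <= alpha
  expect_lte(mean(any_fd), 0.05 + 2 * sqrt(0.05 * 0.95 / n_reps))
})
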