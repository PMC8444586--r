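test_that("balanced subsampling reproduces the 70-30 split arithmetic", {
  # 5 time points x 23 -> 115 balanced, 80 train / 35 test, 16/7 per tp
  meta5 <- flat_meta(c(2, 4, 6, 9, 12), 30)
  bal <- balance_subsample(meta5, "A", n_per_timepoint = 23, seed = 1)
  expect_equal(length(bal$sample_ids), 115)
  expect_equal(bal$plan$n_train, 16)
  expect_equal(bal$plan$n_test, 7)
  expect_equal(bal$plan$total_train, 80)
  expect_equal(bal$plan$total_test, 35)
  sp <- stratified_split(bal$sample_ids, meta5, bal$plan, seed = 2)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$test), 35)
  expect_length(intersect(sp$train, sp$test), 0)
  ages <- meta5$age_months[match(sp$train, meta5$sample_id)]
  expect_true(all(table(ages) == 16))

  # 8 time points x 29 -> 160/72 total, 20/9 per tp
  meta8 <- flat_meta(c(3, 4, 5, 6, 8, 10, 11, 12), 29)
  bal8 <- balance_subsample(meta8, "A", seed = 3)
  expect_equal(bal8$plan$n_per_timepoint, 29)
  expect_equal(bal8$plan$n_train, 20)
  expect_equal(bal8$plan$n_test, 9)
  expect_equal(bal8$plan$total_train, 160)
  expect_equal(bal8$plan$total_test, 72)

  # floor rule
  bal10 <- balance_subsample(flat_meta(c(2, 4), 10), "A", seed = 4)
  expect_equal(bal10$plan$n_train, 7)
  expect_equal(bal10$plan$n_test, 3)

  # shortfall names the offending time point
  expect_error(balance_subsample(meta5, "A", n_per_timepoint = 31), "only 30")
})

test_that("the age regressor learns a perfect feature and stays in the training hull", {
  set.seed(42)
  n <- 60
  ages <- rep(c(2, 4, 6, 9, 12), each = n / 5)
  X <- cbind(signal = ages, matrix(rnorm(n * 9), n))
  colnames(X) <- c("signal", sprintf("noise%02d", 1:9))
  rownames(X) <- sprintf("s%02d", 1:n)
  idx <- sample(n, 40)
  fit <- train_age_regressor(X[idx, ], ages[idx], n_trees = 200, seed = 5)
  pred <- predict(fit, X[-idx, ])
  expect_gt(pearson_r_test(pred, ages[-idx])$r, 0.95)
  # forest averaging keeps predictions inside the training age range
  expect_true(all(pred >= min(ages[idx]) & pred <= max(ages[idx])))
  # determinism under a fixed seed
  fit2 <- train_age_regressor(X[idx, ], ages[idx], n_trees = 200, seed = 5)
  expect_identical(predict(fit2, X[-idx, ]), pred)
  # feature mismatch is reported
  expect_error(predict(fit, X[-idx, 1:3]), "noise04")
})

test_that("pure-noise features rarely yield significant held-out correlation", {
  set.seed(77)
  n <- 50
  ages <- rep(c(2, 4, 6, 9, 12), each = 10)
  sig <- 0
  for (r in 1:10) {
    X <- matrix(rnorm(n * 20), n, dimnames = list(sprintf("s%02d", 1:n), NULL))
    colnames(X) <- sprintf("f%02d", 1:20)
    idx <- sample(n, 35)
    fit <- train_age_regressor(X[idx, ], ages[idx], n_trees = 100, seed = r)
    pr <- pearson_r_test(predict(fit, X[-idx, ]), ages[-idx])
    if (pr$p < 0.05 && pr$r > 0) sig <- sig + 1
  }
  expect_lte(sig, 2)
})

test_that("a constant feature table trains with a warning", {
  X <- matrix(1, 20, 3, dimnames = list(sprintf("s%02d", 1:20), c("a", "b", "c")))
  expect_warning(train_age_regressor(X, rep(c(2, 12), 10), n_trees = 50),
                 "constant")
})

test_that("the calibration spline reproduces linear data and hits df = 3", {
  ages <- rep(c(2, 4, 6, 9, 12), each = 7)
  pred <- 0.8 * ages + 1.3
  sp <- fit_calibration_spline(pred, ages, df = 3)
  expect_equal(predict(sp, ages), pred, tolerance = 1e-8)
  # linear extrapolation beyond the observed range
  expect_equal(predict(sp, 14), 0.8 * 14 + 1.3, tolerance = 1e-8)
  expect_equal(predict(sp, 1), 0.8 * 1 + 1.3, tolerance = 1e-8)
  expect_error(fit_calibration_spline(1:6, rep(c(2, 4, 6), 2)), "4 distinct")

  # effective degrees of freedom: direct trace of the smoother matrix at the
  # fitted smoothing parameter, on distinct-age noisy data
  set.seed(6)
  x <- seq(2, 12, length.out = 25)
  y <- 0.9 * x + rnorm(25, 0, 0.8)
  sp2 <- fit_calibration_spline(y, x, df = 3)
  lam <- sp2$fit$lambda
  tr <- sum(vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- 1
    stats::predict(stats::smooth.spline(x, e, lambda = lam), x)$y[j]
  }, numeric(1)))
  expect_equal(tr, 3, tolerance = 0.01)
  expect_equal(sp2$df, 3, tolerance = 0.01)
})

test_that("relative ages are prediction minus spline and residual-center on calibration data", {
  cfg <- tiny_config(n_subjects_per_cohort = 12, seed = 23)
  sim <- generate_profiles(cfg)
  m <- t(as.matrix(sim$table))
  run <- run_replicate_protocol(m, sim$metadata, "A", R = 2, n_trees = 100,
                                seed = 31)
  # estimate count = |target samples| x |replicates|
  n_b <- sum(sim$metadata$cohort == "B")
  expect_equal(nrow(run$estimates), n_b * 2)
  # definitional identity: relative age = prediction - spline(true age)
  mod <- run$models[[1]]
  e1 <- run$estimates[run$estimates$replicate == 1, ]
  manual <- predict(mod$regressor, m[e1$sample_id, ]) -
    predict(mod$spline, e1$age_months)
  expect_equal(e1$relative_age, manual)
  # scoring a model's own calibration samples: residuals about the spline
  # average to zero (constants lie in the smoother's null space)
  own <- relative_ages(list(mod), m[mod$test_ids, ], sim$metadata)
  expect_lt(abs(mean(own$relative_age)), 1e-6)
})

test_that("delay testing summarizes per-replicate signed-rank calls", {
  est <- expand.grid(sample_id = sprintf("B%02d", 1:10), replicate = 1:3,
                     stringsAsFactors = FALSE)
  est$age_months <- 12
  est$cohort <- "B"
  est$predicted_age <- 10
  est$relative_age <- -1
  out <- test_delay(est)
  expect_equal(nrow(out$per_replicate), 3)
  expect_equal(out$per_replicate$p, rep(2 / 1024, 3))
  expect_equal(out$per_replicate$direction, rep("delay", 3))
  expect_equal(out$summary$frac_delay, 1)
  est$relative_age <- rep(c(-1, 1), 15)
  out2 <- test_delay(est)
  expect_equal(out2$summary$frac_delay, 0)
  expect_error(test_delay(est[est$sample_id %in% sprintf("B%02d", 1:4), ]),
               ">= 5")
})

test_that("the replicate protocol is deterministic and exchangeable cohorts center at zero", {
  cfg <- tiny_config(n_subjects_per_cohort = 12, delay_months = 0,
                     frac_cohort_shifted = 0, seed = 29)
  sim <- generate_profiles(cfg)
  run1 <- run_replicate_protocol(sim$table, sim$metadata, "A", R = 3,
                                 n_trees = 100, seed = 41)
  run2 <- run_replicate_protocol(sim$table, sim$metadata, "A", R = 3,
                                 n_trees = 100, seed = 41)
  expect_identical(run1$estimates, run2$estimates)
  expect_identical(run1$performance, run2$performance)
  # exchangeable cohorts: pooled relative age near zero
  expect_lt(abs(median(run1$estimates$relative_age)), 0.5)
})

test_that("feature sets produce independent result bundles", {
  cfg <- tiny_config(n_subjects_per_cohort = 10, seed = 37)
  sim <- generate_profiles(cfg)
  hier <- functional_hierarchy(synthetic_hierarchy(cfg))
  mods <- aggregate_support(sim$table, hier, "module")
  paths <- aggregate_support(sim$table, hier, "pathway")
  res <- run_age_analysis(modules = mods, pathways = paths,
                          meta = sim$metadata,
                          feature_sets = c("modules", "both"),
                          R = 2, n_trees = 50, seed = 43)
  expect_named(res, c("modules", "both"))
  expect_named(res$modules, c("A", "B"))
  expect_s3_class(res$modules$A, "age_replicate_run")
  expect_equal(res$modules$A$target_cohort, "B")
  expect_equal(nrow(res$both$B$performance), 2)
  # bundles differ: "both" uses a wider feature matrix
  expect_false(identical(res$modules$A$performance$r, res$both$A$performance$r))
})
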