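#' Balanced per-time-point subsampling of one cohort
#'
#' Randomly subsamples one cohort, without replacement, so that every
#' modeled time point contributes the same number of samples, and computes
#' the per-time-point 70-30 train/test allocation (train count =
#' `floor(0.7 * n_t)`).
#'
#' @param meta sample metadata data.frame.
#' @param cohort cohort label to subsample.
#' @param n_per_timepoint requested samples per time point; default: the
#'   minimum available count over time points. A time point with fewer
#'   available samples than requested raises an error naming it.
#' @param timepoints time points to model (default: all present in the
#'   cohort).
#' @param seed integer seed for the subsample draw.
#' @return list with `sample_ids` (balanced set) and `plan` (class
#'   `split_plan`: `timepoints`, `n_per_timepoint`, `n_train`, `n_test`,
#'   totals, `seed`).
#' @export
balance_subsample <- function(meta, cohort, n_per_timepoint = NULL,
                              timepoints = NULL, seed = 1) {
  sub <- meta[meta$cohort == cohort, , drop = FALSE]
  if (nrow(sub) == 0) stop("no samples for cohort '", cohort, "'")
  if (anyDuplicated(sub[c("subject_id", "age_months")])) {
    stop("expected one sample per subject per time point in cohort '",
         cohort, "'")
  }
  timepoints <- sort(timepoints %||% unique(sub$age_months))
  counts <- vapply(timepoints,
                   function(t) sum(sub$age_months == t), integer(1))
  if (is.null(n_per_timepoint)) {
    n_per_timepoint <- min(counts)
  } else if (any(counts < n_per_timepoint)) {
    short <- timepoints[counts < n_per_timepoint][1]
    stop(sprintf("time point %s has only %d samples; %d requested per time point",
                 format(short), counts[timepoints == short][1], n_per_timepoint))
  }
  set.seed(seed)
  ids <- unlist(lapply(timepoints, function(t) {
    pool <- sub$sample_id[sub$age_months == t]
    sample(pool, n_per_timepoint)
  }))
  n_train <- floor(0.7 * n_per_timepoint)
  plan <- structure(list(
    timepoints = timepoints,
    n_per_timepoint = as.integer(n_per_timepoint),
    n_train = as.integer(n_train),
    n_test = as.integer(n_per_timepoint - n_train),
    total_train = as.integer(n_train * length(timepoints)),
    total_test = as.integer((n_per_timepoint - n_train) * length(timepoints)),
    seed = as.integer(seed)
  ), class = "split_plan")
  list(sample_ids = ids, plan = plan)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %d time points x %d samples; train %d/test %d per time point (totals %d/%d)\n",
    length(x$timepoints), x$n_per_timepoint, x$n_train, x$n_test,
    x$total_train, x$total_test))
  invisible(x)
}

#' Stratified 70-30 train/test split of a balanced sample set
#'
#' Splits the balanced sample set of [balance_subsample()] so that every
#' time point contributes exactly `plan$n_train` training and `plan$n_test`
#' testing samples.
#'
#' @param sample_ids balanced sample ids.
#' @param meta sample metadata.
#' @param plan the `split_plan` from [balance_subsample()].
#' @param seed integer seed for the split draw.
#' @return list with disjoint `train` and `test` id vectors whose union is
#'   `sample_ids`.
#' @export
stratified_split <- function(sample_ids, meta, plan, seed = 1) {
  stopifnot(inherits(plan, "split_plan"))
  age <- meta$age_months[match(sample_ids, meta$sample_id)]
  if (anyNA(age)) stop("sample ids missing from metadata")
  set.seed(seed)
  train <- unlist(lapply(plan$timepoints, function(t) {
    pool <- sample_ids[age == t]
    if (length(pool) != plan$n_per_timepoint) {
      stop("balanced set does not match plan at time point ", format(t))
    }
    sample(pool, plan$n_train)
  }))
  list(train = train, test = setdiff(sample_ids, train))
}

#' Train a regularized random-forest age regressor
#'
#' Fits a random forest regressing host age (months) on functional-profile
#' features, with RRF-style guided regularization: the split gain of a
#' feature not yet used anywhere in the forest is multiplied by
#' `gamma <= 1`, so the forest is steered toward a compact feature set.
#' `gamma = 1` gives a plain random forest. Training is single-threaded and
#' deterministic under a fixed seed.
#'
#' @param features numeric matrix, samples x features, rownames = sample
#'   ids.
#' @param ages numeric vector of host ages (months), aligned with rows.
#' @param n_trees number of trees (default 10000; scale down for quick
#'   runs).
#' @param gamma regularization coefficient in (0, 1]; default 0.8.
#' @param mtry candidate features per split; default `max(floor(p/3), 1)`,
#'   the regression-forest convention of the randomForest/RRF family.
#' @param seed integer seed.
#' @return object of class `age_regressor`.
#' @export
train_age_regressor <- function(features, ages, n_trees = 10000, gamma = 0.8,
                                mtry = NULL, seed = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(ages))
  if (length(unique(ages)) < 2) stop("need >= 2 distinct ages in training set")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1) {
    stop("gamma must be in (0, 1]")
  }
  if (all(apply(features, 2, function(v) length(unique(v)) == 1))) {
    warning("all features are constant; the model will predict the mean age")
  }
  mtry <- mtry %||% max(floor(ncol(features) / 3), 1)
  fit <- ranger::ranger(
    x = as.data.frame(features), y = ages,
    num.trees = n_trees,
    mtry = mtry,
    regularization.factor = gamma,
    num.threads = 1,
    seed = seed
  )
  structure(list(fit = fit, feature_ids = colnames(features),
                 age_range = range(ages), n_trees = n_trees, gamma = gamma),
            class = "age_regressor")
}

#' @export
predict.age_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing)) {
    stop("features missing from new data: ", paste(missing, collapse = ", "))
  }
  nd <- as.data.frame(newdata[, object$feature_ids, drop = FALSE])
  as.numeric(stats::predict(object$fit, data = nd, num.threads = 1)$predictions)
}

#' Fit the test-set calibration spline of an age model
#'
#' Fits a cubic smoothing spline of held-out predictions as a function of
#' true age with 3 effective degrees of freedom (trace of the smoother
#' matrix), the reference curve from which relative metagenomic ages are
#' measured. Evaluation beyond the observed age range extrapolates
#' linearly (natural-spline boundary behavior).
#'
#' @param pred model predictions on the replicate's own test set.
#' @param true_age true ages of the test samples (>= 4 distinct values).
#' @param df target effective degrees of freedom (default 3).
#' @return object of class `calibration_spline`.
#' @export
fit_calibration_spline <- function(pred, true_age, df = 3) {
  stopifnot(length(pred) == length(true_age))
  if (length(unique(true_age)) < 4) {
    stop("need >= 4 distinct true ages to fit the calibration spline")
  }
  fit <- stats::smooth.spline(true_age, pred, df = df)
  structure(list(fit = fit, df_target = df, df = fit$df,
                 age_range = range(true_age)),
            class = "calibration_spline")
}

#' @export
predict.calibration_spline <- function(object, age, ...) {
  stats::predict(object$fit, x = age)$y
}

#' Relative metagenomic ages of samples under replicate models
#'
#' A sample's relative metagenomic age under one replicate model is the
#' model's predicted age minus the replicate's calibration-spline value at
#' the sample's true age. Negative values indicate functional capacities
#' that look younger than the training cohort's at that age.
#'
#' @param models list of replicate models (each with `$regressor` and
#'   `$spline`), as built by [run_replicate_protocol()].
#' @param x a [feature_table] (or samples x features matrix) holding the
#'   samples to score.
#' @param meta sample metadata covering those samples.
#' @return data.frame with one row per sample per replicate: `sample_id`,
#'   `replicate`, `age_months`, `cohort`, `predicted_age`, `relative_age`.
#' @export
relative_ages <- function(models, x, meta) {
  m <- if (inherits(x, "feature_table")) t(x$abundance) else as.matrix(x)
  idx <- match(rownames(m), meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  age <- meta$age_months[idx]
  cohort <- meta$cohort[idx]
  out <- lapply(seq_along(models), function(r) {
    mod <- models[[r]]
    pred <- stats::predict(mod$regressor, m)
    data.frame(sample_id = rownames(m), replicate = r, age_months = age,
               cohort = cohort, predicted_age = pred,
               relative_age = pred - stats::predict(mod$spline, age),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed-rank tests for developmental delay per replicate and time point
#'
#' For each replicate and time point, tests whether the median relative
#' metagenomic age differs from zero (two-tailed Wilcoxon signed-rank), and
#' summarizes, per time point, the fraction of replicates calling a
#' significant negative shift (delay) or positive shift (acceleration).
#'
#' @param estimates data.frame from [relative_ages()].
#' @param alpha per-replicate significance level (default 0.05).
#' @return list with `per_replicate` (one row per time point per replicate:
#'   `timepoint`, `replicate`, `n`, `median`, `p`, `direction`) and
#'   `summary` (per time point: `frac_delay`, `frac_accel`,
#'   `n_replicates`).
#' @export
test_delay <- function(estimates, alpha = 0.05) {
  tps <- sort(unique(estimates$age_months))
  reps <- sort(unique(estimates$replicate))
  rows <- list()
  for (t in tps) {
    for (r in reps) {
      v <- estimates$relative_age[estimates$age_months == t &
                                    estimates$replicate == r]
      if (length(v) < 5) {
        stop(sprintf("replicate %d has %d estimate(s) at month %s; need >= 5",
                     r, length(v), format(t)))
      }
      p <- signed_rank_test(v)
      med <- stats::median(v)
      dir <- if (p < alpha && med < 0) "delay"
             else if (p < alpha && med > 0) "acceleration" else "ns"
      rows[[length(rows) + 1]] <-
        data.frame(timepoint = t, replicate = r, n = length(v), median = med,
                   p = p, direction = dir, stringsAsFactors = FALSE)
    }
  }
  per_replicate <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(tps, function(t) {
    sub <- per_replicate[per_replicate$timepoint == t, ]
    data.frame(timepoint = t,
               frac_delay = mean(sub$direction == "delay"),
               frac_accel = mean(sub$direction == "acceleration"),
               n_replicates = nrow(sub))
  }))
  list(per_replicate = per_replicate, summary = summary)
}

#' Replicate metagenomic-age protocol: train on one cohort, score the other
#'
#' The full replicate protocol: for each of `R` replicates, balance the
#' training cohort per time point, make a stratified 70-30 split, fit a
#' regularized random-forest age regressor on the training set, measure
#' held-out Pearson performance, fit the df-3 calibration spline on the
#' test predictions, and score every sample of the target cohort for
#' relative metagenomic age. Replicates differ in both the subsample and
#' the split (fresh seeds per replicate).
#'
#' @param features samples x features numeric matrix (rownames = sample
#'   ids) covering both cohorts, or a [feature_table].
#' @param meta sample metadata.
#' @param train_cohort cohort label to train on.
#' @param target_cohort cohort to score (default: the other cohort in
#'   `meta`).
#' @param R number of replicate models (default 10).
#' @param n_trees,gamma forest hyperparameters (see
#'   [train_age_regressor()]).
#' @param spline_df calibration spline degrees of freedom (default 3).
#' @param n_per_timepoint balanced per-time-point sample count (default:
#'   minimum available).
#' @param alpha significance level for delay calls.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return object of class `age_replicate_run`: list with `models`,
#'   `performance` (per replicate: `r`, `t`, `p`, `q` across replicates),
#'   `estimates` ([relative_ages()] on the target cohort), `delay`
#'   ([test_delay()]), and the parameters used.
#' @export
run_replicate_protocol <- function(features, meta, train_cohort,
                                   target_cohort = NULL, R = 10,
                                   n_trees = 10000, gamma = 0.8,
                                   spline_df = 3, n_per_timepoint = NULL,
                                   alpha = 0.05, seed = 1) {
  m <- if (inherits(features, "feature_table")) t(features$abundance)
       else as.matrix(features)
  cohorts <- sort(unique(meta$cohort))
  target_cohort <- target_cohort %||% setdiff(cohorts, train_cohort)[1]
  seeds <- matrix(derive_seeds(seed, 3 * R), nrow = R)
  models <- vector("list", R)
  perf <- vector("list", R)
  for (r in seq_len(R)) {
    bal <- balance_subsample(meta, train_cohort,
                             n_per_timepoint = n_per_timepoint,
                             seed = seeds[r, 1])
    sp <- stratified_split(bal$sample_ids, meta, bal$plan, seed = seeds[r, 2])
    ages <- stats::setNames(meta$age_months[match(rownames(m), meta$sample_id)],
                            rownames(m))
    reg <- train_age_regressor(m[sp$train, , drop = FALSE], ages[sp$train],
                               n_trees = n_trees, gamma = gamma,
                               seed = seeds[r, 3])
    pred_test <- stats::predict(reg, m[sp$test, , drop = FALSE])
    pr <- pearson_r_test(pred_test, ages[sp$test])
    spl <- fit_calibration_spline(pred_test, ages[sp$test], df = spline_df)
    models[[r]] <- list(replicate = r, regressor = reg, spline = spl,
                        train_ids = sp$train, test_ids = sp$test,
                        plan = bal$plan, performance = pr)
    perf[[r]] <- data.frame(replicate = r, r = pr$r, t = pr$t, p = pr$p,
                            n_test = pr$n)
  }
  performance <- do.call(rbind, perf)
  performance$q <- bh_adjust(performance$p)
  target_ids <- meta$sample_id[meta$cohort == target_cohort]
  target_ids <- intersect(rownames(m), target_ids)
  estimates <- relative_ages(models, m[target_ids, , drop = FALSE], meta)
  delay <- test_delay(estimates, alpha = alpha)
  structure(list(train_cohort = train_cohort, target_cohort = target_cohort,
                 models = models, performance = performance,
                 estimates = estimates, delay = delay,
                 params = list(R = R, n_trees = n_trees, gamma = gamma,
                               spline_df = spline_df,
                               n_per_timepoint = n_per_timepoint,
                               alpha = alpha, seed = seed)),
            class = "age_replicate_run")
}

#' @export
print.age_replicate_run <- function(x, ...) {
  cat(sprintf("<age_replicate_run> trained on '%s' (R = %d), scored '%s'\n",
              x$train_cohort, x$params$R, x$target_cohort))
  cat(sprintf("  held-out r: %.2f-%.2f\n",
              min(x$performance$r), max(x$performance$r)))
  last <- x$delay$summary[nrow(x$delay$summary), ]
  cat(sprintf("  month %g: %.0f%% of replicates call delay, %.0f%% acceleration\n",
              last$timepoint, 100 * last$frac_delay, 100 * last$frac_accel))
  invisible(x)
}

#' Cross-cohort metagenomic-age analysis over one or more feature sets
#'
#' Runs [run_replicate_protocol()] in both directions (each cohort trained
#' and used to score the other) for each requested feature set: module
#' abundances, pathway abundances, or both concatenated.
#'
#' @param modules,pathways [feature_table]s at module and pathway level
#'   (either may be `NULL` if not requested by `feature_sets`).
#' @param meta sample metadata with exactly two cohorts.
#' @param feature_sets subset of `c("modules", "pathways", "both")`.
#' @param ... passed to [run_replicate_protocol()].
#' @param seed master seed.
#' @return nested list: `result[[feature_set]][[train_cohort]]` is an
#'   `age_replicate_run`.
#' @export
run_age_analysis <- function(modules = NULL, pathways = NULL, meta,
                             feature_sets = c("modules", "pathways", "both"),
                             ..., seed = 1) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  cohorts <- sort(unique(meta$cohort))
  if (length(cohorts) != 2) stop("metadata must contain exactly two cohorts")
  mat_of <- function(ft) t(ft$abundance)
  build <- function(fs) {
    switch(fs,
      modules = mat_of(modules),
      pathways = mat_of(pathways),
      both = cbind(mat_of(modules), mat_of(pathways)))
  }
  seeds <- matrix(derive_seeds(seed, 2 * length(feature_sets)), ncol = 2)
  out <- list()
  for (i in seq_along(feature_sets)) {
    fs <- feature_sets[i]
    m <- build(fs)
    out[[fs]] <- stats::setNames(lapply(seq_along(cohorts), function(j) {
      run_replicate_protocol(m, meta, train_cohort = cohorts[j],
                             target_cohort = cohorts[-j], ...,
                             seed = seeds[i, j])
    }), cohorts)
  }
  out
}
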