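#' Configuration for the two-cohort synthetic data generator
#'
#' The generator emulates longitudinal functional profiles for two infant
#' cohorts ("A", the reference cohort, and "B", the delayed cohort) sampled
#' at discrete ages. Feature age trends follow logistic (monotone saturating)
#' curves; cohort B experiences a developmental delay `delay_months`, applied
#' as a time shift floored at the youngest modeled age; a disjoint subset of
#' features carries a pure cohort offset with no delay, so that differential
#' abundance and developmental delay are separable signals; observation noise
#' is multiplicative log-normal.
#'
#' @param n_subjects_per_cohort subjects per cohort; each subject contributes
#'   one sample per time point.
#' @param timepoints strictly increasing sampling ages (months), all > 0.
#' @param n_features_ko number of KO-level features to simulate.
#' @param delay_months developmental lag (months, >= 0) imposed on cohort B.
#' @param frac_trending fraction of features with an age-dependent trend.
#' @param frac_cohort_shifted fraction of features with a pure cohort offset
#'   (flat in age, multiplicatively shifted in cohort B).
#'   `frac_trending + frac_cohort_shifted` must be <= 1.
#' @param noise_sd_log standard deviation (log scale) of the multiplicative
#'   log-normal observation noise; must be > 0.
#' @param seed integer master seed; the full output is byte-reproducible
#'   under a fixed seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_cohort = 25,
                             timepoints = c(2, 4, 6, 9, 12),
                             n_features_ko = 300,
                             delay_months = 2,
                             frac_trending = 0.5,
                             frac_cohort_shifted = 0.2,
                             noise_sd_log = 0.3,
                             seed = 1) {
  assert_scalar_number(n_subjects_per_cohort, "n_subjects_per_cohort", lower = 1)
  assert_scalar_number(n_features_ko, "n_features_ko", lower = 1)
  assert_scalar_number(delay_months, "delay_months", lower = 0)
  assert_scalar_number(frac_trending, "frac_trending", 0, 1)
  assert_scalar_number(frac_cohort_shifted, "frac_cohort_shifted", 0, 1)
  assert_scalar_number(noise_sd_log, "noise_sd_log")
  assert_scalar_number(seed, "seed")
  if (noise_sd_log <= 0) stop("noise_sd_log must be > 0")
  if (!is.numeric(timepoints) || length(timepoints) < 1 ||
      any(!is.finite(timepoints))) {
    stop("timepoints must be finite numbers")
  }
  if (any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing and all > 0")
  }
  if (frac_trending + frac_cohort_shifted > 1 + 1e-12) {
    stop("frac_trending + frac_cohort_shifted must be <= 1")
  }
  structure(list(
    n_subjects_per_cohort = as.integer(n_subjects_per_cohort),
    timepoints = as.numeric(timepoints),
    n_features_ko = as.integer(n_features_ko),
    delay_months = as.numeric(delay_months),
    frac_trending = frac_trending,
    frac_cohort_shifted = frac_cohort_shifted,
    noise_sd_log = noise_sd_log,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Expected (noise-free) abundance under the synthetic generative model
#'
#' Cohort A's mean for feature k at age t is a logistic curve
#' `baseline * (1 + amplitude * plogis((t - midpoint) / scale))` (constant for
#' non-trending features); cohort B's mean is the same curve evaluated at
#' `max(t - delay, t_min)` and multiplied by the feature's cohort-shift
#' multiplier.
#'
#' @param truth ground-truth data.frame from [generate_profiles()].
#' @param age age in months (scalar).
#' @param cohort `"A"` or `"B"`.
#' @param t_min youngest modeled age (floor for the delay shift).
#' @return numeric vector of expected abundances, one per feature.
#' @export
expected_abundance <- function(truth, age, cohort = c("A", "B"), t_min) {
  cohort <- match.arg(cohort)
  t_eff <- if (cohort == "B") max(age - truth$delay_months[1], t_min) else age
  mu <- truth$baseline *
    (1 + truth$amplitude * stats::plogis((t_eff - truth$midpoint) / truth$scale))
  if (cohort == "B") mu <- mu * truth$shift_multiplier
  mu
}

#' Generate two-cohort longitudinal KO-level profiles with known ground truth
#'
#' @param config a [synthetic_config()].
#' @return a list with elements
#'   \describe{
#'     \item{table}{[feature_table] of KO-level abundances (already on the
#'       normalized copy-number-like scale; baselines are O(1)).}
#'     \item{metadata}{data.frame with `sample_id`, `subject_id`,
#'       `age_months`, `cohort`, `breastfed`, `formula_fed`, `abx_current`,
#'       `abx_prior`.}
#'     \item{truth}{data.frame with one row per feature: `feature_id`,
#'       `type` (trending/shifted/flat), `baseline`, `amplitude`, `midpoint`,
#'       `scale`, `shift_multiplier`, `delay_months`.}
#'   }
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- derive_seeds(config$seed, 3)
  K <- config$n_features_ko
  tp <- config$timepoints
  t_min <- tp[1]
  feature_id <- sprintf("K%05d", seq_len(K))

  n_trend <- round(config$frac_trending * K)
  n_shift <- round(config$frac_cohort_shifted * K)
  if (n_trend + n_shift > K) n_shift <- K - n_trend
  type <- rep("flat", K)
  type[seq_len(n_trend)] <- "trending"
  if (n_shift > 0) type[n_trend + seq_len(n_shift)] <- "shifted"

  set.seed(seeds[1])
  baseline <- stats::rlnorm(K, meanlog = 0, sdlog = 0.75)
  up <- stats::runif(K) < 0.5
  # increasing features can grow several-fold; decreasing ones are bounded
  # below by -0.9 so means stay positive
  amplitude <- ifelse(up, stats::runif(K, 0.5, 2), -stats::runif(K, 0.3, 0.9))
  amplitude[type != "trending"] <- 0
  # functional maturation is still ongoing at the oldest sampled age:
  # midpoints extend past the study window so trends do not all saturate
  midpoint <- stats::runif(K, min(tp), max(tp) + 3)
  scale <- stats::runif(K, 1.5, 3.5)
  shift_multiplier <- rep(1, K)
  if (n_shift > 0) {
    # non-developmental cohort offsets on the scale of published module-level
    # effects: mostly below 2x, occasionally larger
    sgn <- ifelse(stats::runif(n_shift) < 0.5, -1, 1)
    shift_multiplier[type == "shifted"] <-
      exp(sgn * stats::runif(n_shift, log(1.25), log(2.5)))
  }
  truth <- data.frame(feature_id, type, baseline, amplitude, midpoint, scale,
                      shift_multiplier, delay_months = config$delay_months,
                      stringsAsFactors = FALSE)

  n_sub <- config$n_subjects_per_cohort
  meta <- do.call(rbind, lapply(c("A", "B"), function(co) {
    subj <- sprintf("%s%02d", co, seq_len(n_sub))
    expand.grid(subject_id = subj, age_months = tp,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
      , c("subject_id", "age_months")]
  }))
  meta$cohort <- substr(meta$subject_id, 1, 1)
  meta$sample_id <- sprintf("%s_m%g", meta$subject_id, meta$age_months)
  meta <- meta[order(meta$cohort, meta$subject_id, meta$age_months), ]
  rownames(meta) <- NULL

  set.seed(seeds[2])
  p_bf <- stats::plogis(2 - 0.35 * meta$age_months)
  meta$breastfed <- as.integer(stats::runif(nrow(meta)) < p_bf)
  meta$formula_fed <- as.integer(stats::runif(nrow(meta)) < (1 - 0.6 * p_bf))
  p_abx <- ifelse(meta$cohort == "B", 0.25, 0.10)
  meta$abx_current <- as.integer(stats::runif(nrow(meta)) < p_abx)
  meta$abx_prior <- as.integer(
    stats::runif(nrow(meta)) < (1 - (1 - p_abx)^(meta$age_months / 2)))
  meta <- meta[, c("sample_id", "subject_id", "age_months", "cohort",
                   "breastfed", "formula_fed", "abx_current", "abx_prior")]

  mu <- vapply(seq_len(nrow(meta)), function(i) {
    expected_abundance(truth, meta$age_months[i], meta$cohort[i], t_min)
  }, numeric(K))
  set.seed(seeds[3])
  noise <- matrix(stats::rnorm(K * nrow(meta), 0, config$noise_sd_log),
                  nrow = K)
  abundance <- mu * exp(noise)
  dimnames(abundance) <- list(feature_id, meta$sample_id)

  list(table = feature_table(abundance, "KO", normalized = TRUE),
       metadata = meta, truth = truth)
}

#' Generate a synthetic KO -> module / pathway membership map
#'
#' Assigns every KO to one module (with a configurable fraction belonging to
#' a second module, exercising support-based allocation) and to one pathway;
#' pathways are coarser groupings of whole modules, mirroring the KEGG
#' hierarchy's nesting.
#'
#' @param config a [synthetic_config()].
#' @param kos_per_module,modules_per_pathway expected group sizes.
#' @param frac_multi fraction of KOs that belong to two modules.
#' @return data.frame with columns `ko_id`, `group_id`, `level`
#'   (module/pathway), suitable for [functional_hierarchy()].
#' @export
synthetic_hierarchy <- function(config, kos_per_module = 5,
                                modules_per_pathway = 4, frac_multi = 0.2) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$n_features_ko
  ko <- sprintf("K%05d", seq_len(K))
  n_mod <- max(1L, ceiling(K / kos_per_module))
  mod_id <- sprintf("M%05d", seq_len(n_mod))
  set.seed(derive_seeds(config$seed, 5)[4])
  primary <- sample(rep_len(seq_len(n_mod), K))
  rows <- data.frame(ko_id = ko, group_id = mod_id[primary],
                     level = "module", stringsAsFactors = FALSE)
  multi <- which(stats::runif(K) < frac_multi)
  if (length(multi)) {
    second <- vapply(primary[multi], function(m) {
      sample(setdiff(seq_len(n_mod), m), 1)
    }, integer(1))
    rows <- rbind(rows, data.frame(ko_id = ko[multi], group_id = mod_id[second],
                                   level = "module", stringsAsFactors = FALSE))
  }
  n_path <- max(1L, ceiling(n_mod / modules_per_pathway))
  path_of_mod <- sprintf("map%05d", rep_len(seq_len(n_path), n_mod))
  names(path_of_mod) <- mod_id
  path_rows <- unique(data.frame(ko_id = rows$ko_id,
                                 group_id = path_of_mod[rows$group_id],
                                 level = "pathway", stringsAsFactors = FALSE))
  out <- rbind(rows, path_rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic read -> gene best-hit table with known expected counts
#'
#' Emulates the tied-best-hit output of a translated-search aligner: each
#' read carries 1..4 tied best-hit genes; genes carry 0..3 KO annotations; a
#' designated set of universal single-copy KOs is sampled at elevated weight
#' (their genes are ubiquitous), providing the normalization denominator.
#' Expected fractional gene and KO counts are recorded so downstream
#' profiling can be checked against ground truth.
#'
#' @param config a [synthetic_config()].
#' @param n_samples number of samples to emit hit tables for.
#' @param reads_per_sample reads per sample.
#' @param n_universal number of universal single-copy KOs.
#' @param frac_unannotated fraction of genes with no KO annotation.
#' @param frac_multi_ko fraction of annotated genes with 2-3 KOs.
#' @return list with `hits` (named list of per-sample data.frames with
#'   `read_id`, `gene_id`, `score`), `gene_to_ko` (data.frame `gene_id`,
#'   `ko_id`), `universal_kos` (character), and `expected` (list with
#'   `gene_counts` and `ko_counts` matrices and per-sample `loss` vector of
#'   unannotated mass).
#' @export
generate_hit_table <- function(config, n_samples = 4, reads_per_sample = 2000,
                               n_universal = 20, frac_unannotated = 0.1,
                               frac_multi_ko = 0.2) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(reads_per_sample, "reads_per_sample", lower = 1)
  set.seed(derive_seeds(config$seed, 5)[5])

  K <- config$n_features_ko
  ko <- sprintf("K%05d", seq_len(K))
  n_universal <- min(n_universal, K)
  universal <- ko[seq_len(n_universal)]

  n_genes <- 2L * K
  gene <- sprintf("g%05d", seq_len(n_genes))
  # one gene per universal KO up front, guaranteed single-KO annotation
  ko_of_gene <- vector("list", n_genes)
  ko_of_gene[seq_len(n_universal)] <- as.list(universal)
  for (i in (n_universal + 1):n_genes) {
    u <- stats::runif(1)
    ko_of_gene[[i]] <- if (u < frac_unannotated) character(0) else {
      k <- if (stats::runif(1) < frac_multi_ko) sample(2:3, 1) else 1L
      sample(ko, k)
    }
  }
  gene_to_ko <- data.frame(
    gene_id = rep(gene, lengths(ko_of_gene)),
    ko_id = unlist(ko_of_gene),
    stringsAsFactors = FALSE
  )

  # universal-KO genes get elevated sampling weight: single-copy core genes
  # are present in every genome, so every sample sees them
  w <- stats::rlnorm(n_genes, 0, 1)
  w[seq_len(n_universal)] <- w[seq_len(n_universal)] + 5
  samples <- sprintf("S%02d", seq_len(n_samples))
  hits <- stats::setNames(vector("list", n_samples), samples)
  gene_counts <- matrix(0, n_genes, n_samples, dimnames = list(gene, samples))
  for (s in seq_len(n_samples)) {
    k_hits <- sample(1:4, reads_per_sample, replace = TRUE,
                     prob = c(0.7, 0.2, 0.07, 0.03))
    picked <- lapply(k_hits, function(k) sample.int(n_genes, k, prob = w))
    read_id <- sprintf("%s_r%05d", samples[s], seq_len(reads_per_sample))
    hits[[s]] <- data.frame(
      read_id = rep(read_id, k_hits),
      gene_id = gene[unlist(picked)],
      score = round(stats::runif(sum(k_hits), 50, 300), 1),
      stringsAsFactors = FALSE
    )
    inc <- tapply(rep(1 / k_hits, k_hits), unlist(picked), sum)
    gene_counts[as.integer(names(inc)), s] <- as.numeric(inc)
  }

  n_ko_of_gene <- lengths(ko_of_gene)
  annotated <- n_ko_of_gene > 0
  share <- gene_counts[annotated, , drop = FALSE] / n_ko_of_gene[annotated]
  ko_counts <- rowsum(
    share[rep(seq_len(sum(annotated)), n_ko_of_gene[annotated]), , drop = FALSE],
    group = gene_to_ko$ko_id
  )
  full <- matrix(0, K, n_samples, dimnames = list(ko, samples))
  full[rownames(ko_counts), ] <- ko_counts
  loss <- colSums(gene_counts[!annotated, , drop = FALSE])

  list(hits = hits, gene_to_ko = gene_to_ko, universal_kos = universal,
       expected = list(gene_counts = gene_counts, ko_counts = full,
                       loss = loss))
}
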