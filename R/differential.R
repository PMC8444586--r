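#' Per-time-point differential abundance between two cohorts
#'
#' For every feature at one time point, compares the two groups with a
#' two-tailed Wilcoxon rank-sum test, adjusts p-values by Benjamini-Hochberg
#' within the family of all features of this table's level at this time
#' point, and reports the log10 ratio of group medians (reference over
#' comparison). Direction is assigned from the sign of the log ratio for
#' features passing the q threshold.
#'
#' @param x a [feature_table] (module, pathway or KO level).
#' @param meta sample metadata data.frame (see [read_metadata()]).
#' @param timepoint age in months to compare at.
#' @param grouping metadata column holding the two group labels (default
#'   `"cohort"`; any binary covariate column works, e.g. `breastfed`).
#' @param reference,comparison the two group labels; by default the first
#'   and second sorted unique values of the grouping column. The log ratio
#'   is `log10(median(reference) / median(comparison))`.
#' @param q_threshold significance threshold on q (default 0.01).
#' @param pseudocount guard for zero medians (see [log_median_ratio()]).
#' @return data.frame with one row per feature: `feature_id`, `level`,
#'   `timepoint`, `p_value`, `q_value`, `log10_median_ratio`, `direction`
#'   (`up_in_ref` / `up_in_cmp` / `ns`), `n_ref`, `n_cmp`.
#' @export
compare_cohorts <- function(x, meta, timepoint, grouping = "cohort",
                            reference = NULL, comparison = NULL,
                            q_threshold = 0.01, pseudocount = 1e-10) {
  stopifnot(inherits(x, "feature_table"))
  if (!grouping %in% names(meta)) stop("metadata has no column '", grouping, "'")
  meta_t <- meta[meta$age_months == timepoint, , drop = FALSE]
  levels_present <- sort(unique(as.character(meta_t[[grouping]])))
  reference <- reference %||% levels_present[1]
  comparison <- comparison %||% setdiff(levels_present, reference)[1]
  ids_ref <- meta_t$sample_id[meta_t[[grouping]] == reference]
  ids_cmp <- meta_t$sample_id[meta_t[[grouping]] == comparison]
  for (grp in list(c(reference, length(ids_ref)), c(comparison, length(ids_cmp)))) {
    if (as.integer(grp[2]) < 2) {
      stop(sprintf("group '%s' has %s sample(s) at month %s; need >= 2",
                   grp[1], grp[2], format(timepoint)))
    }
  }
  m <- x$abundance
  missing <- setdiff(c(ids_ref, ids_cmp), colnames(m))
  if (length(missing)) {
    stop("samples in metadata but not in table: ", paste(missing, collapse = ", "))
  }
  mr <- m[, ids_ref, drop = FALSE]
  mc <- m[, ids_cmp, drop = FALSE]
  p <- vapply(seq_len(nrow(m)),
              function(i) wilcoxon_rank_sum(mr[i, ], mc[i, ]), numeric(1))
  lmr <- vapply(seq_len(nrow(m)),
                function(i) log_median_ratio(mr[i, ], mc[i, ], pseudocount),
                numeric(1))
  q <- bh_adjust(p)
  direction <- rep("ns", nrow(m))
  sig <- q < q_threshold & lmr != 0
  direction[sig & lmr > 0] <- "up_in_ref"
  direction[sig & lmr < 0] <- "up_in_cmp"
  out <- data.frame(feature_id = rownames(m), level = x$level,
                    timepoint = timepoint, p_value = p, q_value = q,
                    log10_median_ratio = lmr, direction = direction,
                    n_ref = length(ids_ref), n_cmp = length(ids_cmp),
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- c(reference = reference, comparison = comparison)
  rownames(out) <- NULL
  out
}

#' Classify per-feature temporal patterns of differential abundance
#'
#' Collapses per-time-point differential results into one row per feature:
#' a significance label per time point, a directional-consistency flag (no
#' feature flips between cohorts among its significant time points), and an
#' expansion flag (|log10 median ratio| strictly larger at the last shared
#' time point than at the first).
#'
#' @param results data.frame of rbind-ed [compare_cohorts()] outputs over
#'   several time points; every time point must carry the same feature set.
#' @return data.frame with `feature_id`, one `label_m<t>` column per time
#'   point, `pattern` (comma-separated labels), `consistent`, `expanding`.
#' @export
classify_patterns <- function(results) {
  tps <- sort(unique(results$timepoint))
  feats <- unique(results$feature_id)
  for (t in tps) {
    have <- results$feature_id[results$timepoint == t]
    if (!setequal(have, feats) || length(have) != length(feats)) {
      stop("every time point must cover the same feature universe exactly once")
    }
  }
  dir_mat <- sapply(tps, function(t) {
    sub <- results[results$timepoint == t, ]
    sub$direction[match(feats, sub$feature_id)]
  })
  dir_mat <- matrix(dir_mat, nrow = length(feats),
                    dimnames = list(feats, paste0("label_m", tps)))
  lmr_first <- results$log10_median_ratio[results$timepoint == tps[1]][
    match(feats, results$feature_id[results$timepoint == tps[1]])]
  lmr_last <- results$log10_median_ratio[results$timepoint == tps[length(tps)]][
    match(feats, results$feature_id[results$timepoint == tps[length(tps)]])]
  consistent <- apply(dir_mat, 1, function(lbl) {
    sig <- lbl[lbl != "ns"]
    length(unique(sig)) <= 1
  })
  out <- data.frame(feature_id = feats, dir_mat,
                    pattern = apply(dir_mat, 1, paste, collapse = ","),
                    consistent = consistent,
                    expanding = abs(lmr_last) > abs(lmr_first),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count features whose cohort difference expands between two time points
#'
#' A feature expands when the absolute log10 median ratio at the later time
#' point is strictly greater than at the earlier one.
#'
#' @param results_t1,results_t2 [compare_cohorts()] outputs at the earlier
#'   and later time point.
#' @param features feature ids to consider (must be present in both).
#' @return list with `n_expanding` and `n_total`.
#' @export
count_expansion <- function(results_t1, results_t2, features) {
  i1 <- match(features, results_t1$feature_id)
  i2 <- match(features, results_t2$feature_id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("features missing from results: ",
         paste(features[is.na(i1) | is.na(i2)], collapse = ", "))
  }
  expanding <- abs(results_t2$log10_median_ratio[i2]) >
    abs(results_t1$log10_median_ratio[i1])
  list(n_expanding = sum(expanding), n_total = length(features))
}
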