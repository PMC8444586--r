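#' Two-tailed Wilcoxon rank-sum test
#'
#' Exact p-value when both groups have at most 12 observations and there are
#' no ties; otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction. If every value in both groups is
#' identical the test is uninformative and p = 1.
#'
#' @param x,y numeric abundance vectors (each length >= 1).
#' @return two-tailed p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  z <- c(x, y)
  if (length(unique(z)) == 1L) return(1)
  ties <- anyDuplicated(z) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  min(p, 1)
}

#' Two-tailed Wilcoxon signed-rank test for a zero median
#'
#' Tests whether the median of `x - mu` is zero. Zeros are dropped (Wilcoxon
#' convention); absolute differences are midranked. For n <= `exact_max` the
#' p-value is computed from the exact sign-flip permutation distribution of
#' the positive-rank sum (valid under ties, where the distribution is
#' conditional on the observed midranks); beyond that, the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. All differences zero gives p = 1.
#'
#' @param x numeric vector.
#' @param mu null median (default 0).
#' @param exact_max largest n for which the exact distribution is enumerated.
#' @return two-tailed p-value.
#' @export
signed_rank_test <- function(x, mu = 0, exact_max = 14) {
  stopifnot(all(is.finite(x)))
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all 2^n sign assignments, via convolution on a
    # half-unit grid (midranks are multiples of 1/2)
    g <- as.integer(round(2 * r))
    dist <- 1
    for (gi in g) {
      padded <- c(dist, numeric(gi))
      shifted <- c(numeric(gi), dist)
      dist <- (padded + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[(v2 + 1L):length(dist)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu_v - sign(v - mu_v) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotonicity enforcement; the output is in the
#' same order as the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with the t-formula significance test
#'
#' Computes r and its two-tailed p from a t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#'
#' @param pred,obs numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return list with `r`, `t`, `p`, `n`.
#' @export
pearson_r_test <- function(pred, obs) {
  n <- length(pred)
  stopifnot(length(obs) == n)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(pred, obs)
  t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 0))
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p, n = n)
}

#' Log10 ratio of group medians
#'
#' `log10((median(x) + eps) / (median(y) + eps))`; the pseudocount guards
#' zero medians.
#'
#' @param x,y nonnegative numeric vectors (x: reference group).
#' @param pseudocount additive guard, default 1e-10 on the normalized
#'   abundance scale.
#' @return signed real; positive means higher median in `x`.
#' @export
log_median_ratio <- function(x, y, pseudocount = 1e-10) {
  stopifnot(length(x) >= 1, length(y) >= 1, all(x >= 0), all(y >= 0))
  log10((stats::median(x) + pseudocount) / (stats::median(y) + pseudocount))
}

#' Chi-squared enrichment test on a 2x2 classification
#'
#' Pearson chi-squared on the 2x2 table (cohort-A-associated vs
#' cohort-B-associated) x (in category vs not), 1 degree of freedom, no
#' continuity correction by default.
#'
#' @param significant_a,significant_b character vectors of feature ids
#'   associated with each cohort (disjoint).
#' @param in_category named logical vector (or character vector of
#'   in-category feature ids) defining the category.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `chi2`, `p`, and the 2x2 `table`.
#' @export
category_enrichment <- function(significant_a, significant_b, in_category,
                                correct = FALSE) {
  if (is.character(in_category)) {
    cat_ids <- in_category
    in_cat <- function(ids) ids %in% cat_ids
  } else if (is.logical(in_category) && !is.null(names(in_category))) {
    in_cat <- function(ids) {
      v <- in_category[ids]
      if (anyNA(v)) stop("category membership missing for: ",
                         paste(ids[is.na(v)], collapse = ", "))
      v
    }
  } else {
    stop("in_category must be a character vector of ids or a named logical vector")
  }
  tab <- rbind(A = c(sum(in_cat(significant_a)), sum(!in_cat(significant_a))),
               B = c(sum(in_cat(significant_b)), sum(!in_cat(significant_b))))
  colnames(tab) <- c("in_category", "out_category")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared enrichment needs nonzero marginals in the 2x2 table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value), table = tab)
}
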