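#' Build a functional hierarchy from a long KO-membership table
#'
#' @param map data.frame with columns `ko_id`, `group_id`, `level` (values
#'   `"module"` or `"pathway"`), one row per membership pair.
#' @return object of class `functional_hierarchy` with mutually consistent
#'   forward (KO -> groups) and reverse (group -> member KOs) maps per level.
#' @export
functional_hierarchy <- function(map) {
  required <- c("ko_id", "group_id", "level")
  if (!is.data.frame(map) || !all(required %in% names(map))) {
    stop("map must be a data.frame with columns ko_id, group_id, level")
  }
  bad <- setdiff(unique(map$level), c("module", "pathway"))
  if (length(bad)) stop("unknown levels in map: ", paste(bad, collapse = ", "))
  map <- unique(map[required])
  build <- function(lv) {
    sub <- map[map$level == lv, , drop = FALSE]
    list(ko_to_group = split(sub$group_id, sub$ko_id),
         group_to_ko = split(sub$ko_id, sub$group_id))
  }
  structure(list(module = build("module"), pathway = build("pathway")),
            class = "functional_hierarchy")
}

#' @export
print.functional_hierarchy <- function(x, ...) {
  cat(sprintf("<functional_hierarchy> %d KOs -> %d modules; %d KOs -> %d pathways\n",
              length(x$module$ko_to_group), length(x$module$group_to_ko),
              length(x$pathway$ko_to_group), length(x$pathway$group_to_ko)))
  invisible(x)
}

#' Fractional read counting: reads to gene counts
#'
#' Each read contributes a total weight of exactly 1; a read tied between k
#' best-hit genes contributes 1/k to each, so total gene mass equals the
#' number of reads.
#'
#' @param hits data.frame with columns `read_id`, `gene_id`; rows are the
#'   tied best hits of each read ((read, gene) pairs must be unique).
#' @return named numeric vector of fractional gene counts.
#' @export
reads_to_gene_counts <- function(hits) {
  if (!is.data.frame(hits) || !all(c("read_id", "gene_id") %in% names(hits))) {
    stop("hits must be a data.frame with columns read_id and gene_id")
  }
  if (nrow(hits) == 0) stop("hits table is empty")
  if (anyDuplicated(hits[c("read_id", "gene_id")])) {
    stop("duplicated (read_id, gene_id) pairs in hit table")
  }
  k <- table(hits$read_id)
  w <- 1 / as.numeric(k[hits$read_id])
  counts <- tapply(w, hits$gene_id, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out[order(names(out))]
}

#' Fractional annotation: gene counts to KO counts
#'
#' Each annotated gene's count is split evenly over its KOs; counts of genes
#' with no KO annotation are dropped into a reported loss tally so that
#' `sum(ko_counts) + loss == sum(gene_counts)` exactly.
#'
#' @param gene_counts named numeric vector of fractional gene counts.
#' @param gene_to_ko data.frame with columns `gene_id`, `ko_id` (one row per
#'   annotation pair).
#' @return list with `ko_counts` (named numeric) and `loss` (unannotated
#'   mass).
#' @export
gene_counts_to_ko_counts <- function(gene_counts, gene_to_ko) {
  if (!all(c("gene_id", "ko_id") %in% names(gene_to_ko))) {
    stop("gene_to_ko must have columns gene_id and ko_id")
  }
  kos_of <- split(gene_to_ko$ko_id, gene_to_ko$gene_id)
  n_ko <- lengths(kos_of)[names(gene_counts)]
  n_ko[is.na(n_ko)] <- 0L
  annotated <- n_ko > 0
  loss <- sum(gene_counts[!annotated])
  if (!any(annotated)) {
    return(list(ko_counts = stats::setNames(numeric(0), character(0)),
                loss = loss))
  }
  share <- gene_counts[annotated] / n_ko[annotated]
  ko_ids <- unlist(kos_of[names(gene_counts)[annotated]], use.names = FALSE)
  counts <- tapply(rep(share, n_ko[annotated]), ko_ids, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  list(ko_counts = out[order(names(out))], loss = loss)
}

#' Single-copy marker normalization of KO counts
#'
#' Divides every KO count in a sample by the median count of a provided list
#' of universal single-copy KOs in that sample, so normalized abundances
#' approximate average copy number per cell and the universal-KO median of
#' the output is 1. Universal KOs absent from the table count as 0 toward
#' the median.
#'
#' @param x a KO-level [feature_table] (or a named numeric vector for a
#'   single sample).
#' @param universal_kos character vector of universal single-copy KO ids.
#' @return object of the same shape as `x`, normalized; for feature tables
#'   the `normalized` flag is set.
#' @export
normalize_single_copy <- function(x, universal_kos) {
  if (length(universal_kos) == 0) stop("universal_kos must be nonempty")
  norm_one <- function(v, sample = "sample") {
    u <- stats::setNames(numeric(length(universal_kos)), universal_kos)
    present <- intersect(universal_kos, names(v))
    u[present] <- v[present]
    med <- stats::median(u)
    if (!is.finite(med) || med <= 0) {
      stop(sprintf("sample '%s' cannot be normalized: universal single-copy KO median is %s",
                   sample, format(med)))
    }
    v / med
  }
  if (inherits(x, "feature_table")) {
    if (x$level != "KO") stop("single-copy normalization applies to KO-level tables")
    m <- x$abundance
    for (j in seq_len(ncol(m))) {
      m[, j] <- norm_one(stats::setNames(m[, j], rownames(m)), colnames(m)[j])
    }
    feature_table(m, "KO", normalized = TRUE)
  } else {
    norm_one(x)
  }
}

#' Support-based aggregation of KO abundances to modules or pathways
#'
#' A group's support in a sample is the fraction of its member KOs with
#' nonzero abundance there. A KO belonging to several groups distributes its
#' abundance across them proportionally to their supports; if every
#' candidate group has zero support the share is split evenly; a KO in
#' exactly one group gives it its full abundance. Total distributed
#' abundance per KO equals its input abundance, so per-sample mass is
#' conserved up to the unmapped tally (KOs absent from the hierarchy).
#'
#' @param x a KO-level [feature_table] of normalized abundances.
#' @param hierarchy a [functional_hierarchy].
#' @param level `"module"` or `"pathway"`.
#' @return [feature_table] at the requested level, with attribute
#'   `"unmapped"`: a per-sample numeric vector of abundance mass carried by
#'   KOs absent from the hierarchy.
#' @export
aggregate_support <- function(x, hierarchy, level = c("module", "pathway")) {
  stopifnot(inherits(x, "feature_table"), inherits(hierarchy, "functional_hierarchy"))
  level <- match.arg(level)
  if (x$level != "KO") stop("aggregation starts from a KO-level table")
  h <- hierarchy[[level]]
  groups <- sort(names(h$group_to_ko))
  m <- x$abundance
  kos <- rownames(m)
  mapped <- kos %in% names(h$ko_to_group)

  # membership matrix: groups x mapped KOs
  G <- matrix(0, length(groups), sum(mapped),
              dimnames = list(groups, kos[mapped]))
  for (g in groups) {
    member <- intersect(h$group_to_ko[[g]], kos[mapped])
    G[g, member] <- 1
  }
  group_size <- lengths(h$group_to_ko)[groups]

  out <- matrix(0, length(groups), ncol(m), dimnames = list(groups, colnames(m)))
  mm <- m[mapped, , drop = FALSE]
  for (j in seq_len(ncol(m))) {
    v <- mm[, j]
    support <- as.numeric(G %*% (v > 0)) / group_size
    W <- G * support                      # candidate-group weights per KO
    tot <- colSums(W)
    zero <- tot == 0
    if (any(zero)) {                      # all-candidate support 0: even split
      W[, zero] <- G[, zero, drop = FALSE]
      tot[zero] <- colSums(G[, zero, drop = FALSE])
    }
    out[, j] <- as.numeric(W %*% (v / tot))
  }
  unmapped <- colSums(m[!mapped, , drop = FALSE])
  res <- feature_table(out, level, normalized = x$normalized)
  attr(res, "unmapped") <- unmapped
  res
}

#' Run the full profiling chain on per-sample hit tables
#'
#' Convenience wrapper: fractional read counting, fractional KO annotation,
#' single-copy normalization, and support-based aggregation to module and
#' pathway tables.
#'
#' @param hits named list of per-sample hit data.frames (`read_id`,
#'   `gene_id`).
#' @param gene_to_ko data.frame (`gene_id`, `ko_id`).
#' @param universal_kos character vector of universal single-copy KO ids.
#' @param hierarchy a [functional_hierarchy], or `NULL` to stop at the KO
#'   level.
#' @return list with `ko_raw`, `ko` (normalized), `modules`, `pathways`
#'   feature tables and `loss` (per-sample unannotated read mass).
#' @export
profile_samples <- function(hits, gene_to_ko, universal_kos, hierarchy = NULL) {
  stopifnot(is.list(hits), length(hits) > 0, !is.null(names(hits)))
  per_sample <- lapply(hits, function(h) {
    gc <- reads_to_gene_counts(h)
    gene_counts_to_ko_counts(gc, gene_to_ko)
  })
  all_kos <- sort(unique(unlist(lapply(per_sample, function(p) names(p$ko_counts)))))
  m <- matrix(0, length(all_kos), length(hits),
              dimnames = list(all_kos, names(hits)))
  for (s in names(hits)) {
    kc <- per_sample[[s]]$ko_counts
    m[names(kc), s] <- kc
  }
  ko_raw <- feature_table(m, "KO", normalized = FALSE)
  ko <- normalize_single_copy(ko_raw, universal_kos)
  out <- list(ko_raw = ko_raw, ko = ko,
              loss = vapply(per_sample, `[[`, numeric(1), "loss"))
  if (!is.null(hierarchy)) {
    out$modules <- aggregate_support(ko, hierarchy, "module")
    out$pathways <- aggregate_support(ko, hierarchy, "pathway")
  }
  out
}
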