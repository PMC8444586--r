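test_that("reads are split fractionally and evenly among tied genes", {
  hits <- data.frame(read_id = c("r1", "r2", "r2"),
                     gene_id = c("gA", "gA", "gB"))
  gc <- reads_to_gene_counts(hits)
  expect_equal(gc[["gA"]], 1.5)
  expect_equal(gc[["gB"]], 0.5)

  # a 4-way tie splits into quarters that sum to one
  hits4 <- data.frame(read_id = "r1", gene_id = paste0("g", 1:4))
  gc4 <- reads_to_gene_counts(hits4)
  expect_equal(unname(gc4), rep(0.25, 4))

  # conservation: single-hit reads sum to the read count
  single <- data.frame(read_id = sprintf("r%03d", 1:100),
                       gene_id = sample(c("gA", "gB", "gC"), 100, replace = TRUE))
  expect_equal(sum(reads_to_gene_counts(single)), 100)

  expect_error(reads_to_gene_counts(hits[0, ]), "empty")
  expect_error(reads_to_gene_counts(rbind(hits, hits[1, ])), "duplicated")
})

test_that("gene counts are split fractionally and evenly among KOs", {
  map <- data.frame(gene_id = c("g", "g", "g"), ko_id = c("K1", "K2", "K3"))
  res <- gene_counts_to_ko_counts(c(g = 1.5), map)
  expect_equal(unname(res$ko_counts), rep(0.5, 3))
  expect_equal(res$loss, 0)

  # unannotated genes go to the loss tally; mass is conserved exactly
  res2 <- gene_counts_to_ko_counts(c(g = 1.5, u1 = 2, u2 = 0.25), map)
  expect_equal(res2$loss, 2.25)
  expect_equal(sum(res2$ko_counts) + res2$loss, 3.75)

  # all genes unannotated -> zero vector, loss = total
  res3 <- gene_counts_to_ko_counts(c(u1 = 2, u2 = 1), map[0, ])
  expect_equal(length(res3$ko_counts), 0)
  expect_equal(res3$loss, 3)
})

test_that("single-copy normalization divides by the universal-KO median", {
  v <- c(U1 = 2, U2 = 4, U3 = 6, K9 = 8)
  out <- normalize_single_copy(v, c("U1", "U2", "U3"))
  expect_equal(out[["K9"]], 2)
  expect_equal(median(out[c("U1", "U2", "U3")]), 1)

  # scale invariance
  expect_equal(normalize_single_copy(v * 7, c("U1", "U2", "U3")), out)

  # zero median -> error naming the sample
  m <- cbind(S1 = c(U1 = 0, U2 = 0, U3 = 0, K9 = 5))
  ft <- feature_table(m, "KO")
  expect_error(normalize_single_copy(ft, c("U1", "U2", "U3")), "S1")
})

test_that("normalization is idempotent", {
  cfg <- tiny_config()
  ht <- generate_hit_table(cfg, n_samples = 3, reads_per_sample = 500)
  prof <- profile_samples(ht$hits, ht$gene_to_ko, ht$universal_kos)
  once <- as.matrix(prof$ko)
  twice <- as.matrix(normalize_single_copy(prof$ko, ht$universal_kos))
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("support-based aggregation allocates proportionally to support", {
  h <- toy_hierarchy()
  # M1 = {K1..K5} (K1 shared), M2 = {K1}. Sample: K1..K4 nonzero, K5 zero.
  m <- cbind(S1 = c(K1 = 1, K2 = 2, K3 = 1, K4 = 1, K5 = 0))
  ft <- feature_table(m, "KO", normalized = TRUE)
  out <- aggregate_support(ft, h, "module")
  # supports: M1 = 4/5 = 0.8, M2 = 1/1 = 1.0 -> K1 shares 0.8/1.8 and 1/1.8
  expect_equal(as.matrix(out)["M1", "S1"], 2 + 1 + 1 + 1 * (0.8 / 1.8))
  expect_equal(as.matrix(out)["M2", "S1"], 1 * (1.0 / 1.8))
  # per-sample mass conserved
  expect_equal(sum(as.matrix(out)), sum(m))

  # single-membership KO gives its full abundance
  out_p <- aggregate_support(ft, h, "pathway")
  expect_equal(as.matrix(out_p)["P1", "S1"], 5)
})

test_that("equal supports split evenly and unmapped KOs are tallied", {
  h <- functional_hierarchy(data.frame(
    ko_id = c("K1", "K1"), group_id = c("M1", "M2"),
    level = "module", stringsAsFactors = FALSE))
  # K1 is the only member of both groups: supports are equal, so its
  # abundance splits 50/50. K9 is absent from the hierarchy.
  m <- cbind(S1 = c(K1 = 2, K9 = 3))
  out <- aggregate_support(feature_table(m, "KO"), h, "module")
  expect_equal(unname(as.matrix(out)[, "S1"]), c(1, 1))
  expect_equal(unname(attr(out, "unmapped")), 3)
})

test_that("profiling is invariant to read, gene and sample order", {
  cfg <- tiny_config(seed = 21)
  ht <- generate_hit_table(cfg, n_samples = 2, reads_per_sample = 300)
  base <- profile_samples(ht$hits, ht$gene_to_ko, ht$universal_kos)
  shuf <- lapply(ht$hits, function(h) h[sample(nrow(h)), ])
  map_shuf <- ht$gene_to_ko[sample(nrow(ht$gene_to_ko)), ]
  perm <- profile_samples(rev(shuf), map_shuf, ht$universal_kos)
  a <- as.matrix(base$ko)
  b <- as.matrix(perm$ko)[rownames(a), colnames(a)]
  expect_equal(b, a)
})

test_that("end-to-end read mass is conserved through KO profiling", {
  cfg <- tiny_config(seed = 31)
  n_reads <- 700
  ht <- generate_hit_table(cfg, n_samples = 3, reads_per_sample = n_reads)
  prof <- profile_samples(ht$hits, ht$gene_to_ko, ht$universal_kos)
  total <- colSums(as.matrix(prof$ko_raw)) + prof$loss
  expect_equal(unname(total), rep(n_reads, 3), tolerance = 1e-9)
  # and matches the generator's recorded expectation exactly
  expect_equal(as.matrix(prof$ko_raw),
               ht$expected$ko_counts[rownames(as.matrix(prof$ko_raw)), ],
               tolerance = 1e-12)
})
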