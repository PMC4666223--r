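make_region_results <- function(genes, q, change, group1 = "A", group2 = "B") {
  n <- length(genes)
  data.frame(group1 = group1, group2 = group2, chrom = "chr1",
             start = seq(0, by = 1000, length.out = n),
             end = seq(1000, by = 1000, length.out = n),
             name = paste0("r", seq_len(n)), gene_name = genes,
             n_probes = 5L, p_group1 = q, p_group2 = 1 - q / 2,
             q_group1 = q, q_group2 = 1 - q / 4,
             direction = ifelse(change >= 0, group2, group1),
             q = q, change_min = change - 0.05, change_median = change,
             change_max = change + 0.05, stringsAsFactors = FALSE)
}

test_that("gene ranking keeps the best region per gene and orders deterministically", {
  rr <- make_region_results(
    genes  = c("G1", "G1", "G2", "G3", "G4", "G5"),
    q      = c(0.01, 0.2, 0.05, 0.05, 0.05, 0.001),
    change = c(0.30, 0.1, 0.30, -0.30, 0.30, -0.2)
  )
  ranked <- rank_genes(rr)
  # G1 scored from its q = 0.01 region
  expect_equal(ranked$score[ranked$gene == "G1"], -log10(0.01))
  # exact expected order: positive scores by magnitude, alphabetical ties,
  # then negatives (most negative last)
  expect_equal(ranked$gene, c("G1", "G2", "G4", "G3", "G5"))
  expect_equal(ranked$score, c(2, -log10(0.05), -log10(0.05),
                               log10(0.05), -3), tolerance = 1e-12)
  # equal q everywhere: the positive-change gene ranks first
  rr2 <- make_region_results(c("Gneg", "Gpos"), c(0.05, 0.05), c(-0.3, 0.3))
  expect_equal(rank_genes(rr2)$gene, c("Gpos", "Gneg"))
  # alternative metric: signed median change
  expect_equal(rank_genes(rr2, metric = "change")$score, c(0.3, -0.3))
  expect_error(rank_genes(make_region_results("G", 0.1, 0.1)[0, ]), "gene")
})

test_that("enrichment score handles the extreme single-hit case and rejects empty sets", {
  ranked <- data.frame(gene = paste0("G", 1:10), score = seq(10, 1))
  es <- enrichment_score(ranked, "G1", weight_p = 0)
  expect_equal(es$ES, 1)
  expect_equal(es$peak_index, 1)
  expect_error(enrichment_score(ranked, c("X1", "X2")), "untestable")
})

test_that("enrichment score equals an independent running-sum computation", {
  set.seed(55)
  for (i in 1:30) {
    n <- 50
    genes <- paste0("G", sample(1000, n))
    scores <- sort(rnorm(n, sd = 3), decreasing = TRUE)
    ranked <- data.frame(gene = genes, score = scores)
    set_genes <- sample(genes, 8)
    for (w in c(0, 1, 2)) {
      mine <- enrichment_score(ranked, set_genes, weight_p = w)
      ref <- es_oracle(genes, scores, set_genes, w)
      expect_equal(mine$ES, ref$ES, tolerance = 1e-12)
      # the two peaks mark equal-magnitude running-sum extrema
      expect_equal(abs(mine$running[ref$peak_index]), abs(ref$ES),
                   tolerance = 1e-12)
    }
  }
})

test_that("unweighted ES is invariant to monotone score transforms and negates on reversal", {
  set.seed(66)
  genes <- paste0("G", 1:40)
  scores <- sort(runif(40, -2, 5), decreasing = TRUE)
  ranked <- data.frame(gene = genes, score = scores)
  set_genes <- sample(genes, 6)
  base <- enrichment_score(ranked, set_genes, weight_p = 0)

  mono <- data.frame(gene = genes, score = exp(scores))  # same order
  expect_equal(enrichment_score(mono, set_genes, weight_p = 0)$ES, base$ES)

  rev_ranked <- ranked[rev(seq_len(40)), ]
  expect_equal(enrichment_score(rev_ranked, set_genes, weight_p = 0)$ES,
               -base$ES, tolerance = 1e-12)
})

test_that("permutation p-values are seeded, bounded and consistent across seeds", {
  set.seed(77)
  genes <- paste0("G", 1:100)
  ranked <- data.frame(gene = genes,
                       score = sort(rnorm(100), decreasing = TRUE))
  set_genes <- genes[c(2, 5, 9, 20, 40)]
  p1 <- permutation_p(ranked, set_genes, n_perm = 200, seed = 5)
  p2 <- permutation_p(ranked, set_genes, n_perm = 200, seed = 5)
  expect_identical(p1$p_perm, p2$p_perm)

  # a maximally concentrated set beats every null draw
  strong <- data.frame(gene = genes,
                       score = c(rep(100, 5), rep(0.01, 95)))
  ps <- permutation_p(strong, genes[1:5], n_perm = 200, seed = 3)
  expect_equal(ps$ES, 1)
  expect_equal(ps$p_perm, 1 / 201)

  # two independent seeds agree within 3 binomial standard errors
  pa <- permutation_p(ranked, set_genes, n_perm = 2000, seed = 11)$p_perm
  pb <- permutation_p(ranked, set_genes, n_perm = 2000, seed = 12)$p_perm
  se <- sqrt(pa * (1 - pa) / 2000)
  expect_lt(abs(pa - pb), 3 * se + 1e-9)

  expect_error(permutation_p(ranked, set_genes, n_perm = 10), "100")
})

test_that("permutation p is approximately uniform under a random null", {
  set.seed(88)
  genes <- paste0("G", 1:60)
  ps <- vapply(1:200, function(i) {
    ranked <- data.frame(gene = genes,
                         score = sort(rnorm(60), decreasing = TRUE))
    permutation_p(ranked, sample(genes, 6), n_perm = 100, seed = 1000 + i)$p_perm
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("leading edge selects the correct side of the peak; Jaccard overlaps", {
  ranked <- data.frame(gene = paste0("G", 1:10), score = seq(5, -4))
  # positive ES: members at ranks <= peak
  expect_equal(leading_edge(ranked, c("G1", "G3", "G9"), es = 0.5, peak_index = 4),
               c("G1", "G3"))
  # negative ES: members after the peak
  expect_equal(leading_edge(ranked, c("G1", "G3", "G9"), es = -0.5, peak_index = 4),
               "G9")

  m <- leading_edge_overlap(list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"),
                                 s3 = c("X", "Y")))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["s1", "s2"], 0.5)
  expect_equal(m["s1", "s3"], 0)
  expect_equal(leading_edge_overlap(list(a = c("A"), b = c("A")))["a", "b"], 1)
})

test_that("run_gsea ties the pieces together and reports untestable sets", {
  rr <- make_region_results(
    genes  = paste0("G", 1:20),
    q      = c(rep(0.001, 5), runif(15, 0.2, 0.9)),
    change = c(rep(0.3, 5), rnorm(15, 0, 0.02))
  )
  sets <- list(hot = paste0("G", 1:5), cold = paste0("G", 10:14),
               absent = c("Z1", "Z2"))
  out <- run_gsea(rr, sets, n_perm = 200, seed = 9)
  expect_equal(out$untestable, "absent")
  expect_equal(nrow(out$results), 2)
  hot <- out$results[out$results$set == "hot", ]
  expect_gt(hot$ES, 0)
  expect_lt(hot$p_perm, 0.05)
  expect_true(all(strsplit(hot$leading_edge, ",")[[1]] %in% sets$hot))
})
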