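psi_fixture <- function(reads_x, reads_y) {
  # 2-exon cluster with per-member bridging reads set directly
  cl <- toy_cluster2()
  sj <- toy_sj(c(300L, 600L, reads_x), c(100L, 400L, reads_y))
  compute_psi(cl, sj, "s1")
}

test_that("PSI divides member junction reads by the cluster total", {
  expect_equal(unname(psi_fixture(6L, 2L)), c(0.75, 0.25))
  expect_equal(unname(psi_fixture(0L, 0L)), c(NA_real_, NA_real_))
  # three members: reads (5, 5, 10) normalise to (0.25, 0.25, 0.5)
  g <- toy_gene(exons = list(A = c(0L, 100L), X = c(200L, 299L),
                             Y = c(400L, 499L), Z = c(600L, 699L),
                             B = c(800L, 900L)),
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B"),
                                   c("A", "Z", "B")))
  cl <- extract_annotated_mxe_candidates(g)[[1]]
  sj <- toy_sj(c(299L, 800L, 5L),                     # X down bridge
               c(100L, 400L, 3L), c(499L, 800L, 2L),  # Y both sides
               c(100L, 600L, 10L))                    # Z up bridge
  psi <- compute_psi(cl, sj, "s1")
  expect_equal(unname(psi), c(0.25, 0.25, 0.5))
  expect_equal(sum(psi), 1)
})

test_that("cluster-wise PSI normalisation holds on a generated cohort", {
  co <- acceptance_cohort()
  genes <- read_annotation(co$paths$gtf)
  clusters <- unlist(lapply(genes, extract_annotated_mxe_candidates),
                     recursive = FALSE)[1:8]
  sj <- read_sj_tables(co$paths$sj_dir)
  pm <- psi_matrix(clusters, sj)
  for (cl in clusters) {
    sub <- pm$psi[cl$member_exon_ids, , drop = FALSE]
    for (s in colnames(sub)) {
      v <- sub[, s]
      expect_true(all(is.na(v)) || abs(sum(v, na.rm = TRUE) - 1) < 1e-9)
    }
  }
})

test_that("RPKM arithmetic and the replicate median", {
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_equal(median(compute_rpkm(c(2, 4, 9), 1000, 1e6)), 4)
  expect_error(compute_rpkm(10, 0, 1e6), "length")
})

test_that("Kruskal-Wallis statistic matches the closed form and kruskal.test", {
  # identical PSI across conditions: statistic 0, p 1
  kw0 <- mxscape:::kw_test(rep(0.5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  # complete separation, n = 3 + 3, with within-group ties
  v <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1)
  g <- rep(c("a", "b"), each = 3)
  kw <- mxscape:::kw_test(v, g)
  expect_equal(kw$statistic, 5)        # hand-ranked, tie-corrected
  ref <- kruskal.test(v, factor(g))
  expect_equal(kw$statistic, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
  # general agreement with the stats oracle, including ties
  set.seed(8)
  for (i in 1:20) {
    x <- round(runif(12), 1)
    grp <- sample(c("a", "b", "c"), 12, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(x)) == 1) next
    ours <- mxscape:::kw_test(x, grp)
    ref <- kruskal.test(x, factor(grp))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("Benjamini-Hochberg step-up matches p.adjust", {
  expect_equal(mxscape:::bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(mxscape:::bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("differential inclusion tests exons and excludes the untestable", {
  psi <- matrix(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1,      # switch exon
                  0.5, 0.5, 0.5, 0.5, 0.5, 0.5,      # flat exon
                  0.4, NA, NA, 0.6, NA, NA),         # too few replicates
                nrow = 3, byrow = TRUE,
                dimnames = list(c("e1", "e2", "e3"), paste0("s", 1:6)))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("a", "b"), each = 3))
  res <- differential_inclusion(psi, design)
  expect_equal(res$tested, c(TRUE, TRUE, FALSE))
  expect_true(is.na(res$padj[3]))
  expect_equal(res$statistic[2], 0)
  expect_equal(res$p[2], 1)
  # BH family = tested exons only (m = 2)
  expect_equal(res$padj[1], min(res$p[1] * 2, 1))
  expect_error(differential_inclusion(psi, design[-1, ]), "missing samples")
})

test_that("Gini index matches its closed forms and the pairwise oracle", {
  expect_equal(gini(c(2, 2, 2, 2)), 0)
  for (n in c(2, 5, 10))
    expect_equal(gini(c(rep(0, n - 1), 1)), (n - 1) / n)
  expect_equal(gini(c(1, 2, 3, 4)), oracle_gini_pairwise(c(1, 2, 3, 4)))
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)
  set.seed(10)
  for (i in 1:20) {
    x <- rgamma(sample(2:15, 1), shape = 1)
    expect_equal(gini(x), oracle_gini_pairwise(x))
    expect_equal(gini(13 * x), gini(x))     # scale invariance
  }
  expect_true(is.na(gini(c(0, 0, 0))))
  expect_error(gini(1), ">= 2")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("delta-PSI pairs Gini extremes and zeroes unexpressed conditions", {
  cl <- toy_cluster2()
  # two conditions x two replicates; X dominates in a, Y in b; nothing in c
  sj <- sj_index(do.call(rbind, lapply(list(
    list("a1", 8L, 2L), list("a2", 8L, 2L),
    list("b1", 2L, 8L), list("b2", 2L, 8L),
    list("c1", 0L, 0L), list("c2", 0L, 0L)), function(x) {
      data.frame(chrom = "chr1", start = c(300L, 100L),
                 end = c(600L, 400L), strand = "+", sample_id = x[[1]],
                 unique_reads = c(x[[2]], x[[3]]))
    })))
  sj <- sj_index(sj[sj$unique_reads > 0, ])
  design <- data.frame(sample = c("a1", "a2", "b1", "b2", "c1", "c2"),
                       condition = rep(c("a", "b", "c"), each = 2))
  pm <- psi_matrix(list(cl), sj, samples = design$sample)
  dp <- delta_psi(cl, pm, design)
  expect_s3_class(dp, "delta_psi")
  expect_true(all(abs(dp$value) <= 1))
  expect_equal(dp$value[dp$condition == "c"], 0)  # unexpressed -> 0
  # the two expressed conditions are antisymmetric for a 2-exon cluster
  expect_equal(dp$value[dp$condition == "a"],
               -dp$value[dp$condition == "b"])
  expect_equal(abs(dp$value[dp$condition == "a"]), 0.6)
})

test_that("delta-PSI pairing rules can be inapplicable", {
  cl <- toy_cluster2()
  sj <- toy_sj(c(300L, 600L, 5L), c(100L, 400L, 5L))
  design <- data.frame(sample = "s1", condition = "a")
  pm <- psi_matrix(list(cl), sj, samples = "s1")
  # all members annotated: known-vs-novel has no novel member
  expect_null(delta_psi(cl, pm, design, pairing_rule = "known_vs_novel"))
  expect_null(delta_psi(cl, pm, design, pairing_rule = "snp_vs_nonsnp",
                        snp_members = character(0)))
  dp <- delta_psi(cl, pm, design, pairing_rule = "snp_vs_nonsnp",
                  snp_members = cl$member_exon_ids[1])
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$value, 0)    # PSI (0.5, 0.5)
})

test_that("expression gates follow the pair and Gini rules", {
  rpkm <- matrix(c(5, 6, 7, 0.1, 0.2, 0.1), nrow = 2, byrow = TRUE)
  expect_true(passes_expression_gate(rpkm, 3, "median_any_member"))
  expect_false(passes_expression_gate(rpkm, 10, "median_any_member"))
  rpkm2 <- matrix(c(12, 0, 0, 0, 11, 0), nrow = 2, byrow = TRUE)
  expect_true(passes_expression_gate(rpkm2, 10, "two_members_any_sample"))
  rpkm3 <- matrix(c(12, 0, 0, 0, 2, 0), nrow = 2, byrow = TRUE)
  expect_false(passes_expression_gate(rpkm3, 10, "two_members_any_sample"))
})
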