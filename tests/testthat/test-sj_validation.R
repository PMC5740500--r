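test_that("STAR SJ rows convert to half-open introns, unique reads only", {
  f <- tempfile()
  writeLines("chr1\t101\t200\t1\t1\t0\t7\t3\t40", f)
  sj <- read_sj_table(f, "s1")
  expect_equal(nrow(sj), 1L)
  expect_equal(sj$start, 100L)
  expect_equal(sj$end, 200L)
  expect_equal(sj$strand, "+")
  expect_equal(sj$unique_reads, 7L)   # multi-mapped column ignored
})

test_that("undetermined strand junctions match genes on either strand", {
  f <- tempfile()
  writeLines(c("chr1\t101\t200\t0\t0\t0\t5\t0\t40",
               "chr1\t301\t400\t2\t0\t0\t4\t0\t40"), f)
  sj <- read_sj_table(f, "s1")
  expect_equal(sj$strand, c("*", "-"))
  pooled <- sj_pool(sj)
  plus <- mxscape:::sj_for_cluster(pooled, "chr1", "+")
  minus <- mxscape:::sj_for_cluster(pooled, "chr1", "-")
  expect_equal(plus$start, 100L)                 # "*" matches + genes
  expect_equal(sort(minus$start), c(100L, 300L)) # and - genes
})

test_that("empty and malformed SJ files are handled", {
  f <- tempfile(); file.create(f)
  expect_equal(nrow(read_sj_table(f, "s1")), 0L)
  writeLines(c("chr1\t101\t200\t1\t1\t0\t7\t3\t40",
               "chr1\t301\t400\t1\t1"), f)
  expect_error(read_sj_table(f, "s1"), "line 2")
  writeLines("chr1\t101\tXX\t1\t1\t0\t7\t3\t40", f)
  expect_error(read_sj_table(f, "s1"), "line 1")
})

test_that("SJ write/read round-trips through the STAR dialect", {
  sj <- toy_sj(c(100L, 200L, 7L), c(300L, 410L, 2L))
  f <- tempfile()
  write_sj_table(sj, f, "s1")
  back <- read_sj_table(f, "s1")
  expect_equal(as.data.frame(back), as.data.frame(sj))
})

test_that("sub-cluster fractionation lists all contiguous runs", {
  subs4 <- enumerate_subclusters(4)
  expect_equal(subs4, list(1:2, 2:3, 3:4, 1:3, 2:4, 1:4))
  expect_equal(enumerate_subclusters(2), list(1:2))
  expect_length(enumerate_subclusters(6), 15L)        # n(n-1)/2
  for (n in 2:8)
    expect_length(enumerate_subclusters(n), n * (n - 1) / 2)
  expect_error(enumerate_subclusters(1), ">= 2")
})

test_that("constraint counts match the closed form and the enumeration", {
  expect_equal(constraint_count(2), 3L)
  expect_equal(constraint_count(3), 7L)
  expect_equal(constraint_count(5), 18L)
  expect_equal(constraint_count(2, strict = TRUE), 5L)
  expect_equal(constraint_count(10), 63L)
  expect_error(constraint_count(1), ">= 2")
  for (n in 2:10) {
    for (strict in c(FALSE, TRUE)) {
      tab <- enumerate_constraints(n, strict)
      expect_equal(nrow(tab), constraint_count(n, strict))
      expect_equal(nrow(unique(tab)), nrow(tab))   # all distinct
      # independent hand count: pairs + per-member bridge sides (+ flanks)
      pairs <- 0L
      for (i in 1:(n - 1)) for (j in (i + 1):n) pairs <- pairs + 1L
      bridges <- 0L
      for (i in 1:n) {
        if (i > 1L) bridges <- bridges + 1L     # upstream bridge
        if (i < n) bridges <- bridges + 1L      # downstream bridge
      }
      expect_equal(nrow(tab), pairs + bridges + if (strict) 2L else 0L)
    }
  }
})

test_that("a bridged, join-free 2-exon cluster validates at 3SJ", {
  cl <- toy_cluster2()       # X [200,300), Y [400,500), flanks A/B
  sj <- toy_sj(c(100L, 200L, 5L),   # A -> X (adjacent)
               c(300L, 600L, 4L),   # X -> B  (bridges Y)
               c(100L, 400L, 6L),   # A -> Y  (bridges X)
               c(500L, 600L, 5L))   # Y -> B (adjacent)
  v <- classify_cluster(cl, sj, min_reads = 3L)
  expect_equal(v$status, "validated")
  expect_equal(v$support_level, "3SJ")
  expect_equal(v$chosen_subcluster, cl$member_exon_ids)
  expect_equal(nrow(v$constraints), constraint_count(2))
  expect_equal(nrow(v$tolerated_joins), 0L)
})

test_that("a joining read rejects frame-compatible members", {
  cl <- toy_cluster2(99L, 99L)      # lengths divisible by three
  sj <- toy_sj(c(299L, 600L, 4L), c(100L, 400L, 6L),
               c(299L, 400L, 1L))   # X -> Y joining read
  v <- classify_cluster(cl, sj, min_reads = 3L)
  expect_equal(v$status, "rejected")
  expect_equal(v$support_level, "none")
})

test_that("joining reads are tolerated when joint inclusion frame-shifts", {
  cl <- toy_cluster2(100L, 100L)    # lengths = 1 mod 3
  sj <- toy_sj(c(300L, 600L, 4L), c(100L, 400L, 6L),
               c(300L, 400L, 2L))   # X -> Y joining read, tolerated
  v <- classify_cluster(cl, sj, min_reads = 3L)
  expect_equal(v$status, "validated")
  expect_equal(nrow(v$tolerated_joins), 1L)
  expect_equal(v$tolerated_joins$reads, 2L)
  # under the pair-sum rule 100+100 = 200 is not divisible by 3 either
  v2 <- classify_cluster(cl, sj, min_reads = 3L, frame_rule = "pair_sum")
  expect_equal(v2$status, "validated")
})

test_that("missing bridging evidence without joins is unresolved", {
  cl <- toy_cluster2()
  sj <- toy_sj(c(300L, 600L, 4L))   # only X's bridge; nothing for Y
  v <- classify_cluster(cl, sj, min_reads = 3L)
  expect_equal(v$status, "unresolved")
  expect_equal(v$support_level, "none")
})

test_that("support levels nest: 3SJ-validated implies 1SJ-validated", {
  cl <- toy_cluster2()
  sj <- toy_sj(c(300L, 600L, 2L), c(100L, 400L, 1L))
  expect_equal(classify_cluster(cl, sj, min_reads = 1L)$status, "validated")
  expect_equal(classify_cluster(cl, sj, min_reads = 3L)$status, "unresolved")
})

test_that("strict mode demands flank-adjacent junctions and pinned bridges", {
  cl <- toy_cluster2()
  base <- list(c(300L, 600L, 4L), c(100L, 400L, 6L))
  # without the adjacent junctions A->X and Y->B strict fails
  v <- classify_cluster(cl, do.call(toy_sj, base), min_reads = 3L,
                        strict = TRUE)
  expect_equal(v$status, "unresolved")
  v2 <- classify_cluster(cl, do.call(toy_sj, c(base, list(
    c(100L, 200L, 3L), c(500L, 600L, 3L)))), min_reads = 3L, strict = TRUE)
  expect_equal(v2$status, "validated")
  expect_equal(nrow(v2$constraints), constraint_count(2, strict = TRUE))
  # a bridge landing past the adjacent flank does not count in strict mode
  far <- list(c(300L, 900L, 4L), c(100L, 400L, 6L),
              c(100L, 200L, 3L), c(500L, 600L, 3L))
  v3 <- classify_cluster(cl, do.call(toy_sj, far), min_reads = 3L,
                         strict = TRUE)
  expect_equal(v3$status, "unresolved")
  # ...but does in default mode ("alternative flank" allowance)
  v4 <- classify_cluster(cl, do.call(toy_sj, far), min_reads = 3L)
  expect_equal(v4$status, "validated")
})

test_that("the largest valid sub-cluster is chosen, with read tie-breaks", {
  # 3-member cluster where member 3 lacks bridging: [1,2] should win
  g <- toy_gene(exons = list(A = c(0L, 100L), X = c(200L, 299L),
                             Y = c(400L, 499L), Z = c(600L, 699L),
                             B = c(800L, 900L)),
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B"),
                                   c("A", "Z", "B")))
  cl <- extract_annotated_mxe_candidates(g)[[1]]
  sj <- toy_sj(c(299L, 800L, 5L),   # X bridges Y and Z
               c(100L, 400L, 5L),   # Y bridged over X
               c(499L, 800L, 5L))   # Y bridges Z
  v <- classify_cluster(cl, sj, min_reads = 3L)
  expect_equal(v$status, "validated")
  expect_equal(v$chosen_subcluster,
               c("g1:chr1:200-299", "g1:chr1:400-499"))
})

test_that("adding reads is monotone in the expected directions", {
  cl <- toy_cluster2(99L, 99L)
  bridges <- list(c(299L, 600L, 4L), c(100L, 400L, 6L))
  v0 <- classify_cluster(cl, do.call(toy_sj, bridges), min_reads = 3L)
  expect_equal(v0$status, "validated")
  # more bridging reads never flip validated -> rejected
  more <- classify_cluster(cl, do.call(toy_sj, list(
    c(299L, 600L, 400L), c(100L, 400L, 600L))), min_reads = 3L)
  expect_equal(more$status, "validated")
  # one non-tolerated joining read always flips validated -> rejected
  joined <- classify_cluster(cl, do.call(toy_sj, c(bridges, list(
    c(299L, 400L, 1L)))), min_reads = 3L)
  expect_equal(joined$status, "rejected")
})

test_that("every cluster gets exactly one status and tallies partition", {
  co <- acceptance_cohort()
  genes <- read_annotation(co$paths$gtf)
  clusters <- unlist(lapply(genes, extract_annotated_mxe_candidates),
                     recursive = FALSE)
  sj <- read_sj_tables(co$paths$sj_dir)
  for (mr in c(1L, 3L)) {
    tab <- classify_clusters(clusters, sj, min_reads = mr)$table
    expect_true(all(tab$status %in% c("validated", "rejected",
                                      "unresolved")))
    expect_equal(sum(tab$status == "validated") +
                   sum(tab$status == "rejected") +
                   sum(tab$status == "unresolved"), length(clusters))
  }
})
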