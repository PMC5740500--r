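# fixed 10-aa search exon used throughout: last codon GTT so that the
# shifted-window construction below ends in a GT donor
PEP10 <- "MKVLDEIRTV"
E10 <- paste0("ATG", "AAA", "GTT", "CTT", "GAT", "GAA", "ATT", "CGT",
              "ACT", "GTT")
TPAD <- strrep("T", 40)

test_that("self-alignment score equals the BLOSUM62 diagonal sum", {
  b62 <- mxscape:::blosum62()
  for (p in c("MKV", PEP10, "WWCC")) {
    aa <- strsplit(p, "")[[1]]
    expect_equal(similarity_score(p, p), sum(diag(b62[aa, aa, drop = FALSE])))
  }
  expect_equal(similarity_score("MKV", "MKV"), 14)   # M5 + K5 + V4
})

test_that("similarity score is symmetric and rejects non-amino-acids", {
  expect_equal(similarity_score("MKVLDE", "MKIWDE"),
               similarity_score("MKIWDE", "MKVLDE"))
  expect_equal(similarity_score(PEP10, "WWCCHHRRKK"),
               similarity_score("WWCCHHRRKK", PEP10))
  expect_error(similarity_score("MKB!", "MKV"), "non-amino-acid")
  expect_error(similarity_score("", "MKV"), "empty")
})

test_that("an exact planted copy is recovered with the maximal score", {
  intron <- paste0(TPAD, "AG", E10, "GT", TPAD)
  hits <- scan_intron(E10, intron, frame = 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, nchar(TPAD) + 2L)
  expect_equal(hits$end, nchar(TPAD) + 2L + 30L)
  expect_equal(hits$splice_class, "GT-AG")
  expect_equal(hits$peptide, PEP10)
  expect_equal(hits$similarity_score, similarity_score(PEP10, PEP10))
  expect_equal(hits$length_delta_nt, 0L)
})

test_that("an in-frame stop codon disqualifies the window", {
  bad <- paste0(substr(E10, 1, 6), "TAA", substr(E10, 10, 30))
  intron <- paste0(TPAD, "AG", bad, "GT", TPAD)
  expect_equal(nrow(scan_intron(E10, intron, frame = 0L)), 0L)
})

test_that("GT-AG beats an overlapping higher-scoring GC-AG candidate", {
  # window A = exact copy with GC donor; window B = A shifted left by one
  # codon (prefixed CAG, truncated tail) with GT donor; B scores lower but
  # wins on splice-class preference
  intron <- paste0(TPAD, "AG", "CAG", E10, "GC", TPAD)
  # low threshold so both overlapping windows pass and preference decides
  hits <- scan_intron(E10, intron, frame = 0L,
                      params = prediction_params(min_score = 10))
  in_region <- hits$start < nchar(TPAD) + 5L + 30L &
    hits$end > nchar(TPAD) + 5L
  expect_equal(sum(in_region), 1L)
  win <- hits[in_region, ]
  expect_equal(win$splice_class, "GT-AG")
  expect_equal(win$start, nchar(TPAD) + 2L)          # the shifted window
  expect_equal(substr(win$peptide, 1, 1), "Q")
  expect_lt(win$similarity_score, similarity_score(PEP10, PEP10))
})

test_that("intron shorter than the minimum window yields no candidates", {
  expect_equal(nrow(scan_intron(E10, "AGTTTTGT", frame = 0L)), 0L)
})

test_that("scan_intron matches the exhaustive window oracle", {
  set.seed(11)
  for (rep in 1:3) {
    pep <- mxscape:::random_peptide(15L)
    exon <- mxscape:::encode_peptide(pep)
    mut <- mxscape:::encode_peptide(mxscape:::mutate_peptide(pep, 0.2))
    intron <- paste0(mxscape:::random_dna(300L), "AG", mut, "GT",
                     mxscape:::random_dna(250L))
    got <- scan_intron(exon, intron, frame = 0L)
    want <- oracle_scan_intron(exon, intron, frame = 0L)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # planted <= 20% diverged copy flanked GT..AG is always recovered
    expect_true(any(got$start == 302L & got$end == 302L + 45L))
    # frame rule: every candidate preserves the search exon's frame
    expect_true(all(got$length_delta_nt %% 3L == 0L))
    expect_true(all(abs(got$length_delta_nt) <= 60L))
  }
})

test_that("predicted candidates merge into positionally ordered clusters", {
  co <- generate_cohort(simulation_config(
    seed = 5L, n_genes = 2L, class_sequence = c("mxe_novel", "mxe"),
    cluster_sizes = c(1L, 2L), variant_rate = 0), tempfile())
  genes <- read_annotation(co$paths$gtf, co$paths$genome)
  genome <- read_genome(co$paths$genome)
  g <- genes$G001
  pred <- predict_mxe_candidates(g, genome)
  expect_gte(nrow(pred), 1L)
  # no predicted candidate overlaps an annotated exon
  for (k in seq_len(nrow(pred)))
    expect_false(any(pred$start[k] < g$exons$end &
                       pred$end[k] > g$exons$start))
  cl <- build_candidate_clusters(g, extract_annotated_mxe_candidates(g),
                                 pred)
  expect_length(cl, 1L)
  m <- cl[[1]]$members
  expect_true(all(diff(m$start) > 0))          # ordered by position
  expect_true("predicted" %in% m$source && "annotated" %in% m$source)
  # planted copy is among the members (truth lists annotated + novel)
  truth_iv <- strsplit(co$truth$clusters$members[1], ",")[[1]]
  got_iv <- sprintf("%s:%d-%d", m$chrom, m$start, m$end)
  expect_true(all(truth_iv %in% got_iv))
})

test_that("candidates overlapping annotated terminal exons are dropped", {
  g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                             B = c(600L, 690L)),
                transcripts = list(c("A", "X", "B")))
  pred <- data.frame(search_exon_id = "g1:chr1:200-290", chrom = "chr1",
                     start = c(320L, 650L), end = c(410L, 740L),
                     strand = "+", splice_class_site = "GT-AG",
                     peptide = "X", similarity_score = 50,
                     length_nt = 90L, length_delta_nt = 0L, phase_in = 0L,
                     stringsAsFactors = FALSE)
  cl <- build_candidate_clusters(g, list(), pred)
  expect_length(cl, 1L)
  # only the intronic candidate survives; the one on terminal exon B is gone
  expect_equal(nrow(cl[[1]]$members), 2L)
  expect_true(all(cl[[1]]$members$start %in% c(200L, 320L)))
})
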