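test_that("GTF coordinates convert to 0-based half-open intervals", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tannotated\texon\t101\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), gtf)
  genes <- read_annotation(gtf)
  ex <- genes$g1$exons
  expect_equal(ex$start, 100L)
  expect_equal(ex$end, 200L)
  expect_equal(ex$length_nt, 100L)
})

test_that("a two-transcript toy gene round-trips through GTF I/O", {
  g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                             Y = c(400L, 490L), B = c(600L, 690L)),
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B")))
  path1 <- tempfile(fileext = ".gtf")
  write_annotation(list(g), path1)
  back <- read_annotation(path1)
  expect_length(back, 1L)
  expect_length(back$g1$transcripts, 2L)
  expect_equal(nrow(back$g1$exons), 4L)
  # write(read(f)) is byte-identical to f
  path2 <- tempfile(fileext = ".gtf")
  write_annotation(back, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("phases track cumulative coding length, on both strands", {
  gtf_f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tannotated\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tannotated\texon\t201\t350\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tannotated\texon\t501\t600\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), gtf_f)
  g <- read_annotation(gtf_f)$g1
  expect_equal(unname(g$exons$phase_in), c(0L, 100L %% 3L,
                                           (100L + 150L) %% 3L))
  # reverse strand: transcription runs right to left
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tannotated\texon\t1\t100\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t1";'),
    paste0("chr1\tannotated\texon\t201\t350\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t1";'),
    paste0("chr1\tannotated\texon\t501\t600\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t1";')), gtf)
  g2 <- read_annotation(gtf)$g2
  ex <- g2$exons[order(g2$exons$start), ]
  # first transcribed exon is the rightmost one
  expect_equal(ex$phase_in[ex$start == 500L], 0L)
  expect_equal(ex$phase_in[ex$start == 200L], 100L %% 3L)
  expect_equal(ex$phase_in[ex$start == 0L], 250L %% 3L)
  expect_equal(g2$transcripts[[1]][1], ex$exon_id[ex$start == 500L])
})

test_that("transcripts with overlapping exons are skipped with a warning", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tannotated\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g"; transcript_id "bad";'),
    paste0("chr1\tannotated\texon\t50\t150\t.\t+\t.\t",
           'gene_id "g"; transcript_id "bad";'),
    paste0("chr1\tannotated\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g"; transcript_id "ok";')), gtf)
  expect_warning(genes <- read_annotation(gtf), "overlapping")
  expect_equal(names(genes$g$transcripts), "ok")
})

test_that("exons outside chromosome bounds are a hard error", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("A", 50)), fa)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tannotated\texon\t10\t120\t.\t+\t.\t",
                    'gene_id "g"; transcript_id "t";'), gtf)
  expect_error(read_annotation(gtf, fa), "bounds")
})

test_that("mutually exclusive internal neighbours form one cluster", {
  g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                             Y = c(400L, 490L), B = c(600L, 690L)),
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B")))
  cl <- extract_annotated_mxe_candidates(g)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$member_exon_ids,
               c("g1:chr1:200-290", "g1:chr1:400-490"))
  expect_equal(cl[[1]]$upstream_boundary, 90L)
  expect_equal(cl[[1]]$downstream_boundary, 600L)
  expect_length(attr(cl, "terminal_candidates"), 0L)
})

test_that("terminal mutually exclusive exons go to the side list", {
  g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                             Y = c(400L, 490L)),
                transcripts = list(c("A", "X"), c("A", "Y")))
  cl <- extract_annotated_mxe_candidates(g)
  expect_length(cl, 0L)
  side <- attr(cl, "terminal_candidates")
  expect_length(side, 1L)
  expect_equal(side[[1]], c("g1:chr1:200-290", "g1:chr1:400-490"))
})

test_that("co-occurrence in any transcript disqualifies the pair", {
  g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                             Y = c(400L, 490L), B = c(600L, 690L)),
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B"),
                                   c("A", "X", "Y", "B")))
  expect_length(extract_annotated_mxe_candidates(g), 0L)
})

test_that("extraction matches brute force over all membership patterns", {
  # two internal exons X, Y; three transcripts, each containing flanks A, B;
  # enumerate all 2^6 membership patterns of X/Y in the three transcripts
  for (code in 0:63) {
    bits <- as.logical(bitwAnd(code, 2^(0:5)))
    mem <- matrix(bits, nrow = 2)        # rows X,Y; cols transcripts 1..3
    txs <- lapply(1:3, function(t) {
      v <- c("A", if (mem[1, t]) "X", if (mem[2, t]) "Y", "B")
      v
    })
    txs <- unique(txs)
    g <- toy_gene(exons = list(A = c(0L, 90L), X = c(200L, 290L),
                               Y = c(400L, 490L), B = c(600L, 690L)),
                  transcripts = txs)
    cl <- extract_annotated_mxe_candidates(g)
    # oracle: emitted iff each member present somewhere, absent somewhere
    # (over unique transcripts), and never co-present
    in_x <- vapply(txs, function(t) "X" %in% t, logical(1))
    in_y <- vapply(txs, function(t) "Y" %in% t, logical(1))
    expected <- any(in_x) && any(in_y) && any(!in_x) && any(!in_y) &&
      !any(in_x & in_y)
    expect_equal(length(cl) == 1L, expected, info = paste("code", code))
    if (expected)
      expect_equal(length(cl[[1]]$member_exon_ids), 2L)
  }
})

test_that("cluster invariants hold on generated cohorts", {
  co <- acceptance_cohort()
  genes <- read_annotation(co$paths$gtf)
  for (g in genes) {
    cls <- extract_annotated_mxe_candidates(g)
    for (cl in cls) {
      # members internal in some transcript
      for (e in cl$member_exon_ids) {
        internal <- any(vapply(g$transcripts, function(t) {
          i <- match(e, t); !is.na(i) && i > 1L && i < length(t)
        }, logical(1)))
        expect_true(internal)
      }
      # no transcript holds two members
      for (t in g$transcripts)
        expect_lte(sum(cl$member_exon_ids %in% t), 1L)
      # members non-overlapping and ordered
      m <- cl$members
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    }
  }
})
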