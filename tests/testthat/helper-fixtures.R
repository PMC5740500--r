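# Fixture builders: tiny gene models and SJ tables constructed in code, and
# a lazily cached worked cohort shared across test files.

# gene model from a compact spec: exons = named list of c(start, end),
# transcripts = list of exon-name vectors (transcription order)
toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     exons, transcripts) {
  ids <- setNames(sprintf("%s:%s:%d-%d", gene_id, chrom,
                          vapply(exons, `[`, 0, 1),
                          vapply(exons, `[`, 0, 2)), names(exons))
  ex <- data.frame(
    exon_id = unname(ids), chrom = chrom,
    start = vapply(exons, `[`, 0, 1), end = vapply(exons, `[`, 0, 2),
    strand = strand, stringsAsFactors = FALSE)
  ex$length_nt <- ex$end - ex$start
  ex$phase_in <- 0L
  ex$source <- "annotated"
  ex$gene_id <- gene_id
  txl <- lapply(transcripts, function(v) unname(ids[v]))
  names(txl) <- paste0(gene_id, ".t", seq_along(txl))
  ex$splice_class <- mxscape:::classify_exon_roles(ex$exon_id, txl)
  ex <- ex[order(ex$start), ]
  rownames(ex) <- NULL
  gene_model(gene_id, chrom, strand, ex, txl)
}

# sj table from triples: list(c(start, end, reads), ...) on one sample
toy_sj <- function(..., chrom = "chr1", strand = "+", sample_id = "s1") {
  rows <- list(...)
  if (length(rows) == 0L) return(sj_index())
  sj_index(do.call(rbind, lapply(rows, function(r) data.frame(
    chrom = chrom, start = r[1], end = r[2], strand = strand,
    sample_id = sample_id, unique_reads = r[3], stringsAsFactors = FALSE))))
}

# canonical 2-exon test cluster: flank A [0,100), members X [200,300) and
# Y [400,500), flank B [600,700); member lengths adjustable
toy_cluster2 <- function(len_x = 100L, len_y = 100L) {
  exons <- list(A = c(0L, 100L), X = c(200L, 200L + len_x),
                Y = c(400L, 400L + len_y), B = c(600L, 700L))
  g <- toy_gene(exons = exons,
                transcripts = list(c("A", "X", "B"), c("A", "Y", "B")))
  extract_annotated_mxe_candidates(g)[[1]]
}

worked_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_worked_fixture(file.path(tempdir(), "mx_worked"))
    cache
  }
})

acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 20240915L, n_genes = 100L)
      cache <<- generate_cohort(cfg, file.path(tempdir(), "mx_acc"))
    }
    cache
  }
})
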