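## Gene models: GTF I/O with reading-frame bookkeeping, and extraction of
## annotated mutually-exclusive exon candidates from transcript structures.

exon_id_of <- function(gene_id, chrom, start, end) {
  sprintf("%s:%s:%d-%d", gene_id, chrom, start, end)
}

#' Construct a gene model
#'
#' A gene model holds the unique coding exons of one gene (0-based half-open
#' genomic coordinates) together with its transcripts as ordered exon-id
#' vectors in transcription order (reverse-strand transcripts run from high
#' to low genomic coordinate).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns exon_id, chrom, start, end, strand,
#'   length_nt, phase_in, source, splice_class.
#' @param transcripts named list of exon-id character vectors in
#'   transcription order.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, transcripts) {
  stopifnot(all(exons$end > exons$start),
            all(exons$length_nt == exons$end - exons$start))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exons, %d transcripts\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              length(x$transcripts)))
  invisible(x)
}

## phase at exon start = cumulative coding length of preceding exons mod 3
transcript_phases <- function(lengths) {
  c(0L, cumsum(lengths)[-length(lengths)] %% 3L)
}

#' Read a genome FASTA
#'
#' @param fasta_path path to a (possibly multi-sequence) FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene models from a GTF annotation
#'
#' Imports exon records from a 1-based inclusive GTF, converts them to the
#' internal 0-based half-open convention, computes the codon phase at each
#' exon start per transcript, and groups exons into one [gene_model] per
#' gene. Transcripts whose exons overlap each other are skipped with a
#' warning; exons outside chromosome bounds (when a genome is supplied) are a
#' hard error.
#'
#' @param gtf_path path to a GTF file with gene_id/transcript_id attributes.
#' @param fasta_path optional genome FASTA used to check exon bounds.
#' @return named list of [gene_model] objects, in order of first appearance.
#' @export
read_annotation <- function(gtf_path, fasta_path = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    gtf_source = as.character(gr$source),
    stringsAsFactors = FALSE)
  if (!is.null(fasta_path)) {
    genome <- read_genome(fasta_path)
    bad <- df$start < 0L | df$end > S4Vectors::width(genome)[
      match(df$chrom, names(genome))]
    if (any(is.na(bad)) || any(bad))
      stop("exon outside chromosome bounds in ", gtf_path)
  }
  genes <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    strand <- sub$strand[1]
    chrom <- sub$chrom[1]
    sub$exon_id <- exon_id_of(g, sub$chrom, sub$start, sub$end)
    transcripts <- list()
    phase_by_exon <- character(0)
    phases <- list()
    for (tx in unique(sub$transcript_id)) {
      te <- sub[sub$transcript_id == tx, , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]
      if (nrow(te) > 1L && any(te$start[-1] < te$end[-nrow(te)])) {
        warning(sprintf("transcript %s of gene %s has overlapping exons; skipped",
                        tx, g))
        next
      }
      ord <- if (strand == "-") rev(seq_len(nrow(te))) else seq_len(nrow(te))
      te <- te[ord, , drop = FALSE]               # transcription order
      transcripts[[tx]] <- te$exon_id
      ph <- transcript_phases(te$end - te$start)
      new <- !(te$exon_id %in% names(phases))
      phases[te$exon_id[new]] <- ph[new]
    }
    if (length(transcripts) == 0L) next
    ex <- unique(sub[, c("exon_id", "chrom", "start", "end", "strand",
                         "gtf_source")])
    ex <- ex[order(ex$start, ex$end), , drop = FALSE]
    ex$length_nt <- ex$end - ex$start
    ex$phase_in <- as.integer(unlist(phases[ex$exon_id]))
    ex$source <- ifelse(ex$gtf_source == "predicted", "predicted", "annotated")
    ex$gtf_source <- NULL
    ex$gene_id <- g
    ex$splice_class <- classify_exon_roles(ex$exon_id, transcripts)
    rownames(ex) <- NULL
    genes[[g]] <- gene_model(g, chrom, strand, ex, transcripts)
  }
  genes
}

## constitutive (all transcripts) / terminal (never internal) /
## other_alternative; refined to mxe_annotated by candidate extraction.
classify_exon_roles <- function(exon_ids, transcripts) {
  n_tx <- length(transcripts)
  in_n <- vapply(exon_ids, function(e)
    sum(vapply(transcripts, function(t) e %in% t, logical(1))), integer(1))
  internal_any <- vapply(exon_ids, function(e) {
    any(vapply(transcripts, function(t) {
      i <- match(e, t)
      !is.na(i) && i > 1L && i < length(t)
    }, logical(1)))
  }, logical(1))
  out <- rep("other_alternative", length(exon_ids))
  out[in_n == n_tx] <- "constitutive"
  out[!internal_any] <- "terminal"
  out
}

#' Write gene models to GTF
#'
#' Emits one canonical exon line per transcript exon (1-based inclusive
#' coordinates), grouped by gene and transcript in stored order, exons in
#' ascending genomic order. `read_annotation()` followed by
#' `write_annotation()` reproduces a file written by this function
#' byte-identically.
#'
#' @param genes list of [gene_model] objects.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_annotation <- function(genes, path) {
  lines <- character(0)
  for (gm in genes) {
    ex <- gm$exons
    for (tx in names(gm$transcripts)) {
      ids <- gm$transcripts[[tx]]
      te <- ex[match(ids, ex$exon_id), , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]    # genomic order on disk
      lines <- c(lines, sprintf(
        "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        te$chrom, te$source, te$start + 1L, te$end, te$strand,
        gm$gene_id, tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an MXE cluster
#'
#' An ordered run of neighbouring candidate exons within one gene, plus the
#' closest non-member flanking exon edges (end coordinate of the nearest
#' upstream exon, start coordinate of the nearest downstream exon; NA when
#' the cluster is gene-terminal).
#'
#' @param cluster_id identifier.
#' @param gene_id owning gene.
#' @param members exon data.frame (rows ordered by genomic position).
#' @param upstream_boundary,downstream_boundary flanking exon edges.
#' @param chrom,strand location of the cluster.
#' @return object of class `mxe_cluster`.
#' @export
mxe_cluster <- function(cluster_id, gene_id, members,
                        upstream_boundary = NA_integer_,
                        downstream_boundary = NA_integer_,
                        chrom = members$chrom[1], strand = members$strand[1]) {
  stopifnot(nrow(members) >= 2L)
  members <- members[order(members$start), , drop = FALSE]
  if (any(members$start[-1] < members$end[-nrow(members)]))
    stop("cluster members must be mutually non-overlapping")
  structure(list(cluster_id = cluster_id, gene_id = gene_id,
                 members = members,
                 member_exon_ids = members$exon_id,
                 upstream_boundary = upstream_boundary,
                 downstream_boundary = downstream_boundary,
                 chrom = chrom, strand = strand),
            class = "mxe_cluster")
}

#' @export
print.mxe_cluster <- function(x, ...) {
  cat(sprintf("mxe_cluster %s (%s, %d members): %s\n", x$cluster_id,
              x$gene_id, nrow(x$members),
              paste(x$member_exon_ids, collapse = ", ")))
  invisible(x)
}

## flanking boundaries of a member run among all gene exons
run_boundaries <- function(ex_all, members) {
  before <- ex_all$end[ex_all$end <= min(members$start) &
                         !(ex_all$exon_id %in% members$exon_id)]
  after <- ex_all$start[ex_all$start >= max(members$end) &
                          !(ex_all$exon_id %in% members$exon_id)]
  list(up = if (length(before)) max(before) else NA_integer_,
       down = if (length(after)) min(after) else NA_integer_)
}

#' Extract annotated MXE candidate clusters from a gene model
#'
#' Returns maximal runs of neighbouring internal exons such that every member
#' appears in at least one transcript, is absent from at least one
#' transcript, no transcript contains two members, and members do not
#' overlap. Runs whose exons are terminal in every transcript (alternative
#' promoter / polyadenylation candidates) are excluded from the result and
#' collected on the `"terminal_candidates"` attribute instead.
#'
#' @param gene a [gene_model] with at least two transcripts (a single
#'   transcript yields no candidates).
#' @return list of [mxe_cluster] (possibly empty) with attribute
#'   `terminal_candidates` (a list of exon-id vectors).
#' @export
extract_annotated_mxe_candidates <- function(gene) {
  ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
  n_tx <- length(gene$transcripts)
  terminal_side <- list()
  if (n_tx < 2L) {
    out <- list()
    attr(out, "terminal_candidates") <- terminal_side
    return(out)
  }
  in_tx <- sapply(gene$transcripts, function(t) ex$exon_id %in% t)
  in_tx <- matrix(in_tx, nrow = nrow(ex))
  present <- rowSums(in_tx) >= 1L
  absent_somewhere <- rowSums(in_tx) < n_tx
  internal <- vapply(ex$exon_id, function(e) {
    any(vapply(gene$transcripts, function(t) {
      i <- match(e, t)
      !is.na(i) && i > 1L && i < length(t)
    }, logical(1)))
  }, logical(1))
  candidate <- present & absent_somewhere

  runs_of <- function(keep) {
    runs <- list(); cur <- integer(0)
    for (i in seq_len(nrow(ex))) {
      if (!keep[i]) {                 # non-eligible exon between members
        if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
        cur <- integer(0)
        next
      }
      if (length(cur) && ex$start[i] < ex$end[cur[length(cur)]]) {
        # overlapping boundaries: distinct exons, never co-members
        if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
        cur <- i
      } else cur <- c(cur, i)
    }
    if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
    runs
  }

  ## a contiguous sub-run is admissible iff no transcript holds two members
  cooccur_free <- function(idx) {
    !any(colSums(in_tx[idx, , drop = FALSE]) >= 2L)
  }
  decompose <- function(idx) {
    picked <- list()
    taken <- rep(FALSE, length(idx))
    subs <- enumerate_subclusters(length(idx))
    for (s in rev(subs)) {           # largest first
      if (any(taken[s])) next
      if (cooccur_free(idx[s])) {
        picked[[length(picked) + 1L]] <- idx[s]
        taken[s] <- TRUE
      }
    }
    picked[order(vapply(picked, min, integer(1)))]
  }

  clusters <- list()
  for (run in runs_of(candidate & internal)) {
    for (idx in decompose(run)) {
      members <- ex[idx, , drop = FALSE]
      members$splice_class <- "mxe_annotated"
      b <- run_boundaries(ex, members)
      cid <- sprintf("%s.c%d", gene$gene_id, length(clusters) + 1L)
      clusters[[length(clusters) + 1L]] <-
        mxe_cluster(cid, gene$gene_id, members, b$up, b$down,
                    chrom = gene$chrom, strand = gene$strand)
    }
  }
  ## exons never internal but otherwise mutually exclusive: side list
  for (run in runs_of(candidate & !internal)) {
    for (idx in decompose(run))
      terminal_side[[length(terminal_side) + 1L]] <- ex$exon_id[idx]
  }
  attr(clusters, "terminal_candidates") <- terminal_side
  clusters
}

#' Tabulate clusters as a data.frame
#'
#' @param clusters list of [mxe_cluster].
#' @return one row per cluster: id, gene, size, span, member ids.
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      chrom = character(0), n_members = integer(0),
                      start = integer(0), end = integer(0),
                      members = character(0)))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, gene_id = cl$gene_id, chrom = cl$chrom,
    n_members = nrow(cl$members), start = min(cl$members$start),
    end = max(cl$members$end),
    members = paste(cl$member_exon_ids, collapse = ","),
    stringsAsFactors = FALSE)))
}
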