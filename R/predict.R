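## Tandem-exon-duplication search: predict frame-preserving, similarity-scored
## exon candidates inside the introns neighbouring each internal exon.

#' Prediction parameters
#'
#' @param min_exon_length_aa minimum candidate peptide length (default 10).
#' @param max_length_difference_aa maximum length difference between search
#'   exon and candidate, in amino acids (default 20, i.e. 60 nt in steps of
#'   three to preserve the reading frame).
#' @param min_score minimum amino-acid similarity score. The published
#'   pipeline used 10 on the (unpublished) scale of its internal scorer; on
#'   this package's BLOSUM62 global-alignment scale the default of 25 was
#'   calibrated on synthetic cohorts, where planted divergent copies score
#'   at least ~70 and the best chance window in ~10^5 enumerated windows
#'   scores 17.
#' @param splice_site_preference ordered donor/acceptor classes; earlier
#'   entries win among overlapping candidates.
#' @param gap_opening,gap_extension affine gap penalties for the global
#'   alignment used by [similarity_score()].
#' @return list of class `prediction_params`.
#' @export
prediction_params <- function(min_exon_length_aa = 10L,
                              max_length_difference_aa = 20L,
                              min_score = 25,
                              splice_site_preference = c("GT-AG", "GC-AG", "GG-AG"),
                              gap_opening = 10, gap_extension = 0.5) {
  stopifnot(min_exon_length_aa > 0, max_length_difference_aa > 0,
            min_score > 0)
  structure(list(min_exon_length_aa = as.integer(min_exon_length_aa),
                 max_length_difference_aa = as.integer(max_length_difference_aa),
                 min_score = min_score,
                 splice_site_preference = splice_site_preference,
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "prediction_params")
}

.mx_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.mx_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mx_cache$BLOSUM62 <- get("BLOSUM62", envir = e)
  }
  .mx_cache$BLOSUM62
}

AA_STANDARD20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Amino-acid similarity score
#'
#' Global (Needleman-Wunsch) alignment score under BLOSUM62 with affine
#' gaps. Symmetric; the self-score of a peptide is the sum of the matrix
#' diagonal over its residues.
#'
#' @param pep_a,pep_b non-empty peptide strings over the 20 standard amino
#'   acids.
#' @param gap_opening,gap_extension affine gap penalties (positive numbers).
#' @return numeric alignment score.
#' @export
similarity_score <- function(pep_a, pep_b, gap_opening = 10,
                             gap_extension = 0.5) {
  for (p in c(pep_a, pep_b)) {
    if (!nzchar(p)) stop("empty peptide")
    if (!all(strsplit(p, "")[[1]] %in% AA_STANDARD20))
      stop("non-amino-acid symbols in peptide: ", p)
  }
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep_a), Biostrings::AAString(pep_b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    scoreOnly = TRUE))
}

#' Translate DNA in a given codon phase
#'
#' @param dna nucleotide string (transcription orientation).
#' @param frame codon offset at the sequence start: `frame` bases at the
#'   start belong to the previous codon and are skipped, as is any trailing
#'   partial codon.
#' @return peptide string (may contain `*` for stops).
#' @export
translate_frame <- function(dna, frame = 0L) {
  skip <- (3L - (frame %% 3L)) %% 3L
  n_cod <- (nchar(dna) - skip) %/% 3L
  if (n_cod <= 0L) return("")
  cds <- substr(dna, skip + 1L, skip + 3L * n_cod)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Scan an intron for frame-preserving exon candidates
#'
#' Enumerates every window whose length differs from the search exon by a
#' multiple of three up to `max_length_difference_aa * 3` nucleotides, keeps
#' windows flanked by an AG acceptor immediately upstream and an allowed
#' donor dinucleotide (GT, GC or GG, in that order of preference) immediately
#' downstream, translates each window in the search exon's frame, discards
#' peptides with in-frame stop codons or shorter than `min_exon_length_aa`,
#' keeps candidates whose global-alignment similarity to the search-exon
#' peptide exceeds `min_score`, and among overlapping candidates keeps the
#' one with the most preferred splice-site class, then the highest score.
#'
#' @param search_seq nucleotide sequence of the search exon (transcription
#'   orientation).
#' @param intron_seq nucleotide sequence of one neighbouring intron,
#'   excluding the flanking exons (transcription orientation).
#' @param frame the search exon's codon phase (`phase_in`).
#' @param params a [prediction_params] object.
#' @return data.frame of candidates with 0-based half-open offsets within the
#'   intron (`start`, `end`), `splice_class`, `peptide`, `similarity_score`,
#'   `length_nt` and `length_delta_nt`; zero rows when the intron is too
#'   short or nothing qualifies.
#' @export
scan_intron <- function(search_seq, intron_seq, frame = 0L,
                        params = prediction_params()) {
  L <- nchar(search_seq)
  n <- nchar(intron_seq)
  allowed_donors <- sub("-AG$", "", params$splice_site_preference)
  deltas <- seq(-params$max_length_difference_aa * 3L,
                params$max_length_difference_aa * 3L, by = 3L)
  widths <- unique(L + deltas)
  widths <- widths[widths >= 3L * params$min_exon_length_aa - 2L & widths >= 3L]
  empty <- data.frame(start = integer(0), end = integer(0),
                      splice_class = character(0), peptide = character(0),
                      similarity_score = numeric(0), length_nt = integer(0),
                      length_delta_nt = integer(0))
  if (length(widths) == 0L || n < min(widths) + 4L) return(empty)
  search_pep <- translate_frame(search_seq, frame)

  ## positions of eligible acceptors (AG upstream) and donors, computed once
  chars <- strsplit(intron_seq, "")[[1]]
  di <- paste0(chars[-n], chars[-1])            # dinucleotide at i..i+1
  skip <- (3L - (frame %% 3L)) %% 3L
  rows <- list()
  for (w in widths) {
    if (n < w + 4L) next
    s <- 3:(n - w - 1L)             # 1-based window starts; room for AG / NN
    if (length(s) == 0L) next
    keep <- di[s - 2L] == "AG" & di[s + w] %in% allowed_donors
    if (!any(keep)) next
    s <- s[keep]
    n_cod <- (w - skip) %/% 3L
    if (n_cod < params$min_exon_length_aa) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, end = s - 1L + w,
      splice_class = paste0(di[s + w], "-AG"),
      length_nt = w, length_delta_nt = w - L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)
  ## translate every surviving window in one call, then filter stops/length
  cds <- substr(substring(intron_seq, cand$start + 1L, cand$end),
                skip + 1L, skip + 3L * ((cand$length_nt - skip) %/% 3L))
  cand$peptide <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), if.fuzzy.codon = "X"))
  cand <- cand[!grepl("*", cand$peptide, fixed = TRUE) &
                 nchar(cand$peptide) >= params$min_exon_length_aa, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand$similarity_score <- as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(cand$peptide),
    Biostrings::AAString(search_pep),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    scoreOnly = TRUE))
  cand <- cand[cand$similarity_score > params$min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ## overlap resolution: preferred splice class, then score, then position
  pref <- match(cand$splice_class, params$splice_site_preference)
  ord <- order(pref, -cand$similarity_score, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- kept & cand$start < cand$end[i] & cand$end > cand$start[i]
    if (!any(ov)) kept[i] <- TRUE
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  cand[, c("start", "end", "splice_class", "peptide", "similarity_score",
           "length_nt", "length_delta_nt")]
}

## introns neighbouring an exon within its transcripts, as genomic intervals
neighbour_introns <- function(gene, exon_id) {
  out <- list()
  for (t in gene$transcripts) {
    i <- match(exon_id, t)
    if (is.na(i)) next
    ex <- gene$exons
    pos <- function(id) ex[match(id, ex$exon_id), c("start", "end")]
    here <- pos(exon_id)
    gap <- function(a, b) c(min(a$end, b$end), max(a$start, b$start))
    if (i > 1L) out[[length(out) + 1L]] <- gap(pos(t[i - 1L]), here)
    if (i < length(t)) out[[length(out) + 1L]] <- gap(pos(t[i + 1L]), here)
  }
  ## genomic intervals [end of left exon, start of right exon)
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ivs <- unique(do.call(rbind, lapply(out, function(v) {
    data.frame(start = v[1], end = v[2])
  })))
  ivs[!is.na(ivs$start) & ivs$end > ivs$start, , drop = FALSE]
}

#' Predict novel MXE candidates for one gene
#'
#' Runs [scan_intron()] over both neighbouring introns of every internal
#' exon, in the exon's reading frame and transcription orientation, and maps
#' hits back to genomic coordinates. Candidates overlapping any annotated
#' exon of the gene are dropped.
#'
#' @param gene a [gene_model].
#' @param genome [Biostrings::DNAStringSet] with the gene's chromosome.
#' @param params [prediction_params].
#' @return data.frame of predicted exons (genomic 0-based half-open) with the
#'   id of their search exon.
#' @export
predict_mxe_candidates <- function(gene, genome, params = prediction_params()) {
  ex <- gene$exons
  chrom_seq <- genome[[gene$chrom]]
  minus <- gene$strand == "-"
  internal <- vapply(ex$exon_id, function(e) {
    any(vapply(gene$transcripts, function(t) {
      i <- match(e, t); !is.na(i) && i > 1L && i < length(t)
    }, logical(1)))
  }, logical(1))
  hits <- list()
  for (i in which(internal)) {
    eseq <- as.character(Biostrings::subseq(chrom_seq, ex$start[i] + 1L,
                                            ex$end[i]))
    if (minus) eseq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(eseq)))
    pep <- translate_frame(eseq, ex$phase_in[i])
    if (grepl("*", pep, fixed = TRUE) || !nzchar(pep)) next
    ivs <- neighbour_introns(gene, ex$exon_id[i])
    for (r in seq_len(nrow(ivs))) {
      iv <- ivs[r, ]
      iseq <- as.character(Biostrings::subseq(chrom_seq, iv$start + 1L, iv$end))
      if (minus) iseq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(iseq)))
      cand <- scan_intron(eseq, iseq, frame = ex$phase_in[i], params = params)
      if (nrow(cand) == 0L) next
      if (minus) {
        gstart <- iv$end - cand$end
        gend <- iv$end - cand$start
      } else {
        gstart <- iv$start + cand$start
        gend <- iv$start + cand$end
      }
      hits[[length(hits) + 1L]] <- data.frame(
        search_exon_id = ex$exon_id[i], chrom = gene$chrom,
        start = gstart, end = gend, strand = gene$strand,
        splice_class_site = cand$splice_class, peptide = cand$peptide,
        similarity_score = cand$similarity_score,
        length_nt = cand$length_nt, length_delta_nt = cand$length_delta_nt,
        phase_in = ex$phase_in[i], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(search_exon_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  out <- unique(do.call(rbind, hits))
  ## predicted candidates must not overlap annotated exons of the gene
  ov <- vapply(seq_len(nrow(out)), function(k)
    any(out$start[k] < ex$end & out$end[k] > ex$start), logical(1))
  out[!ov, , drop = FALSE]
}

#' Merge predicted candidates with annotated clusters
#'
#' Each search exon is merged with its surviving intron candidates into one
#' positionally ordered cluster; when the search exon already belongs to an
#' annotated cluster the candidates extend that cluster. Candidates
#' overlapping annotated terminal exons of the gene are dropped.
#'
#' @param gene a [gene_model].
#' @param annotated_clusters list of [mxe_cluster] from
#'   [extract_annotated_mxe_candidates()].
#' @param predicted data.frame from [predict_mxe_candidates()].
#' @return list of [mxe_cluster] (annotated clusters, possibly extended,
#'   followed by purely novel clusters).
#' @export
build_candidate_clusters <- function(gene, annotated_clusters, predicted) {
  ex <- gene$exons
  term <- ex[ex$splice_class == "terminal", , drop = FALSE]
  if (nrow(predicted)) {
    ovt <- vapply(seq_len(nrow(predicted)), function(k)
      any(predicted$start[k] < term$end & predicted$end[k] > term$start),
      logical(1))
    predicted <- predicted[!ovt, , drop = FALSE]
  }
  clusters <- annotated_clusters
  if (nrow(predicted) == 0L) return(clusters)
  predicted$exon_id <- exon_id_of(gene$gene_id, predicted$chrom,
                                  predicted$start, predicted$end)
  pred_exon_row <- function(p) data.frame(
    exon_id = p$exon_id, chrom = p$chrom, start = p$start, end = p$end,
    strand = p$strand, length_nt = p$end - p$start, phase_in = p$phase_in,
    source = "predicted", gene_id = gene$gene_id, splice_class = "novel",
    stringsAsFactors = FALSE)
  ## append candidates to a member table, skipping duplicates and anything
  ## overlapping an already-present member (candidates from the two introns
  ## of different search exons can collide)
  merge_members <- function(members, newex) {
    for (k in seq_len(nrow(newex))) {
      if (newex$exon_id[k] %in% members$exon_id) next
      if (any(newex$start[k] < members$end & newex$end[k] > members$start))
        next
      members <- rbind(members, newex[k, ])
    }
    members
  }
  by_search <- split(predicted, predicted$search_exon_id)
  for (se in names(by_search)) {
    prows <- by_search[[se]]
    newex <- do.call(rbind, lapply(seq_len(nrow(prows)),
                                   function(k) pred_exon_row(prows[k, ])))
    owner <- which(vapply(clusters, function(cl) se %in% cl$member_exon_ids,
                          logical(1)))
    if (length(owner)) {
      cl <- clusters[[owner[1]]]
      members <- merge_members(cl$members[, names(newex)], newex)
      if (nrow(members) == nrow(cl$members)) next
      b <- run_boundaries(ex, members)
      clusters[[owner[1]]] <- mxe_cluster(cl$cluster_id, gene$gene_id,
                                          members, b$up, b$down,
                                          chrom = gene$chrom,
                                          strand = gene$strand)
    } else {
      members <- merge_members(
        ex[ex$exon_id == se,
           c("exon_id", "chrom", "start", "end", "strand", "length_nt",
             "phase_in", "source", "gene_id", "splice_class")], newex)
      if (nrow(members) < 2L) next
      b <- run_boundaries(ex, members)
      cid <- sprintf("%s.p%d", gene$gene_id, length(clusters) + 1L)
      clusters[[length(clusters) + 1L]] <-
        mxe_cluster(cid, gene$gene_id, members, b$up, b$down,
                    chrom = gene$chrom, strand = gene$strand)
    }
  }
  clusters
}
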