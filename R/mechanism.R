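## Candidate regulatory mechanisms for validated clusters: minor-spliceosome
## (U12) donor incompatibility, steric branch-point proximity, and
## reading-frame coupling to nonsense-mediated decay.

#' Detect a U12-type donor site
#'
#' Matches the first eight intronic nucleotides against the minor-spliceosome
#' donor consensus `[AG]TATCCTT`. The invariant TATC core (offsets 2-5 of the
#' 8-mer) must match exactly; up to `k` mismatches are allowed over the
#' remaining positions (offset 1 counts as a match for A or G).
#'
#' @param donor_region at least the first 8 intronic nucleotides.
#' @param k mismatch tolerance outside the core (default 1).
#' @return logical flag.
#' @export
detect_u12_donor <- function(donor_region, k = 1L) {
  if (nchar(donor_region) < 8L)
    stop("donor region must be at least 8 nt")
  s <- strsplit(toupper(substr(donor_region, 1L, 8L)), "")[[1]]
  if (paste(s[2:5], collapse = "") != "TATC") return(FALSE)
  mism <- sum(!(s[1] %in% c("A", "G")), s[6] != "C", s[7] != "T",
              s[8] != "T")
  mism <= k
}

#' Steric branch-point proximity flag
#'
#' An intron is flagged when a too-short distance between its donor site and
#' the branch point (< 50 bp) would sterically block splicing of the
#' intervening intron. Introns of 500 bp or more are never flagged: branch
#' point prediction is unreliable there and multiple branch points with
#' different kinetics may exist.
#'
#' @param intron_length intron length in nucleotides.
#' @param bp_position branch-point offset from the intron donor site
#'   (0-based nucleotides into the intron).
#' @param max_distance steric distance threshold (default 50).
#' @param intron_gate length gate (default 500).
#' @return logical flag.
#' @export
steric_flag <- function(intron_length, bp_position, max_distance = 50L,
                        intron_gate = 500L) {
  if (bp_position < 0 || bp_position >= intron_length)
    stop("branch point outside its intron")
  intron_length < intron_gate && bp_position < max_distance
}

#' Naive branch-point scorer (synthetic data fallback)
#'
#' Best match to the yTNAy lariat consensus within the 3' half of the
#' intron; ties resolved towards the 3' end, where branch points typically
#' sit. Intended for synthetic cohorts only; real analyses should supply a
#' precomputed branch-point table.
#'
#' @param intron_seq intron nucleotide sequence.
#' @return list with `position` (0-based offset of the branch-point A from
#'   the donor) and `score` (0-4 consensus matches), or NULL when the intron
#'   is shorter than 10 nt.
#' @export
find_branch_point <- function(intron_seq) {
  n <- nchar(intron_seq)
  if (n < 10L) return(NULL)
  s <- strsplit(toupper(intron_seq), "")[[1]]
  from <- max(floor(n / 2), 1L)
  starts <- from:(n - 4L)
  score <- vapply(starts, function(i) {
    sum(s[i] %in% c("C", "T"), s[i + 1L] == "T", s[i + 3L] == "A",
        s[i + 4L] %in% c("C", "T"))
  }, numeric(1))
  has_a <- vapply(starts, function(i) s[i + 3L] == "A", logical(1))
  if (any(has_a)) { starts <- starts[has_a]; score <- score[has_a] }
  best <- max(score)
  i <- max(starts[score == best])
  list(position = i + 2L, score = best)    # 0-based offset of the A
}

#' Read / write a branch-point table
#'
#' TSV with columns chrom, intron_start, intron_end (0-based half-open),
#' bp_pos (genomic 0-based position of the branch-point adenosine), score.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_branch_points <- function(path) {
  bp <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "bp_pos", "score")
  stopifnot(all(need %in% names(bp)))
  bad <- bp$bp_pos < bp$intron_start | bp$bp_pos >= bp$intron_end
  if (any(bad)) stop("branch point outside its intron at row ",
                     which(bad)[1])
  bp
}

#' @rdname read_branch_points
#' @param bp branch-point data.frame.
#' @export
write_branch_points <- function(bp, path) {
  write.table(bp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## 8-mer donor regions of the intron preceding the cluster and of the intron
## following each member, in transcription orientation
cluster_donor_regions <- function(gene, cluster, genome) {
  chrom_seq <- genome[[cluster$chrom]]
  minus <- cluster$strand == "-"
  take <- function(gstart, gend) {
    if (gend - gstart < 8L) return(NULL)
    if (minus) {
      s <- Biostrings::subseq(chrom_seq, gend - 7L, gend)
      as.character(Biostrings::reverseComplement(s))
    } else as.character(Biostrings::subseq(chrom_seq, gstart + 1L,
                                           gstart + 8L))
  }
  m <- cluster$members
  ex <- gene$exons
  regions <- list()
  ## intron preceding the cluster (between upstream flank and first member,
  ## in transcription orientation)
  if (minus) {
    if (!is.na(cluster$downstream_boundary))
      regions$preceding <- take(max(m$end), cluster$downstream_boundary)
  } else if (!is.na(cluster$upstream_boundary))
    regions$preceding <- take(cluster$upstream_boundary, min(m$start))
  ## intron following each member
  for (i in seq_len(nrow(m))) {
    nxt_start <- if (minus) {
      edges <- c(ex$end[ex$end <= m$start[i]],
                 m$end[m$end <= m$start[i]])
      if (length(edges)) c(max(edges), m$start[i]) else NULL
    } else {
      edges <- c(ex$start[ex$start >= m$end[i]],
                 m$start[m$start >= m$end[i]])
      if (length(edges)) c(m$end[i], min(edges)) else NULL
    }
    if (!is.null(nxt_start) && nxt_start[2] > nxt_start[1])
      regions[[paste0("after_", m$exon_id[i])]] <-
        take(nxt_start[1], nxt_start[2])
  }
  Filter(Negate(is.null), regions)
}

## introns internal to the cluster span, as rows of a bp table lookup
cluster_intron_bps <- function(cluster, bp_table) {
  if (is.null(bp_table) || nrow(bp_table) == 0L)
    return(data.frame(chrom = character(0), intron_start = integer(0),
                      intron_end = integer(0), bp_pos = integer(0),
                      score = numeric(0)))
  span_lo <- min(cluster$members$start)
  span_hi <- max(cluster$members$end)
  lo <- if (!is.na(cluster$upstream_boundary)) cluster$upstream_boundary
        else span_lo
  hi <- if (!is.na(cluster$downstream_boundary)) cluster$downstream_boundary
        else span_hi
  bp_table[bp_table$chrom == cluster$chrom &
             bp_table$intron_start >= lo & bp_table$intron_end <= hi, ,
           drop = FALSE]
}

#' Classify the splicing mechanism of a validated cluster
#'
#' Evaluates three independent flags: `u12_incompatible` (a minor-spliceosome
#' donor at one of the cluster's introns), `steric_bp` (a branch point within
#' 50 bp of a donor in a < 500 bp intron between or around the members) and
#' `frame_nmd` (any member length not divisible by three, so joint inclusion
#' would frame-shift and expose the transcript to nonsense-mediated decay).
#' The label is assigned by fixed priority u12 > steric > frame_nmd, with
#' `unexplained` when no flag is set. Whether joining reads were actually
#' observed is reported alongside.
#'
#' @param cluster an [mxe_cluster].
#' @param validation the cluster's `validation_result`.
#' @param gene the owning [gene_model] (for donor extraction); may be NULL
#'   when `donor_regions` is given.
#' @param genome genome [Biostrings::DNAStringSet]; may be NULL when
#'   `donor_regions` is given.
#' @param bp_table branch-point table (see [read_branch_points()]) or NULL.
#' @param donor_regions optional pre-extracted donor 8-mers (overrides
#'   gene/genome extraction).
#' @param k U12 mismatch tolerance.
#' @param max_distance,intron_gate steric thresholds, see [steric_flag()].
#' @return list of class `mechanism_call` with the flags, the label and
#'   `joining_reads_observed`.
#' @export
classify_mechanism <- function(cluster, validation, gene = NULL,
                               genome = NULL, bp_table = NULL,
                               donor_regions = NULL, k = 1L,
                               max_distance = 50L, intron_gate = 500L) {
  if (is.null(donor_regions)) {
    donor_regions <- if (!is.null(gene) && !is.null(genome))
      cluster_donor_regions(gene, cluster, genome) else list()
  }
  u12 <- any(vapply(donor_regions, detect_u12_donor, logical(1), k = k))
  bps <- cluster_intron_bps(cluster, bp_table)
  steric <- nrow(bps) > 0L && any(vapply(seq_len(nrow(bps)), function(r)
    steric_flag(bps$intron_end[r] - bps$intron_start[r],
                bps$bp_pos[r] - bps$intron_start[r],
                max_distance = max_distance, intron_gate = intron_gate),
    logical(1)))
  frame_nmd <- any(cluster$members$length_nt %% 3L != 0L)
  joins <- validation$constraints[validation$constraints$kind == "no_join", ]
  joining_observed <- any(joins$reads > 0L)
  label <- if (u12) "u12" else if (steric) "steric"
           else if (frame_nmd) "frame_nmd" else "unexplained"
  structure(list(cluster_id = cluster$cluster_id, u12_incompatible = u12,
                 steric_bp = steric, frame_nmd = frame_nmd,
                 joining_reads_observed = joining_observed, label = label),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("cluster %s: %s (u12=%s steric=%s frame_nmd=%s joins=%s)\n",
              x$cluster_id, x$label, x$u12_incompatible, x$steric_bp,
              x$frame_nmd, x$joining_reads_observed))
  invisible(x)
}
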