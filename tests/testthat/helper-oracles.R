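# Independent brute-force oracles. These deliberately re-derive results with
# naive enumeration (own codon table, all-pairs loops, exhaustive labelings)
# so they share no code path with the implementation they check.

ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases)
    codons <- c(codons, paste0(b1, b2, b3))
  setNames(aa, codons)
})

oracle_translate <- function(dna, frame = 0L) {
  skip <- (3L - (frame %% 3L)) %% 3L
  n <- (nchar(dna) - skip) %/% 3L
  if (n <= 0L) return("")
  paste(vapply(seq_len(n), function(i)
    unname(ORACLE_CODONS[substr(dna, skip + 3L * i - 2L, skip + 3L * i)]),
    ""), collapse = "")
}

# naive window enumeration mirroring every stated filter independently;
# scoring shares the similarity_score primitive (the oracle checks the
# enumeration and filtering, not the substitution matrix)
oracle_scan_intron <- function(search_seq, intron_seq, frame = 0L,
                               params = prediction_params()) {
  L <- nchar(search_seq)
  n <- nchar(intron_seq)
  donors <- sub("-AG$", "", params$splice_site_preference)
  search_pep <- oracle_translate(search_seq, frame)
  rows <- list()
  for (delta in seq(-params$max_length_difference_aa * 3L,
                    params$max_length_difference_aa * 3L, by = 3L)) {
    w <- L + delta
    if (w < 3L) next
    for (s in seq_len(n)) {                      # 1-based start
      if (s < 3L || s + w + 1L > n) next
      if (substr(intron_seq, s - 2L, s - 1L) != "AG") next
      donor <- substr(intron_seq, s + w, s + w + 1L)
      if (!donor %in% donors) next
      pep <- oracle_translate(substr(intron_seq, s, s + w - 1L), frame)
      if (grepl("*", pep, fixed = TRUE)) next
      if (nchar(pep) < params$min_exon_length_aa) next
      sc <- similarity_score(pep, search_pep,
                             gap_opening = params$gap_opening,
                             gap_extension = params$gap_extension)
      if (sc <= params$min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s - 1L, end = s - 1L + w,
        splice_class = paste0(donor, "-AG"), peptide = pep,
        similarity_score = sc, length_nt = w, length_delta_nt = w - L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      splice_class = character(0), peptide = character(0),
                      similarity_score = numeric(0), length_nt = integer(0),
                      length_delta_nt = integer(0)))
  cand <- do.call(rbind, rows)
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
  rownames(cand) <- NULL
  cand
}

# two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, probabilities from choose()
oracle_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  xs <- max(0, m - n2):min(m, n1)
  pr <- vapply(xs, function(x)           # log scale to dodge overflow
    exp(lchoose(n1, x) + lchoose(n2, m - x) - lchoose(n1 + n2, m)),
    numeric(1))
  obs <- pr[match(k1, xs)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

oracle_gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# exhaustive Dollo: over all single-gain node labelings consistent with the
# observed leaves (unknown leaves free), minimise the number of 1->0 edges
oracle_dollo_min_losses <- function(tree, presence) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  obs <- setNames(rep(NA, n_tip), tree$tip.label)
  obs[names(presence)] <- ifelse(presence == "1", TRUE,
                                 ifelse(presence == "0", FALSE, NA))
  fixed <- which(!is.na(obs))
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  bit <- 2^(0:(n_node - 1))
  best <- Inf
  for (code in 0:(2^n_node - 1)) {
    lab <- bitwAnd(code, bit) > 0
    if (!all(lab[fixed] == obs[fixed])) next
    gains <- sum(!lab[e1] & lab[e2]) + as.integer(lab[root])
    if (gains != 1L) next
    losses <- sum(lab[e1] & !lab[e2])
    if (losses < best) best <- losses
  }
  best
}

# naive all-pairs interval intersection
oracle_intersect <- function(exons, variants) {
  hits <- list()
  for (i in seq_len(nrow(exons)))
    for (j in seq_len(nrow(variants)))
      if (exons$chrom[i] == variants$chrom[j] &&
          variants$pos[j] >= exons$start[i] &&
          variants$pos[j] < exons$end[i])
        hits[[length(hits) + 1L]] <- data.frame(
          exon_id = exons$exon_id[i], variant_row = j,
          stringsAsFactors = FALSE)
  if (length(hits) == 0L)
    return(data.frame(exon_id = character(0), variant_row = integer(0)))
  do.call(rbind, hits)
}
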