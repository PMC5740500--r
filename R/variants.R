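## Clinical-variant intersection and pathogenic-variant enrichment testing.

#' Read a BED-like variant table
#'
#' TSV with header columns chrom, pos (1-based), ref, alt,
#' clinical_significance, variant_type (SNV/indel/structural). Positions are
#' converted to the internal 0-based convention; rows with several
#' comma-separated alternate alleles are split per allele.
#'
#' @param path file path.
#' @return data.frame with 0-based `pos`.
#' @export
read_variant_table <- function(path) {
  v <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "clinical_significance",
            "variant_type")
  stopifnot(all(need %in% names(v)))
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  v <- v[rep(seq_len(nrow(v)), lengths(alts)), , drop = FALSE]
  v$alt <- unlist(alts)
  v$pos <- as.integer(v$pos) - 1L
  bad <- v$variant_type == "SNV" & (nchar(v$ref) != 1L | nchar(v$alt) != 1L)
  if (any(bad)) stop("SNV with multi-base alleles at row ", which(bad)[1])
  rownames(v) <- NULL
  v
}

#' Read variants from a VCF (ClinVar-style)
#'
#' Uses VariantAnnotation when available; the clinical significance is taken
#' from the CLNSIG info field. Structural variants are any record whose ref
#' or alt allele is symbolic or longer than 50 bp.
#'
#' @param path VCF path.
#' @return data.frame in the [read_variant_table()] layout (0-based pos).
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  info <- VariantAnnotation::info(vcf)
  sig <- if ("CLNSIG" %in% names(info))
    vapply(info$CLNSIG, function(x) paste(as.character(x), collapse = "/"),
           "") else rep("", length(vcf))
  rows <- list()
  for (i in seq_along(vcf)) {
    for (a in as.character(alt_list[[i]])) {
      type <- if (grepl("[<>\\[\\]]", a) || nchar(ref[i]) > 50L ||
                  nchar(a) > 50L) "structural"
              else if (nchar(ref[i]) == 1L && nchar(a) == 1L) "SNV"
              else "indel"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr))[i],
        pos = GenomicRanges::start(rr)[i] - 1L, ref = ref[i], alt = a,
        clinical_significance = sig[i], variant_type = type,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Keep potentially pathogenic variants
#'
#' Removes every record whose clinical-significance string contains "benign"
#' (case-insensitive, so "Likely benign" and conflicting strings such as
#' "Benign/Likely benign" are removed too) and all structural variants.
#'
#' @param records variant data.frame.
#' @return filtered data.frame.
#' @export
filter_pathogenic <- function(records) {
  keep <- !grepl("benign", records$clinical_significance,
                 ignore.case = TRUE) & records$variant_type != "structural"
  records[keep, , drop = FALSE]
}

#' Intersect exons with variant positions
#'
#' A variant is assigned to every exon whose half-open interval contains its
#' position (a variant on the exon start overlaps; one on the exclusive end
#' coordinate does not).
#'
#' @param exons data.frame with exon_id, chrom, start, end (0-based
#'   half-open).
#' @param variants data.frame with chrom, pos (0-based).
#' @return list with `hits` (data.frame exon_id, variant_row) and
#'   `exon_flag` (named logical: exon carries >= 1 variant).
#' @export
intersect_exons <- function(exons, variants) {
  flag <- setNames(rep(FALSE, nrow(exons)), exons$exon_id)
  if (nrow(exons) == 0L || nrow(variants) == 0L)
    return(list(hits = data.frame(exon_id = character(0),
                                  variant_row = integer(0)),
                exon_flag = flag))
  eg <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start + 1L, exons$end))
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos + 1L, width = 1))
  ov <- GenomicRanges::findOverlaps(eg, vg)
  hits <- data.frame(exon_id = exons$exon_id[S4Vectors::queryHits(ov)],
                     variant_row = S4Vectors::subjectHits(ov),
                     stringsAsFactors = FALSE)
  flag[unique(hits$exon_id)] <- TRUE
  list(hits = hits, exon_flag = flag)
}

## two-sided Fisher exact p by hypergeometric tail summation over the 2x2
## table (k1, n1-k1; k2, n2-k2)
fisher_p2 <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  if (m == 0L || m == n1 + n2) return(1)
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  x <- lo:hi
  d <- dhyper(x, n1, n2, m)
  sum(d[d <= d[match(k1, x)] * (1 + 1e-7)])
}

#' Pathogenic-variant enrichment test
#'
#' Compares the proportion of variant-bearing exons in a class (e.g. MXEs or
#' cassette exons) against a background exon set with a two-sided Fisher
#' exact test computed by hypergeometric tail summation. Proportions are
#' reported as percentages rounded to one decimal, matching the convention
#' of published exon counts.
#'
#' @param k_class,n_class variant-bearing and total exons in the class.
#' @param k_background,n_background same for the background set.
#' @return list of class `enrichment_result`: counts, `prop_class` and
#'   `prop_background` (1-decimal percent), `odds_ratio`
#'   (k1(n2-k2)/(k2(n1-k1)); NA on a zero margin) and two-sided `p`.
#' @export
enrichment_test <- function(k_class, n_class, k_background, n_background) {
  stopifnot(k_class <= n_class, k_background <= n_background,
            k_class >= 0, k_background >= 0)
  or <- {
    denom <- k_background * (n_class - k_class)
    if (denom == 0) NA_real_
    else (k_class * (n_background - k_background)) / denom
  }
  p <- fisher_p2(k_class, n_class, k_background, n_background)
  structure(list(k_class = k_class, n_class = n_class,
                 k_background = k_background, n_background = n_background,
                 prop_class = round(100 * k_class / n_class, 1),
                 prop_background = round(100 * k_background / n_background, 1),
                 odds_ratio = or, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%d/%d (%.1f%%) vs %d/%d (%.1f%%); OR=%.3g, p=%.3g\n",
              x$k_class, x$n_class, x$prop_class, x$k_background,
              x$n_background, x$prop_background, x$odds_ratio, x$p))
  invisible(x)
}
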