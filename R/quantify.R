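## Inclusion quantification: percent-spliced-in, RPKM, differential
## inclusion (Kruskal-Wallis + Benjamini-Hochberg, both authored here),
## Gini tissue specificity and delta-PSI.

## bridging reads of member i of a cluster in the pooled table: first member
## uses its downstream bridge only, last member its upstream bridge only,
## internal members the sum of both.
member_bridge_reads <- function(cluster, pooled, i) {
  m <- cluster$members
  n <- nrow(m)
  r <- 0L
  if (i < n) r <- r + reads_bridge_down(pooled, m$end[i], m$end[n])
  if (i > 1L) r <- r + reads_bridge_up(pooled, m$start[i], m$start[1])
  r
}

#' Percent-spliced-in of a cluster in one sample
#'
#' PSI of a member is its junction reads divided by the summed junction
#' reads of all members of the cluster in the sample. A member's junction
#' reads are the sum of its bridging junctions (both sides where both exist;
#' the terminal members of the cluster use their single bridging side).
#' An all-zero denominator yields all-missing PSIs.
#'
#' @param cluster an [mxe_cluster].
#' @param sj an [sj_index].
#' @param sample sample id.
#' @return named numeric vector of PSIs (NA when unexpressed), one per
#'   member; non-missing values sum to 1.
#' @export
compute_psi <- function(cluster, sj, sample) {
  pooled <- sj_for_cluster(sj_pool(sj, samples = sample), cluster$chrom,
                           cluster$strand)
  r <- vapply(seq_len(nrow(cluster$members)), member_bridge_reads,
              numeric(1), cluster = cluster, pooled = pooled)
  names(r) <- cluster$member_exon_ids
  if (sum(r) == 0) return(setNames(rep(NA_real_, length(r)), names(r)))
  r / sum(r)
}

#' PSI matrix over clusters and samples
#'
#' @param clusters list of [mxe_cluster].
#' @param sj an [sj_index].
#' @param samples sample ids (default: all samples in `sj`).
#' @return object of class `psi_matrix`: list with `psi` (exon x sample
#'   matrix) and `cluster_of` (named vector exon_id -> cluster_id).
#' @export
psi_matrix <- function(clusters, sj, samples = unique(sj$sample_id)) {
  rows <- unlist(lapply(clusters, `[[`, "member_exon_ids"))
  cluster_of <- setNames(
    rep(vapply(clusters, `[[`, "", "cluster_id"),
        vapply(clusters, function(c) length(c$member_exon_ids), 0L)),
    rows)
  psi <- matrix(NA_real_, nrow = length(rows), ncol = length(samples),
                dimnames = list(rows, samples))
  for (s in samples)
    for (cl in clusters)
      psi[cl$member_exon_ids, s] <- compute_psi(cl, sj, s)
  structure(list(psi = psi, cluster_of = cluster_of),
            class = "psi_matrix")
}

#' Reads per kilobase per million mapped reads
#'
#' @param exon_read_count reads mapped to the exon.
#' @param exon_length_nt exon length in nucleotides (> 0).
#' @param total_mapped_reads total mapped reads in the sample (> 0).
#' @return RPKM value.
#' @export
compute_rpkm <- function(exon_read_count, exon_length_nt,
                         total_mapped_reads) {
  if (any(exon_length_nt <= 0)) stop("exon length must be positive")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be positive")
  exon_read_count / (exon_length_nt / 1000) / (total_mapped_reads / 1e6)
}

## Kruskal-Wallis rank statistic with tie correction (authored; see tests
## for the stats::kruskal.test cross-check). All-tied input: statistic 0.
kw_test <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  N <- length(values)
  g <- unique(groups)
  if (N < 2L || length(g) < 2L)
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_))
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = length(g) - 1L, p = 1))
  rk <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(g, function(gr) {
      idx <- groups == gr
      sum(idx) * (mean(rk[idx]) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  df <- length(g) - 1L
  list(statistic = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

## Benjamini-Hochberg step-up (authored)
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Differential inclusion across conditions
#'
#' Tests each exon's PSI across experimental conditions with a tie-corrected
#' Kruskal-Wallis rank test, then applies Benjamini-Hochberg adjustment over
#' the tested exons. Exons lacking at least two conditions with at least
#' `min_reps` non-missing replicates are untested (excluded from the BH
#' family), not assigned p = 1.
#'
#' @param psi a [psi_matrix()] or a plain exon x sample matrix.
#' @param design data.frame with columns `sample` and `condition` covering
#'   every column of the PSI matrix.
#' @param min_reps minimum non-missing replicates per condition (default 2).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame: exon_id, statistic, df, p, padj, tested, significant.
#' @export
differential_inclusion <- function(psi, design, min_reps = 2L,
                                   alpha = 0.05) {
  mat <- if (inherits(psi, "psi_matrix")) psi$psi else psi
  if (!all(colnames(mat) %in% design$sample))
    stop("design is missing samples: ",
         paste(setdiff(colnames(mat), design$sample), collapse = ", "))
  cond <- setNames(as.character(design$condition),
                   as.character(design$sample))[colnames(mat)]
  res <- data.frame(exon_id = rownames(mat), statistic = NA_real_,
                    df = NA_integer_, p = NA_real_, padj = NA_real_,
                    tested = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    reps <- tapply(!is.na(v), cond, sum)
    if (sum(reps >= min_reps) < 2L) next
    keep <- cond %in% names(reps)[reps >= min_reps] & !is.na(v)
    kw <- kw_test(v[keep], cond[keep])
    res$statistic[i] <- kw$statistic
    res$df[i] <- kw$df
    res$p[i] <- kw$p
    res$tested[i] <- TRUE
  }
  res$padj[res$tested] <- bh_adjust(res$p[res$tested])
  res$significant <- res$tested & !is.na(res$padj) & res$padj < alpha
  res
}

#' Gini index of inequality
#'
#' Population (uncorrected) form over ascending-sorted non-negative values:
#' G = sum((2i - n - 1) x_i) / (n^2 mean(x)). Equal values give 0; a single
#' positive value among n-1 zeros gives (n-1)/n. Scale-invariant.
#'
#' @param values at least two non-negative values.
#' @param unbiased apply the n/(n-1) small-sample correction (default FALSE,
#'   matching the uncorrected form).
#' @return Gini index in \[0, 1\], or NA when all values are zero.
#' @export
gini <- function(values, unbiased = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need >= 2 values")
  if (any(values < 0)) stop("values must be non-negative")
  if (all(values == 0)) return(NA_real_)
  xs <- sort(values)
  n <- length(xs)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
  if (unbiased) g <- g * n / (n - 1)
  g
}

#' Per-exon Gini indices and per-cluster specificity designations
#'
#' For each exon, mean PSI per condition is computed and the Gini index
#' taken across conditions; within each cluster the member with the maximum
#' Gini is designated `specific` and the one with the minimum `ubiquitous`.
#' Clusters where every member's PSI is missing are excluded.
#'
#' @param psi a [psi_matrix()].
#' @param design design data.frame (`sample`, `condition`).
#' @param unbiased passed to [gini()].
#' @return data.frame: exon_id, cluster_id, gini, designation.
#' @export
gini_by_exon <- function(psi, design, unbiased = FALSE) {
  mat <- psi$psi
  cond <- setNames(as.character(design$condition),
                   as.character(design$sample))[colnames(mat)]
  cond_means <- t(apply(mat, 1, function(v)
    tapply(v, cond, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))))
  g <- apply(cond_means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || all(v == 0)) return(NA_real_)
    gini(v, unbiased = unbiased)
  })
  out <- data.frame(exon_id = rownames(mat),
                    cluster_id = psi$cluster_of[rownames(mat)],
                    gini = as.numeric(g), designation = NA_character_,
                    stringsAsFactors = FALSE)
  for (cl in unique(out$cluster_id)) {
    idx <- which(out$cluster_id == cl & !is.na(out$gini))
    if (length(idx) < 2L) next
    spec <- idx[which.max(out$gini[idx])]
    rest <- setdiff(idx, spec)            # ties: specific wins the slot
    out$designation[spec] <- "specific"
    out$designation[rest[which.min(out$gini[rest])]] <- "ubiquitous"
  }
  rownames(out) <- NULL
  out
}

#' Delta-PSI between a cluster's specific and ubiquitous members
#'
#' Per condition, the mean PSI of the ubiquitous member is subtracted from
#' the mean PSI of the specific member. Members are paired by rule:
#' `gini_extremes` (maximum vs minimum Gini), `known_vs_novel` (novel vs
#' annotated source) or `snp_vs_nonsnp` (pathogenic-variant-bearing vs not;
#' requires `snp_members`). Conditions where either member is missing or the
#' cluster is unexpressed yield 0. Values lie in \[-1, 1\] by construction;
#' any heat-map rescaling is a reporting concern, not applied here.
#'
#' @param cluster an [mxe_cluster].
#' @param psi a [psi_matrix()].
#' @param design design data.frame (`sample`, `condition`).
#' @param pairing_rule pairing rule, see above.
#' @param gini_table optional precomputed [gini_by_exon()] output.
#' @param snp_members exon ids bearing pathogenic variants (for
#'   `snp_vs_nonsnp`).
#' @return data.frame (condition, value, specific, ubiquitous) of class
#'   `delta_psi`, or NULL when the pairing rule is inapplicable (untested).
#' @export
delta_psi <- function(cluster, psi, design,
                      pairing_rule = c("gini_extremes", "known_vs_novel",
                                       "snp_vs_nonsnp"),
                      gini_table = NULL, snp_members = character(0)) {
  pairing_rule <- match.arg(pairing_rule)
  ids <- cluster$member_exon_ids
  pick <- switch(pairing_rule,
    gini_extremes = {
      gt <- gini_table %||% gini_by_exon(psi, design)
      gt <- gt[gt$exon_id %in% ids & !is.na(gt$gini), ]
      if (nrow(gt) < 2L) return(NULL)
      spec <- which.max(gt$gini)
      rest <- setdiff(seq_len(nrow(gt)), spec)
      list(specific = gt$exon_id[spec],
           ubiquitous = gt$exon_id[rest[which.min(gt$gini[rest])]])
    },
    known_vs_novel = {
      src <- setNames(cluster$members$source, ids)
      nov <- ids[src == "predicted"]; ann <- ids[src == "annotated"]
      if (!length(nov) || !length(ann)) return(NULL)
      list(specific = nov[1], ubiquitous = ann[1])
    },
    snp_vs_nonsnp = {
      with_snp <- intersect(ids, snp_members)
      without <- setdiff(ids, snp_members)
      if (!length(with_snp) || !length(without)) return(NULL)
      list(specific = with_snp[1], ubiquitous = without[1])
    })
  mat <- psi$psi
  cond <- setNames(as.character(design$condition),
                   as.character(design$sample))[colnames(mat)]
  conds <- unique(cond)
  vals <- vapply(conds, function(cn) {
    a <- mean(mat[pick$specific, cond == cn], na.rm = TRUE)
    b <- mean(mat[pick$ubiquitous, cond == cn], na.rm = TRUE)
    if (is.nan(a) || is.nan(b)) 0 else a - b   # unexpressed pairs -> 0
  }, numeric(1))
  structure(data.frame(condition = conds, value = as.numeric(vals),
                       specific = pick$specific,
                       ubiquitous = pick$ubiquitous,
                       stringsAsFactors = FALSE),
            class = c("delta_psi", "data.frame"),
            pairing_rule = pairing_rule)
}

#' Median-RPKM expression gate
#'
#' @param rpkm exon x sample RPKM matrix (cluster members as rows).
#' @param min_rpkm threshold.
#' @param mode "median_any_member" (pair analyses: any member's median RPKM
#'   above threshold) or "two_members_any_sample" (Gini cluster analysis:
#'   at least two members reach the threshold in at least one sample).
#' @return logical.
#' @export
passes_expression_gate <- function(rpkm, min_rpkm,
                                   mode = c("median_any_member",
                                            "two_members_any_sample")) {
  mode <- match.arg(mode)
  if (mode == "median_any_member")
    any(apply(rpkm, 1, median, na.rm = TRUE) > min_rpkm)
  else sum(apply(rpkm, 1, function(v) any(v >= min_rpkm, na.rm = TRUE))) >= 2L
}
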