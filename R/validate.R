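## Read-evidence validation of MXE candidate clusters: constraint
## enumeration, sub-cluster decomposition, frame-shift tolerance and
## 1SJ/3SJ support levels.

#' Enumerate contiguous sub-clusters
#'
#' All contiguous index runs of length >= 2 of a cluster of size `n`,
#' ordered by length then start: a 4-exon cluster yields
#' \[1,2\], \[2,3\], \[3,4\], \[1,2,3\], \[2,3,4\], \[1,2,3,4\].
#'
#' @param n cluster size (>= 2).
#' @return list of integer vectors, n(n-1)/2 of them.
#' @export
enumerate_subclusters <- function(n) {
  if (!is.numeric(n) || n < 2L) stop("cluster size must be >= 2")
  n <- as.integer(n)
  out <- list()
  for (len in 2:n)
    for (s in 1:(n - len + 1L))
      out[[length(out) + 1L]] <- s:(s + len - 1L)
  out
}

#' Number of read-evidence constraints for a cluster
#'
#' Default mode counts one joining-read-absence constraint per member pair
#' (n(n-1)/2) plus the bridging-junction requirements (first member:
#' downstream bridge only; last member: upstream only; internal members:
#' both; 2(n-1) in total). Strict mode adds the two junctions connecting the
#' terminal members to the immediately adjacent annotated exons.
#'
#' @param n cluster size (>= 2).
#' @param strict require flank-adjacent junctions as well.
#' @return integer constraint count: n(n-1)/2 + 2(n-1) (+ 2 if strict).
#' @export
constraint_count <- function(n, strict = FALSE) {
  if (!is.numeric(n) || n < 2L) stop("cluster size must be >= 2")
  n <- as.integer(n)
  as.integer(n * (n - 1L) / 2L + 2L * (n - 1L) + if (strict) 2L else 0L)
}

#' Enumerate the individual constraints of a cluster
#'
#' @param n cluster size (>= 2).
#' @param strict include the two flank-adjacent junction requirements.
#' @return data.frame with columns `kind` (no_join, bridge_up, bridge_down,
#'   flank_up, flank_down), `i`, `j` (member indices; `j` is NA except for
#'   no_join). One row per constraint; `nrow()` equals [constraint_count()].
#' @export
enumerate_constraints <- function(n, strict = FALSE) {
  if (!is.numeric(n) || n < 2L) stop("cluster size must be >= 2")
  n <- as.integer(n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- data.frame(kind = "no_join", i = pairs[, "row"], j = pairs[, "col"])
  rows <- rows[order(rows$i, rows$j), ]
  rows <- rbind(rows,
                data.frame(kind = "bridge_down", i = 1:(n - 1L), j = NA_integer_),
                data.frame(kind = "bridge_up", i = 2:n, j = NA_integer_))
  if (strict)
    rows <- rbind(rows,
                  data.frame(kind = "flank_up", i = 1L, j = NA_integer_),
                  data.frame(kind = "flank_down", i = n, j = NA_integer_))
  rownames(rows) <- NULL
  rows
}

## reads on junctions with given end points / spans, over a pooled table
reads_exact <- function(p, js, je) {
  sum(p$unique_reads[p$start == js & p$end == je])
}
reads_bridge_down <- function(p, member_end, span_to, strict_to = NA) {
  if (!is.na(strict_to))
    return(sum(p$unique_reads[p$start == member_end & p$end == strict_to &
                                p$end >= span_to]))
  sum(p$unique_reads[p$start == member_end & p$end >= span_to])
}
reads_bridge_up <- function(p, member_start, span_from, strict_from = NA) {
  if (!is.na(strict_from))
    return(sum(p$unique_reads[p$end == member_start & p$start == strict_from &
                                p$start <= span_from]))
  sum(p$unique_reads[p$end == member_start & p$start <= span_from])
}

## frame-shift tolerance of a joining read between members i and j
join_tolerated <- function(len_i, len_j, rule = c("per_pair", "pair_sum")) {
  rule <- match.arg(rule)
  if (rule == "per_pair") (len_i %% 3L != 0L) || (len_j %% 3L != 0L)
  else ((len_i + len_j) %% 3L) != 0L
}

## evaluate every constraint of sub-cluster `idx` of `cluster`
evaluate_subcluster <- function(cluster, pooled, idx, min_reads, strict,
                                frame_rule) {
  m <- cluster$members[idx, , drop = FALSE]
  k <- nrow(m)
  rows <- list()
  add <- function(kind, i, j, reads, satisfied, tolerated = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, i = idx[i], j = if (is.na(j)) NA_integer_ else idx[j],
      reads = reads, satisfied = satisfied, tolerated = tolerated)
  }
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    r <- reads_exact(pooled, m$end[a], m$start[b])
    tol <- join_tolerated(m$length_nt[a], m$length_nt[b], frame_rule)
    add("no_join", a, b, r, r == 0L || tol, tolerated = r > 0L && tol)
  }
  for (a in seq_len(k - 1L)) {
    r <- reads_bridge_down(pooled, m$end[a], m$end[k],
                           if (strict) cluster$downstream_boundary else NA)
    add("bridge_down", a, NA, r, r >= min_reads)
  }
  for (a in 2:k) {
    r <- reads_bridge_up(pooled, m$start[a], m$start[1],
                         if (strict) cluster$upstream_boundary else NA)
    add("bridge_up", a, NA, r, r >= min_reads)
  }
  if (strict) {
    r <- reads_exact(pooled, cluster$upstream_boundary, m$start[1])
    add("flank_up", 1L, NA, r, r >= min_reads)
    r <- reads_exact(pooled, m$end[k], cluster$downstream_boundary)
    add("flank_down", k, NA, r, r >= min_reads)
  }
  do.call(rbind, rows)
}

#' Set aside predicted members without any junction data
#'
#' Predicted (novel) cluster members with no splice-junction read touching
#' either boundary carry no expression evidence either way: they are
#' candidates for which junction data are missing, not counter-evidence
#' against their neighbours. Left in place they would still break sub-cluster
#' contiguity, so they are removed from the cluster before validation and
#' reported separately. Annotated members are never pruned — their missing
#' reads are informative and keep the cluster unresolved.
#'
#' @param clusters list of [mxe_cluster].
#' @param sj an [sj_index].
#' @param samples optional sample subset used for the evidence check.
#' @return list with `clusters` (pruned; clusters reduced below two members
#'   are dropped) and `set_aside` (data.frame of removed exon ids and of
#'   cluster ids dropped entirely).
#' @export
prune_unsupported_members <- function(clusters, sj, samples = NULL) {
  pooled_all <- sj_pool(sj, samples)
  removed <- list()
  dropped <- character(0)
  kept <- list()
  for (cl in clusters) {
    pooled <- sj_for_cluster(pooled_all, cl$chrom, cl$strand)
    m <- cl$members
    supported <- vapply(seq_len(nrow(m)), function(i) {
      m$source[i] != "predicted" ||
        any(pooled$end == m$start[i] & pooled$unique_reads > 0L) ||
        any(pooled$start == m$end[i] & pooled$unique_reads > 0L)
    }, logical(1))
    if (all(supported)) {
      kept[[length(kept) + 1L]] <- cl
      next
    }
    removed[[length(removed) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id, exon_id = m$exon_id[!supported],
      stringsAsFactors = FALSE)
    if (sum(supported) >= 2L) {
      kept[[length(kept) + 1L]] <- mxe_cluster(
        cl$cluster_id, cl$gene_id, m[supported, , drop = FALSE],
        cl$upstream_boundary, cl$downstream_boundary,
        chrom = cl$chrom, strand = cl$strand)
    } else dropped <- c(dropped, cl$cluster_id)
  }
  list(clusters = kept,
       set_aside = list(
         members = if (length(removed)) do.call(rbind, removed) else
           data.frame(cluster_id = character(0), exon_id = character(0)),
         dropped_clusters = dropped))
}

#' Validate an MXE candidate cluster against splice-junction evidence
#'
#' Reads are pooled across the requested samples before thresholding. Every
#' contiguous sub-cluster is evaluated, largest first: a sub-cluster is valid
#' iff every member's required bridging junctions (junctions whose skipped
#' interval spans all other sub-cluster members, with the exon-proximal end
#' on the member boundary) carry at least `min_reads` pooled reads, and no
#' junction directly joining two members carries any read, unless that join
#' is tolerated because joint inclusion would shift the reading frame (a
#' member length not divisible by three). The largest valid sub-cluster
#' (ties: highest summed bridging reads, then leftmost) is returned as
#' `validated`. When no sub-cluster is valid, the cluster is `rejected` if a
#' non-tolerated joining read exists and `unresolved` otherwise (bridging
#' evidence missing). Strict mode additionally requires the junctions linking
#' the terminal members to the immediately adjacent annotated exons and pins
#' the distal bridge ends to those flank boundaries.
#'
#' @param cluster an [mxe_cluster].
#' @param sj an [sj_index].
#' @param min_reads support threshold (1 for 1SJ, 3 for 3SJ).
#' @param strict flag, see above.
#' @param samples optional subset of samples to pool.
#' @param frame_rule how frame-shift tolerance is computed for a joining pair
#'   ("per_pair": either length not divisible by three; "pair_sum": the sum).
#' @return list of class `validation_result`: cluster_id, status
#'   (validated/rejected/unresolved), chosen_subcluster (exon ids),
#'   support_level (1SJ/3SJ/none), constraints (evaluated table for the
#'   chosen sub-cluster, or the full cluster otherwise), tolerated_joins
#'   (data.frame of excused member pairs).
#' @export
classify_cluster <- function(cluster, sj, min_reads = 3L, strict = FALSE,
                             samples = NULL,
                             frame_rule = c("per_pair", "pair_sum")) {
  frame_rule <- match.arg(frame_rule)
  stopifnot(inherits(cluster, "mxe_cluster"))
  if (strict && (is.na(cluster$upstream_boundary) ||
                 is.na(cluster$downstream_boundary)))
    stop("strict mode needs both flanking boundaries for ",
         cluster$cluster_id)
  n <- nrow(cluster$members)
  pooled <- sj_for_cluster(sj_pool(sj, samples), cluster$chrom,
                           cluster$strand)
  subs <- enumerate_subclusters(n)
  ## largest first; within a length, leftmost first (tie-break order)
  subs <- subs[order(-lengths(subs), vapply(subs, min, integer(1)))]
  best <- NULL
  best_len <- -1L
  best_reads <- -Inf
  for (idx in subs) {
    if (length(idx) < best_len) break
    ev <- evaluate_subcluster(cluster, pooled, idx, min_reads, strict,
                              frame_rule)
    if (all(ev$satisfied)) {
      br <- sum(ev$reads[ev$kind %in% c("bridge_up", "bridge_down")])
      if (length(idx) > best_len ||
          (length(idx) == best_len && br > best_reads)) {
        best <- list(idx = idx, ev = ev)
        best_len <- length(idx)
        best_reads <- br
      }
    }
  }
  full_ev <- evaluate_subcluster(cluster, pooled, seq_len(n), min_reads,
                                 strict, frame_rule)
  if (!is.null(best)) {
    tolerated <- best$ev[best$ev$kind == "no_join" & best$ev$tolerated,
                         c("i", "j", "reads")]
    res <- list(cluster_id = cluster$cluster_id, status = "validated",
                chosen_subcluster = cluster$member_exon_ids[best$idx],
                support_level = if (min_reads >= 3L) "3SJ" else "1SJ",
                constraints = best$ev, tolerated_joins = tolerated)
  } else {
    joins <- full_ev[full_ev$kind == "no_join", , drop = FALSE]
    hard_join <- any(joins$reads > 0L & !joins$tolerated)
    res <- list(cluster_id = cluster$cluster_id,
                status = if (hard_join) "rejected" else "unresolved",
                chosen_subcluster = character(0), support_level = "none",
                constraints = full_ev,
                tolerated_joins = joins[joins$tolerated,
                                        c("i", "j", "reads")])
  }
  class(res) <- "validation_result"
  res
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("cluster %s: %s (%s)%s\n", x$cluster_id, x$status,
              x$support_level,
              if (length(x$chosen_subcluster))
                paste0(" [", paste(x$chosen_subcluster, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Validate a set of clusters
#'
#' @param clusters list of [mxe_cluster].
#' @inheritParams classify_cluster
#' @return list with `results` (list of `validation_result`) and `table`
#'   (one row per cluster: cluster_id, status, support_level, n_members,
#'   n_chosen, tolerated_joins count).
#' @export
classify_clusters <- function(clusters, sj, min_reads = 3L, strict = FALSE,
                              samples = NULL,
                              frame_rule = c("per_pair", "pair_sum")) {
  frame_rule <- match.arg(frame_rule)
  results <- lapply(clusters, classify_cluster, sj = sj,
                    min_reads = min_reads, strict = strict,
                    samples = samples, frame_rule = frame_rule)
  names(results) <- vapply(results, `[[`, "", "cluster_id")
  table <- do.call(rbind, lapply(results, function(r) data.frame(
    cluster_id = r$cluster_id, status = r$status,
    support_level = r$support_level,
    n_chosen = length(r$chosen_subcluster),
    n_tolerated_joins = nrow(r$tolerated_joins),
    stringsAsFactors = FALSE)))
  rownames(table) <- NULL
  list(results = results, table = table)
}
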