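## Splice-junction tables in STAR SJ.out.tab dialect and a pooled lookup index.

#' Construct a splice-junction index
#'
#' @param df data.frame with columns chrom, start, end (intron interval,
#'   0-based half-open), strand ("+", "-" or "*" for undetermined),
#'   sample_id, unique_reads.
#' @return object of class `sj_index` (a data.frame).
#' @export
sj_index <- function(df = data.frame(chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0),
                                     sample_id = character(0),
                                     unique_reads = integer(0))) {
  need <- c("chrom", "start", "end", "strand", "sample_id", "unique_reads")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  stopifnot(all(df$end > df$start), all(df$unique_reads >= 0))
  class(df) <- c("sj_index", "data.frame")
  df
}

#' Read one STAR SJ.out.tab file
#'
#' Nine whitespace-separated columns: chrom, intron first base (1-based),
#' intron last base (1-based), strand code (0 undefined, 1 +, 2 -), motif
#' code, annotated flag, unique reads, multi-mapping reads, max overhang.
#' Intron intervals are converted to 0-based half-open; only unique reads are
#' kept (multi-mapped reads are ignored); strand code 0 becomes "*" and
#' matches genes on either strand.
#'
#' @param path file path (may be empty).
#' @param sample_id sample label attached to every junction.
#' @return an [sj_index] fragment.
#' @export
read_sj_table <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(sj_index())
  fields <- strsplit(lines, "[ \t]+")
  n_ok <- lengths(fields) == 9L
  if (!all(n_ok))
    stop(sprintf("malformed SJ row at line %d of %s (expected 9 columns)",
                 which(!n_ok)[1], path))
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num))
    stop(sprintf("malformed SJ row at line %d of %s (non-numeric field)",
                 which(apply(num, 1, anyNA))[1], path))
  strand <- c("*", "+", "-")[num[, 3] + 1L]
  if (anyNA(strand))
    stop("invalid strand code in ", path)
  sj_index(data.frame(chrom = m[, 1],
                      start = as.integer(num[, 1]) - 1L,
                      end = as.integer(num[, 2]),
                      strand = strand, sample_id = sample_id,
                      unique_reads = as.integer(num[, 6]),
                      stringsAsFactors = FALSE))
}

#' Read a directory of SJ tables
#'
#' @param paths named character vector (names = sample ids) or a directory;
#'   in a directory every `*.SJ.out.tab` file is read and the sample id is
#'   the file name without that suffix.
#' @return combined [sj_index].
#' @export
read_sj_tables <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.SJ\\.out\\.tab$",
                        full.names = TRUE)
    paths <- setNames(files, sub("\\.SJ\\.out\\.tab$", "", basename(files)))
  }
  parts <- lapply(names(paths), function(s) read_sj_table(paths[[s]], s))
  sj_index(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Write an SJ table in STAR dialect
#'
#' Inverse of [read_sj_table()] for one sample: motif and annotated columns
#' are written as 0, multi-mapping reads as 0, overhang as 50.
#'
#' @param sj an [sj_index].
#' @param path output path.
#' @param sample_id sample to write.
#' @return invisibly, the path.
#' @export
write_sj_table <- function(sj, path, sample_id) {
  s <- sj[sj$sample_id == sample_id, , drop = FALSE]
  s <- s[order(s$chrom, s$start, s$end), , drop = FALSE]
  code <- match(s$strand, c("*", "+", "-")) - 1L
  writeLines(sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t50",
                     s$chrom, s$start + 1L, s$end, code, s$unique_reads),
             path)
  invisible(path)
}

#' Pool junction reads across samples
#'
#' @param sj an [sj_index].
#' @param samples optional subset of sample ids to pool; default all.
#' @return data.frame chrom/start/end/strand/unique_reads with one row per
#'   junction, reads summed over the pooled samples.
#' @export
sj_pool <- function(sj, samples = NULL) {
  if (!is.null(samples)) sj <- sj[sj$sample_id %in% samples, , drop = FALSE]
  if (nrow(sj) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      unique_reads = integer(0)))
  key <- paste(sj$chrom, sj$start, sj$end, sj$strand, sep = "\r")
  tot <- tapply(sj$unique_reads, key, sum)
  parts <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], start = as.integer(parts[, 2]),
                    end = as.integer(parts[, 3]), strand = parts[, 4],
                    unique_reads = as.integer(tot), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

## pooled reads restricted to a cluster's chromosome and compatible strand
## (undetermined junctions match either strand)
sj_for_cluster <- function(pooled, chrom, strand) {
  pooled[pooled$chrom == chrom &
           (pooled$strand == "*" | pooled$strand == strand), , drop = FALSE]
}
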