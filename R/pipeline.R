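## End-to-end orchestration: annotate -> predict -> validate (1SJ and 3SJ)
## -> mechanism -> quantify -> differential -> Gini/delta-PSI -> variants
## -> conservation, with a summary mirroring the candidate accounting.

#' Pipeline run configuration
#'
#' @param gtf,fasta,sj_dir,design required input paths (`sj_dir` may also be
#'   a named vector of SJ files).
#' @param bp_table,variants,tree,presence optional input paths.
#' @param min_score,max_length_difference_aa,min_exon_length_aa prediction
#'   thresholds (see [prediction_params()]).
#' @param strict strict validation mode flag.
#' @param rpkm_gate_pair,rpkm_gate_gini expression gates (median RPKM > 3
#'   for pair analyses; RPKM >= 10 in >= 1 dataset for >= 2 members for the
#'   Gini cluster analysis).
#' @param alpha adjusted-p significance threshold.
#' @param bp_distance,intron_gate steric thresholds.
#' @param predict run the intron-scanning prediction stage (can be switched
#'   off for annotation-only cohorts).
#' @param seed RNG seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(gtf, fasta, sj_dir, design, bp_table = NULL,
                       variants = NULL, tree = NULL, presence = NULL,
                       min_score = 25, max_length_difference_aa = 20L,
                       min_exon_length_aa = 10L, strict = FALSE,
                       rpkm_gate_pair = 3, rpkm_gate_gini = 10,
                       alpha = 0.05, bp_distance = 50L, intron_gate = 500L,
                       predict = TRUE, seed = 1L) {
  stopifnot(min_score > 0, alpha > 0, bp_distance > 0, intron_gate > 0,
            rpkm_gate_pair > 0, rpkm_gate_gini > 0)
  missing_in <- c(gtf, fasta, design)[!file.exists(c(gtf, fasta, design))]
  if (length(missing_in))
    stop("input file does not exist: ", paste(missing_in, collapse = ", "))
  structure(list(gtf = gtf, fasta = fasta, sj_dir = sj_dir, design = design,
                 bp_table = bp_table, variants = variants, tree = tree,
                 presence = presence, min_score = min_score,
                 max_length_difference_aa = max_length_difference_aa,
                 min_exon_length_aa = min_exon_length_aa, strict = strict,
                 rpkm_gate_pair = rpkm_gate_pair,
                 rpkm_gate_gini = rpkm_gate_gini, alpha = alpha,
                 bp_distance = bp_distance, intron_gate = intron_gate,
                 predict = predict, seed = seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs and assembles a summary of
#' candidate counts by class (annotated MXE / other / novel), validation
#' tallies at both support levels, mechanism fractions and differential
#' counts. Any stage failure aborts with the stage name; outputs computed so
#' far are attached to the error condition.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list of class `mxscape_run` with genes, clusters,
#'   validation_1sj/_3sj, mechanisms, psi, differential, gini, delta_psi,
#'   variant analysis, conservation and `summary`.
#' @export
run_all <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out <- list(config = config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial <- out
      stop(cond)
    })
  }

  say("stage annotate")
  out$genes <- stage("annotate",
                     read_annotation(config$gtf, config$fasta))
  genome <- stage("annotate", read_genome(config$fasta))
  annotated <- stage("annotate", {
    cl <- lapply(out$genes, extract_annotated_mxe_candidates)
    out$terminal_candidates <- unlist(lapply(cl, attr,
                                             "terminal_candidates"),
                                      recursive = FALSE)
    cl
  })

  say("stage predict")
  out$clusters <- stage("predict", {
    params <- prediction_params(
      min_exon_length_aa = config$min_exon_length_aa,
      max_length_difference_aa = config$max_length_difference_aa,
      min_score = config$min_score)
    all <- list()
    for (g in names(out$genes)) {
      gene <- out$genes[[g]]
      pred <- if (config$predict)
        predict_mxe_candidates(gene, genome, params)
      else data.frame(search_exon_id = character(0))
      cl <- if (nrow(pred))
        build_candidate_clusters(gene, annotated[[g]], pred)
      else annotated[[g]]
      all <- c(all, cl)
    }
    all
  })

  say("stage validate")
  sj <- stage("validate", {
    paths <- config$sj_dir
    read_sj_tables(paths)
  })
  out$sj <- sj
  ## predicted members with no junction data at all are candidates with
  ## missing evidence, not counter-evidence: set them aside before scoring
  pruned <- stage("validate", prune_unsupported_members(out$clusters, sj))
  out$clusters <- pruned$clusters
  out$set_aside <- pruned$set_aside
  out$validation_1sj <- stage("validate",
    classify_clusters(out$clusters, sj, min_reads = 1L,
                      strict = config$strict))
  out$validation_3sj <- stage("validate",
    classify_clusters(out$clusters, sj, min_reads = 3L,
                      strict = config$strict))

  say("stage mechanism")
  bp <- if (!is.null(config$bp_table)) read_branch_points(config$bp_table)
        else NULL
  out$mechanisms <- stage("mechanism", {
    v1 <- out$validation_1sj
    idx <- which(v1$table$status == "validated")
    calls <- lapply(idx, function(i) {
      cl <- out$clusters[[i]]
      classify_mechanism(cl, v1$results[[cl$cluster_id]],
                         gene = out$genes[[cl$gene_id]], genome = genome,
                         bp_table = bp, max_distance = config$bp_distance,
                         intron_gate = config$intron_gate)
    })
    names(calls) <- vapply(calls, `[[`, "", "cluster_id")
    calls
  })

  say("stage quantify")
  design <- read.table(config$design, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  validated_ids <- out$validation_1sj$table$cluster_id[
    out$validation_1sj$table$status == "validated"]
  vclusters <- Filter(function(c) c$cluster_id %in% validated_ids,
                      out$clusters)
  out$psi <- stage("quantify", psi_matrix(vclusters, sj,
                                          samples = design$sample))
  out$differential <- stage("differential",
    differential_inclusion(out$psi, design, alpha = config$alpha))
  out$gini <- stage("gini", gini_by_exon(out$psi, design))
  out$delta_psi <- stage("delta_psi", {
    dp <- lapply(vclusters, delta_psi, psi = out$psi, design = design,
                 gini_table = out$gini)
    names(dp) <- vapply(vclusters, `[[`, "", "cluster_id")
    Filter(Negate(is.null), dp)
  })

  if (!is.null(config$variants)) {
    say("stage variants")
    out$variants <- stage("variants", {
      v <- read_variant_table(config$variants)
      path <- filter_pathogenic(v)
      exons <- do.call(rbind, lapply(vclusters, `[[`, "members"))
      hit <- intersect_exons(exons, path)
      list(records = v, pathogenic = path, hits = hit$hits,
           exon_flag = hit$exon_flag)
    })
  }

  if (!is.null(config$tree) && !is.null(config$presence)) {
    say("stage conserve")
    out$conservation <- stage("conserve",
      dollo_analysis(config$tree, config$presence))
  }

  out$summary <- pipeline_summary(out)
  class(out) <- "mxscape_run"
  out
}

## Candidate/validation accounting across support levels
pipeline_summary <- function(out) {
  cls_class <- vapply(out$clusters, function(cl) {
    src <- cl$members$splice_class
    if (any(src == "novel")) "novel_exon"
    else if (all(src == "mxe_annotated")) "annotated_mxe"
    else "annotated_other"
  }, "")
  tally <- function(tab) c(validated = sum(tab$status == "validated"),
                           rejected = sum(tab$status == "rejected"),
                           unresolved = sum(tab$status == "unresolved"))
  mech <- if (length(out$mechanisms))
    table(vapply(out$mechanisms, `[[`, "", "label")) else table(character(0))
  list(n_clusters = length(out$clusters),
       candidates_by_class = table(cls_class),
       n_set_aside = if (is.null(out$set_aside)) 0L else
         nrow(out$set_aside$members),
       tally_1sj = tally(out$validation_1sj$table),
       tally_3sj = tally(out$validation_3sj$table),
       mechanism_labels = mech,
       n_differential = sum(out$differential$significant, na.rm = TRUE),
       n_tested = sum(out$differential$tested))
}

#' @export
print.mxscape_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("mxscape run: %d candidate clusters\n", s$n_clusters))
  cat("  by class: ", paste(names(s$candidates_by_class),
                            s$candidates_by_class, sep = "=",
                            collapse = ", "), "\n")
  cat(sprintf("  1SJ: %d validated / %d rejected / %d unresolved\n",
              s$tally_1sj["validated"], s$tally_1sj["rejected"],
              s$tally_1sj["unresolved"]))
  cat(sprintf("  3SJ: %d validated / %d rejected / %d unresolved\n",
              s$tally_3sj["validated"], s$tally_3sj["rejected"],
              s$tally_3sj["unresolved"]))
  if (length(s$mechanism_labels))
    cat("  mechanisms: ", paste(names(s$mechanism_labels),
                                s$mechanism_labels, sep = "=",
                                collapse = ", "), "\n")
  cat(sprintf("  differential inclusion: %d of %d tested exons\n",
              s$n_differential, s$n_tested))
  invisible(x)
}
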