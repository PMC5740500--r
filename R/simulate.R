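## Synthetic cohorts with known ground truth: genomes, annotations, SJ read
## tables, branch-point tables, variant tables and species presence
## matrices, emulating the statistical structure the analysis assumes.

CODONS_BY_AA <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "AGA"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"), M = "ATG",
  F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA"),
  S = c("TCT", "TCC", "TCA"), T = c("ACT", "ACC", "ACA"),
  W = "TGG", Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA"))

random_peptide <- function(n_aa) {
  paste(sample(names(CODONS_BY_AA), n_aa, replace = TRUE), collapse = "")
}

encode_peptide <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) sample(CODONS_BY_AA[[a]], 1L), ""),
        collapse = "")
}

mutate_peptide <- function(pep, divergence) {
  aa <- strsplit(pep, "")[[1]]
  flip <- runif(length(aa)) < divergence
  aa[flip] <- vapply(which(flip), function(i)
    sample(setdiff(names(CODONS_BY_AA), aa[i]), 1L), "")
  paste(aa, collapse = "")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## intron with canonical GT...AG ends; optional planted exonic insert
## (preceded by AG, followed by GT) and optional U12 donor 8-mer
make_intron <- function(len, insert = NULL, u12 = FALSE) {
  donor <- if (u12) "GTATCCTT" else paste0("GT", random_dna(6))
  if (is.null(insert)) {
    body <- random_dna(len - 10L)
    return(list(seq = paste0(donor, body, "AG"), insert_at = NA_integer_))
  }
  pad <- len - 10L - nchar(insert) - 4L
  if (pad < 20L) stop("intron too short for planted insert")
  left <- random_dna(floor(pad / 2))
  right <- random_dna(pad - floor(pad / 2))
  seq <- paste0(donor, left, "AG", insert, "GT", right, "AG")
  list(seq = seq, insert_at = 8L + nchar(left) + 2L)  # 0-based offset
}

## Dirichlet draw via gamma variates
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-6), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulation configuration
#'
#' Defaults describe a small desk-scale cohort: clusters of 2-5 members,
#' four conditions with three replicates, 30 reads per cluster per sample,
#' noise-free splicing. Cluster classes: `mxe` (frame-compatible, lengths
#' divisible by three), `mxe_frameshift` (member lengths not divisible by
#' three, occasional joining reads that the frame-shift rule must tolerate),
#' `mxe_u12` (a minor-spliceosome donor planted on the intron preceding the
#' cluster), `mxe_novel` (a single annotated exon with a divergent copy
#' planted in its downstream intron, to be recovered by prediction),
#' `cassette` (two neighbouring exons annotated in separate transcripts but
#' expressed jointly, i.e. joining reads) and `constitutive`.
#'
#' @param seed RNG seed; fixes all outputs bit-for-bit.
#' @param n_genes number of genes.
#' @param class_fractions named fractions over the classes above (sum 1).
#' @param cluster_size_probs distribution over cluster sizes 2-5 (classes
#'   other than `mxe`/`mxe_frameshift` use size 2, `mxe_novel` size 2 after
#'   prediction).
#' @param exon_length_aa range of member peptide lengths.
#' @param intron_length range of intron lengths (nt); values below 500
#'   exercise the short-intron branch-point logic.
#' @param aa_divergence amino-acid substitution rate between cluster members.
#' @param depth expected junction reads per cluster per sample.
#' @param conditions,replicates design dimensions.
#' @param psi_concentration Dirichlet concentration of per-sample PSI around
#'   the condition profile (larger = less sampling noise).
#' @param default_psi baseline inclusion of the default member.
#' @param regulated_fraction fraction of MXE clusters with a
#'   condition-dependent ("default + regulated") profile; the rest keep one
#'   constant profile across conditions (nulls for differential testing).
#' @param noise_rate probability that a mis-splicing joining read is emitted
#'   for a true MXE pair, per sample and member pair.
#' @param frameshift_join_rate probability of a (tolerated) joining read per
#'   sample for `mxe_frameshift` clusters.
#' @param steric_rate fraction of MXE clusters with a branch point planted
#'   within 50 bp of a donor in a short intron.
#' @param variant_rate fraction of MXE clusters carrying a planted
#'   pathogenic SNV; benign and structural decoys are added alongside.
#' @param n_species,species_loss_rate,unknown_rate presence-matrix
#'   generation over a balanced species tree.
#' @param class_sequence optional explicit class per gene (overrides
#'   `class_fractions`).
#' @param cluster_sizes optional explicit cluster size per gene.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 20L,
                              class_fractions = c(mxe = 0.35,
                                                  mxe_frameshift = 0.10,
                                                  mxe_u12 = 0.10,
                                                  mxe_novel = 0.15,
                                                  cassette = 0.15,
                                                  constitutive = 0.15),
                              cluster_size_probs = c(`2` = 0.6, `3` = 0.2,
                                                     `4` = 0.15, `5` = 0.05),
                              exon_length_aa = c(15L, 40L),
                              intron_length = c(250L, 900L),
                              aa_divergence = 0.15,
                              depth = 30L, conditions = 4L, replicates = 3L,
                              psi_concentration = 60,
                              default_psi = 0.7,
                              regulated_fraction = 1.0,
                              noise_rate = 0,
                              frameshift_join_rate = 0.5,
                              steric_rate = 0.2,
                              variant_rate = 0.25,
                              n_species = 8L, species_loss_rate = 0.15,
                              unknown_rate = 0.05,
                              class_sequence = NULL,
                              cluster_sizes = NULL) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8,
            all(class_fractions >= 0),
            noise_rate >= 0, noise_rate <= 1,
            regulated_fraction >= 0, regulated_fraction <= 1,
            depth > 0, conditions >= 2, replicates >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

## condition x member PSI profiles ("default + regulated" structure)
make_psi_profiles <- function(k, conditions, default_psi, regulated) {
  base <- c(default_psi, rep((1 - default_psi) / (k - 1), k - 1L))
  prof <- matrix(rep(base, conditions), nrow = conditions, byrow = TRUE)
  if (regulated && k >= 2L) {
    for (j in 2:k) {
      cj <- ((j - 2L) %% conditions) + 1L     # home condition of member j
      w <- rep(0.25 / max(k - 2L, 1L), k)
      if (k == 2L) w[] <- 0
      w[1] <- 0.35
      w[j] <- if (k == 2L) 0.65 else 0.4
      prof[cj, ] <- w / sum(w)
    }
  }
  prof
}

#' Generate a synthetic cohort
#'
#' Writes a complete input bundle to `out_dir`: `genome.fa`,
#' `annotation.gtf`, one `<sample>.SJ.out.tab` per sample under `sj/`,
#' `design.tsv`, `branch_points.tsv`, `variants.tsv`, `species_tree.nwk`,
#' `presence_matrix.tsv`, `exon_counts.tsv` and `truth_clusters.tsv`.
#' MXE clusters emit bridging junction reads per member with multinomial
#' proportions from the planted PSI profile and no joining reads except at
#' the configured noise rate; cassette clusters additionally emit joining
#' reads between neighbours at high rate; constitutive exons emit adjacent
#' junctions only. Cluster member sequences are divergent copies of one
#' another. The same seed reproduces every file byte-identically.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `dir`, `paths` (named file paths), `truth` (clusters
#'   data.frame, psi profiles, variants, presence origins) and `config`.
#' @export
generate_cohort <- function(config, out_dir = tempfile("mxcohort")) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "sj"), showWarnings = FALSE)

  classes <- config$class_sequence %||% sample(
    names(config$class_fractions), config$n_genes, replace = TRUE,
    prob = config$class_fractions)
  n_genes <- length(classes)
  sizes <- config$cluster_sizes %||% vapply(classes, function(cl) {
    if (cl %in% c("mxe", "mxe_frameshift", "mxe_u12"))
      as.integer(sample(names(config$cluster_size_probs), 1L,
                        prob = config$cluster_size_probs))
    else 2L
  }, integer(1))

  samples <- paste0("cond", rep(seq_len(config$conditions),
                                each = config$replicates), "_rep",
                    rep(seq_len(config$replicates), config$conditions))
  design <- data.frame(sample = samples,
                       condition = paste0("cond",
                                          rep(seq_len(config$conditions),
                                              each = config$replicates)),
                       replicate = rep(seq_len(config$replicates),
                                       config$conditions),
                       stringsAsFactors = FALSE)

  chrom <- "chr1"
  cursor <- 0L
  genome_parts <- character(0)
  gtf_rows <- list()      # per transcript exon rows
  sj_rows <- list()
  bp_rows <- list()
  var_rows <- list()
  truth_rows <- list()
  truth_profiles <- list()
  exon_count_rows <- list()

  emit_sj <- function(sample, start, end, reads) {
    if (reads > 0L)
      sj_rows[[length(sj_rows) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end, strand = "+",
        sample_id = sample, unique_reads = as.integer(reads))
  }
  pad <- function(n) {
    genome_parts[[length(genome_parts) + 1L]] <<- random_dna(n)
    cursor <<- cursor + n
  }
  place <- function(seq) {
    start <- cursor
    genome_parts[[length(genome_parts) + 1L]] <<- seq
    cursor <<- cursor + nchar(seq)
    c(start, cursor)
  }

  for (gi in seq_len(n_genes)) {
    gene_id <- sprintf("G%03d", gi)
    cls <- classes[gi]
    k <- if (cls %in% c("constitutive", "mxe_novel")) 1L
         else if (cls == "cassette") 2L
         else sizes[gi]
    pad(500L)

    flankA_aa <- sample(20:40, 1L)
    flankB_aa <- sample(20:40, 1L)
    member_aa <- sample(config$exon_length_aa[1]:config$exon_length_aa[2], 1L)
    pep1 <- random_peptide(member_aa)
    peps <- c(pep1, vapply(seq_len(max(k - 1L, 0L)), function(.)
      mutate_peptide(pep1, config$aa_divergence), ""))
    member_seqs <- vapply(peps[seq_len(k)], encode_peptide, "")
    if (cls == "mxe_frameshift")
      member_seqs <- paste0(member_seqs, "G")   # lengths = 1 mod 3

    flankA <- encode_peptide(random_peptide(flankA_aa))
    flankB <- encode_peptide(random_peptide(flankB_aa))
    ilen <- function() sample(config$intron_length[1]:config$intron_length[2], 1L)

    ## planted novel copy lives in the intron after the single member
    novel_insert <- if (cls == "mxe_novel")
      encode_peptide(mutate_peptide(pep1, config$aa_divergence)) else NULL

    steric_here <- cls %in% c("mxe", "mxe_frameshift", "mxe_u12") &&
      runif(1) < config$steric_rate

    ## assemble gene left to right: flankA, introns/members..., flankB
    a_iv <- place(flankA)
    intr <- make_intron(ilen(), u12 = cls == "mxe_u12")
    i0_iv <- place(intr$seq)
    member_iv <- matrix(0L, nrow = k, ncol = 2)
    novel_iv <- NULL
    for (j in seq_len(k)) {
      member_iv[j, ] <- place(member_seqs[j])
      last <- j == k
      short <- steric_here && j == 1L && k >= 1L
      len_j <- if (short) 300L else ilen()
      ins <- if (last && !is.null(novel_insert)) novel_insert else NULL
      intr_j <- make_intron(len_j, insert = ins)
      iv <- place(intr_j$seq)
      if (!is.null(ins))
        novel_iv <- c(iv[1] + intr_j$insert_at,
                      iv[1] + intr_j$insert_at + nchar(ins))
      ## branch-point entry for short introns
      if (len_j < 500L) {
        bp_off <- if (short) sample(20:45, 1L)
                  else len_j - sample(25:40, 1L)
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          chrom = chrom, intron_start = iv[1], intron_end = iv[2],
          bp_pos = iv[1] + bp_off, score = 1, stringsAsFactors = FALSE)
      }
    }
    b_iv <- place(flankB)

    exon_line <- function(tx, iv, src = "annotated") data.frame(
      gene = gene_id, tx = tx, start = iv[1], end = iv[2], source = src,
      stringsAsFactors = FALSE)
    if (cls == "constitutive") {
      tx <- paste0(gene_id, ".t1")
      gtf_rows[[length(gtf_rows) + 1L]] <- rbind(
        exon_line(tx, a_iv), exon_line(tx, member_iv[1, ]),
        exon_line(tx, b_iv))
    } else if (cls == "mxe_novel") {
      tx <- paste0(gene_id, ".t1")
      gtf_rows[[length(gtf_rows) + 1L]] <- rbind(
        exon_line(tx, a_iv), exon_line(tx, member_iv[1, ]),
        exon_line(tx, b_iv))
    } else {
      ## one transcript per member (cassette pairs look mutually exclusive
      ## in the annotation; the reads reveal joint inclusion)
      for (j in seq_len(k)) {
        tx <- sprintf("%s.t%d", gene_id, j)
        gtf_rows[[length(gtf_rows) + 1L]] <- rbind(
          exon_line(tx, a_iv), exon_line(tx, member_iv[j, ]),
          exon_line(tx, b_iv))
      }
    }

    ## --- read emission ----------------------------------------------------
    members_all <- if (cls == "mxe_novel") rbind(member_iv, novel_iv)
                   else member_iv
    k_eff <- nrow(members_all)
    regulated <- cls != "constitutive" &&
      runif(1) < config$regulated_fraction
    prof <- if (cls == "constitutive") NULL
            else make_psi_profiles(k_eff, config$conditions,
                                   config$default_psi, regulated)
    for (si in seq_len(nrow(design))) {
      sm <- design$sample[si]
      ci <- as.integer(sub("cond", "", design$condition[si]))
      if (cls == "constitutive") {
        r <- rpois(1, config$depth)
        emit_sj(sm, a_iv[2], member_iv[1, 1], r)
        emit_sj(sm, member_iv[1, 2], b_iv[1], r)
        exon_count_rows[[length(exon_count_rows) + 1L]] <- data.frame(
          gene = gene_id, exon_start = member_iv[1, 1],
          exon_end = member_iv[1, 2], sample = sm, reads = 2L * r)
        next
      }
      if (cls == "cassette") {
        n_both <- rpois(1, config$depth * 0.6)
        n_x <- rpois(1, config$depth * 0.2)
        n_y <- rpois(1, config$depth * 0.2)
        emit_sj(sm, a_iv[2], members_all[1, 1], n_both + n_x)
        emit_sj(sm, members_all[1, 2], members_all[2, 1], n_both)  # joining
        emit_sj(sm, members_all[2, 2], b_iv[1], n_both + n_y)
        emit_sj(sm, members_all[1, 2], b_iv[1], n_x)    # skip Y
        emit_sj(sm, a_iv[2], members_all[2, 1], n_y)    # skip X
        next
      }
      p <- rdirichlet1(config$psi_concentration * prof[ci, ])
      r <- as.integer(rmultinom(1, config$depth, p))
      for (j in seq_len(k_eff)) {
        emit_sj(sm, a_iv[2], members_all[j, 1], r[j])
        emit_sj(sm, members_all[j, 2], b_iv[1], r[j])
        exon_count_rows[[length(exon_count_rows) + 1L]] <- data.frame(
          gene = gene_id, exon_start = members_all[j, 1],
          exon_end = members_all[j, 2], sample = sm, reads = 2L * r[j])
      }
      join_rate <- if (cls == "mxe_frameshift") config$frameshift_join_rate
                   else config$noise_rate
      if (join_rate > 0 && k_eff >= 2L) {
        for (a in seq_len(k_eff - 1L)) for (b in (a + 1L):k_eff) {
          if (rbinom(1, 1, join_rate) == 1L)
            emit_sj(sm, members_all[a, 2], members_all[b, 1], 1L)
        }
      }
    }

    ## --- planted variants -------------------------------------------------
    if (cls %in% c("mxe", "mxe_frameshift", "mxe_u12", "mxe_novel") &&
        runif(1) < config$variant_rate) {
      pos <- members_all[1, 1] + sample.int(
        members_all[1, 2] - members_all[1, 1], 1L) - 1L
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos + 1L, ref = "A", alt = "G",
        clinical_significance = "Pathogenic", variant_type = "SNV",
        gene = gene_id, stringsAsFactors = FALSE)
      if (k_eff >= 2L) {
        pos2 <- members_all[2, 1] + sample.int(
          members_all[2, 2] - members_all[2, 1], 1L) - 1L
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = chrom, pos = pos2 + 1L, ref = "C", alt = "T",
          clinical_significance = "Benign/Likely benign",
          variant_type = "SNV", gene = gene_id, stringsAsFactors = FALSE)
      }
    }

    ## --- truth ------------------------------------------------------------
    if (cls != "constitutive") {
      member_str <- paste(sprintf("%s:%d-%d", chrom, members_all[, 1],
                                  members_all[, 2]), collapse = ",")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = gene_id, class = cls, n_members = k_eff,
        members = member_str,
        frame_nmd = cls == "mxe_frameshift",
        u12 = cls == "mxe_u12", steric = steric_here,
        regulated = regulated, stringsAsFactors = FALSE)
      if (!is.null(prof))
        truth_profiles[[gene_id]] <- prof
    }
    pad(300L)
  }
  pad(500L)

  ## --- species tree and presence matrix -----------------------------------
  n_sp <- config$n_species
  sp <- paste0("sp", seq_len(n_sp))
  build_nwk <- function(labels) {
    if (length(labels) == 1L) return(labels)
    h <- length(labels) %/% 2L
    paste0("(", build_nwk(labels[1:h]), ",",
           build_nwk(labels[(h + 1L):length(labels)]), ")")
  }
  nwk <- paste0(build_nwk(sp), ";")
  tree <- ape::read.tree(text = nwk)
  truth_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(0), class = character(0))
  mx_rows <- truth_df[grepl("^mxe", truth_df$class), , drop = FALSE]
  presence <- NULL
  origins <- NULL
  if (nrow(mx_rows)) {
    internal_nodes <- (n_sp + 1L):(n_sp + tree$Nnode)
    presence <- matrix("0", nrow = nrow(mx_rows), ncol = n_sp,
                       dimnames = list(mx_rows$gene_id, sp))
    origins <- setNames(integer(nrow(mx_rows)), mx_rows$gene_id)
    desc_tips <- function(node) {
      if (node <= n_sp) return(node)
      unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], desc_tips))
    }
    for (r in seq_len(nrow(mx_rows))) {
      org <- sample(internal_nodes, 1L)
      origins[r] <- org
      tips <- desc_tips(org)
      pres <- rep("1", length(tips))
      pres[runif(length(tips)) < config$species_loss_rate] <- "0"
      if (all(pres == "0")) pres[1] <- "1"
      presence[r, tips] <- pres
      unk <- runif(n_sp) < config$unknown_rate
      presence[r, unk] <- "?"
      if (!any(presence[r, ] == "1"))
        presence[r, tips[1]] <- "1"
    }
  }

  ## --- write files ---------------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    sj_dir = file.path(out_dir, "sj"),
    design = file.path(out_dir, "design.tsv"),
    branch_points = file.path(out_dir, "branch_points.tsv"),
    variants = file.path(out_dir, "variants.tsv"),
    tree = file.path(out_dir, "species_tree.nwk"),
    presence = file.path(out_dir, "presence_matrix.tsv"),
    exon_counts = file.path(out_dir, "exon_counts.tsv"),
    truth = file.path(out_dir, "truth_clusters.tsv"))

  genome <- Biostrings::DNAStringSet(setNames(
    paste(genome_parts, collapse = ""), chrom))
  Biostrings::writeXStringSet(genome, paths$genome)

  gtf <- do.call(rbind, gtf_rows)
  writeLines(sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    chrom, gtf$source, gtf$start + 1L, gtf$end, gtf$gene, gtf$tx),
    paths$gtf)

  sj_all <- if (length(sj_rows))
    sj_index(do.call(rbind, sj_rows)) else sj_index()
  ## merge duplicate junction rows per sample before writing
  if (nrow(sj_all)) {
    key <- paste(sj_all$chrom, sj_all$start, sj_all$end, sj_all$strand,
                 sj_all$sample_id, sep = "\r")
    tot <- tapply(sj_all$unique_reads, key, sum)
    parts <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
    sj_all <- sj_index(data.frame(
      chrom = parts[, 1], start = as.integer(parts[, 2]),
      end = as.integer(parts[, 3]), strand = parts[, 4],
      sample_id = parts[, 5], unique_reads = as.integer(tot),
      stringsAsFactors = FALSE))
  }
  for (sm in samples)
    write_sj_table(sj_all, file.path(paths$sj_dir,
                                     paste0(sm, ".SJ.out.tab")), sm)

  write.table(design, paths$design, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bp <- if (length(bp_rows)) do.call(rbind, bp_rows) else
    data.frame(chrom = character(0), intron_start = integer(0),
               intron_end = integer(0), bp_pos = integer(0),
               score = numeric(0))
  write_branch_points(bp, paths$branch_points)
  vars <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), clinical_significance = character(0),
               variant_type = character(0), gene = character(0))
  write.table(vars, paths$variants, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(nwk, paths$tree)
  if (!is.null(presence)) {
    pm <- data.frame(cluster_id = rownames(presence), presence,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(pm, paths$presence, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else writeLines("cluster_id", paths$presence)
  ec <- if (length(exon_count_rows)) do.call(rbind, exon_count_rows) else
    data.frame(gene = character(0), exon_start = integer(0),
               exon_end = integer(0), sample = character(0),
               reads = integer(0))
  write.table(ec, paths$exon_counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(dir = out_dir, paths = paths,
       truth = list(clusters = truth_df, profiles = truth_profiles,
                    variants = vars, origins = origins,
                    presence = presence, design = design),
       config = config)
}

#' Deterministic miniature worked fixture
#'
#' A five-gene cohort used by the documentation examples: one 2-exon MXE
#' cluster, one 4-exon MXE cluster, one cassette pair, one
#' frame-shift-tolerated cluster and one cluster behind a planted
#' minor-spliceosome donor. Identical on every platform.
#'
#' @param out_dir output directory.
#' @return see [generate_cohort()].
#' @export
generate_worked_fixture <- function(out_dir = tempfile("mxfixture")) {
  cfg <- simulation_config(
    seed = 42L, n_genes = 5L,
    class_sequence = c("mxe", "mxe", "cassette", "mxe_frameshift",
                       "mxe_u12"),
    cluster_sizes = c(2L, 4L, 2L, 2L, 2L),
    noise_rate = 0, steric_rate = 0, variant_rate = 1,
    conditions = 3L, replicates = 2L)
  generate_cohort(cfg, out_dir)
}
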