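# Planted-truth simulator: genome, annotation, repeats, reads, PAR-CLIP
# transitions and expression/interaction tables.
#
# The generator states a small but complete world: ~20 genes on one
# chromosome, each with GT/AG splice signals written on the gene strand;
# planted circRNAs over runs of internal exons with NB-distributed,
# batch-structured back-splice junction read counts; inverted / co-oriented
# Alu pairs in the 1-kb flanking introns; A-to-I editing at Alu adenosines;
# T-to-C transition events in bound flanks; miRNA response elements written
# into circularised exons (including junction-spanning ones); and downstream
# mRNA/protein fold-change and miRNA-interaction tables with planted
# responder targets.  Everything downstream is computable from the returned
# ground truth, which the test suite uses as its oracle.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic world.  Defaults
#' are the package's stated desk-scale conditions (see the methods vignette);
#' an identical configuration (including `seed`) yields byte-identical
#' outputs.
#'
#' @param seed integer RNG seed
#' @param n_genes number of genes
#' @param exons_per_gene integer range (min, max) of exons per gene
#' @param exon_len,intron_len integer ranges in nt
#' @param n_circ number of planted circRNAs (decoys are extra)
#' @param circ_abundance mean BSJ read pairs per junction per sample
#' @param n_samples_per_condition replicates per condition (WT, MUT)
#' @param n_batches number of experiment batches
#' @param nb_dispersion NB dispersion of all simulated counts
#' @param planted_lfc per-circRNA condition log2 fold change, recycled
#' @param read_len,frag_len read and fragment length (nt); frag_len >= read_len
#' @param alu_len Alu element length (nt)
#' @param editing_rate per-site A-to-I editing probability within Alus
#' @param transition_density T-to-C events per kb in bound flanks
#' @param background_transition_density background T-to-C events per kb
#' @param adapter_frac fraction of linear fragments with adapter read-through
#' @param dup_frac fraction of exact duplicate pairs appended
#' @param alu_coverage target read depth over Alu elements (pre-mRNA stand-in)
#' @param gene_abundance mean linear fragments per gene per sample
#' @param n_mirnas number of simulated mature miRNAs
#' @param n_decoys number of decoy junctions with AT..AC signals
#' @param n_noncoding number of non-coding host genes
#' @param intergenic_len spacer between genes (nt)
#' @param adapter adapter sequence for read-through simulation
#' @param max_mm mismatch budget assumed by the detector
#' @return object of class `circfus_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(4L, 8L),
                       exon_len = c(150L, 400L),
                       intron_len = c(2800L, 4000L),
                       n_circ = 15L,
                       circ_abundance = 20,
                       n_samples_per_condition = 3L,
                       n_batches = 3L,
                       nb_dispersion = 0.1,
                       planted_lfc = c(-2, 0, 2),
                       read_len = 100L,
                       frag_len = 250L,
                       alu_len = 300L,
                       editing_rate = 0.1,
                       transition_density = 5,
                       background_transition_density = 0.05,
                       adapter_frac = 0.05,
                       dup_frac = 0.05,
                       alu_coverage = 15,
                       gene_abundance = 250,
                       n_mirnas = 8L,
                       n_decoys = 2L,
                       n_noncoding = 2L,
                       intergenic_len = 2000L,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       max_mm = 2L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_circ = as.integer(n_circ),
              circ_abundance = circ_abundance,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_batches = as.integer(n_batches),
              nb_dispersion = nb_dispersion,
              planted_lfc = rep_len(planted_lfc, n_circ),
              read_len = as.integer(read_len),
              frag_len = as.integer(frag_len),
              alu_len = as.integer(alu_len),
              editing_rate = editing_rate,
              transition_density = transition_density,
              background_transition_density = background_transition_density,
              adapter_frac = adapter_frac, dup_frac = dup_frac,
              alu_coverage = alu_coverage, gene_abundance = gene_abundance,
              n_mirnas = as.integer(n_mirnas),
              n_decoys = as.integer(n_decoys),
              n_noncoding = as.integer(n_noncoding),
              intergenic_len = as.integer(intergenic_len),
              adapter = adapter, max_mm = as.integer(max_mm))
  counts <- c("n_genes", "n_circ", "n_samples_per_condition", "n_batches",
              "read_len", "frag_len", "alu_len", "intergenic_len")
  for (f in counts)
    if (cfg[[f]] <= 0) stop("configuration error: ", f, " must be positive")
  for (f in c("editing_rate", "adapter_frac", "dup_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0,1]")
  if (cfg$frag_len < cfg$read_len)
    stop("configuration error: frag_len must be >= read_len")
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be positive")
  if (cfg$exons_per_gene[1] < 3)
    stop("configuration error: genes need >= 3 exons for internal exons")
  if (cfg$n_genes < cfg$n_circ + cfg$n_decoys)
    stop("configuration error: need one host gene per (decoy) circRNA")
  class(cfg) <- "circfus_config"
  cfg
}

# sample uniformly from an inclusive integer range given as c(lo, hi)
sample_range <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

#' Generate the synthetic reference: genome, annotation, Alus, ground truth
#'
#' Writes the stated world: every gene has >= 3 exons; every planted
#' circularised region is preceded by an AG acceptor and followed by a GT
#' donor on the gene strand (decoys carry AT..AC instead); downregulated
#' circRNAs carry an inverted Alu pair within 1 kb of the circularised exons,
#' upregulated ones a co-oriented pair; miRNA response elements (including
#' junction-spanning ones) are written into sponge circRNAs.
#'
#' @param config a [sim_config()] object
#' @return list with `genome` (named character), `model` (gene model),
#'   `alus` (BED-style data.frame) and `truth` (class `circfus_truth`)
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "circfus_config"))
  if ((config$n_circ > 0 || config$n_decoys > 0) &&
      config$intron_len[1] < 2L * config$alu_len + 2000L)
    stop("configuration error: intron_len must be >= 2*alu_len + 2 kb ",
         "when flanking Alus are requested")
  set.seed(config$seed)
  n_all_circ <- config$n_circ + config$n_decoys

  ## ---- gene skeletons ------------------------------------------------------
  genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample_range(config$exons_per_gene)
    genes[[g]] <- list(
      gene_id = sprintf("gene_%02d", g),
      tx_id = sprintf("tx_%02d", g),
      strand = sample(c("+", "-"), 1),
      n_ex = n_ex,
      exon_len = sample_range(config$exon_len, n_ex),
      intron_len = sample_range(config$intron_len, n_ex - 1),
      biotype = "protein_coding")
  }
  if (config$n_noncoding > 0) {
    nc <- seq(config$n_genes - config$n_noncoding + 1L, config$n_genes)
    nc <- setdiff(nc, seq_len(n_all_circ))  # never a circ host
    for (g in nc) genes[[g]]$biotype <- "lincRNA"
  }

  ## ---- circRNA placement ---------------------------------------------------
  circs <- NULL
  lfc <- c(config$planted_lfc, rep(0, config$n_decoys))
  for (k in seq_len(n_all_circ)) {
    gi <- genes[[k]]
    n_run <- sample_range(c(1L, min(3L, gi$n_ex - 2L)))
    first <- sample_range(c(2L, gi$n_ex - n_run))
    # a fragment must not wrap the circle more than once
    while (sum(gi$exon_len[first:(first + n_run - 1L)]) <
             config$frag_len + 30L) {
      if (first + n_run - 1L < gi$n_ex - 1L) n_run <- n_run + 1L
      else if (first > 2L) { first <- first - 1L; n_run <- n_run + 1L }
      else stop("simulation error: gene too small to host a circRNA")
    }
    circs <- rbind(circs, data.frame(
      circ_id = sprintf("circ_%02d", k),
      gene_id = gi$gene_id, tx_id = gi$tx_id,
      first_exon = first, last_exon = first + n_run - 1L,
      n_exons = n_run,
      lfc = lfc[k],
      decoy = k > config$n_circ))
  }
  down <- which(!circs$decoy & circs$lfc < 0)
  up <- which(!circs$decoy & circs$lfc > 0)
  sponges <- head(down, 3)
  circs$cytoplasmic <- FALSE
  circs$cytoplasmic[!circs$decoy] <-
    rep(c(TRUE, FALSE), length.out = sum(!circs$decoy))
  circs$cytoplasmic[sponges] <- TRUE
  concordant_circ <- if (length(down) > 3) tail(down, 1) else integer(0)

  ## ---- raw sequences (gene-strand space) -----------------------------------
  for (g in seq_len(config$n_genes)) {
    gi <- genes[[g]]
    ex_seq <- vapply(gi$exon_len, random_dna, character(1))
    in_seq <- vapply(gi$intron_len, random_dna, character(1))
    for (i in seq_along(in_seq)) {
      substr(in_seq[i], 1, 2) <- "GT"
      substr(in_seq[i], gi$intron_len[i] - 1L, gi$intron_len[i]) <- "AG"
    }
    genes[[g]]$ex_seq <- ex_seq
    genes[[g]]$in_seq <- in_seq
  }

  # decoy junction signals: AT donor after last circ exon, AC acceptor before
  # the first circ exon (gene-strand orientation)
  for (k in which(circs$decoy)) {
    g <- match(circs$gene_id[k], vapply(genes, `[[`, "", "gene_id"))
    fi <- circs$first_exon[k]; la <- circs$last_exon[k]
    substr(genes[[g]]$in_seq[la], 1, 2) <- "AT"
    ilen <- genes[[g]]$intron_len[fi - 1L]
    substr(genes[[g]]$in_seq[fi - 1L], ilen - 1L, ilen) <- "AC"
  }

  ## ---- miRNAs and planted response elements --------------------------------
  mirnas <- setNames(vapply(rep(21L, config$n_mirnas), random_dna,
                            character(1)),
                     sprintf("miR-%d", seq_len(config$n_mirnas)))
  planted_sites <- NULL
  plant_body_site <- function(g, exon, offset, mir) {
    site <- revcomp(mirnas[[mir]])
    genes[[g]]$ex_seq[exon] <<-
      seq_replace(genes[[g]]$ex_seq[exon], offset, site)
  }
  plant_bsj_site <- function(g, first, last, mir, k = 10L) {
    site <- revcomp(mirnas[[mir]])
    n <- nchar(site)
    llen <- nchar(genes[[g]]$ex_seq[last])
    genes[[g]]$ex_seq[last] <<-
      seq_replace(genes[[g]]$ex_seq[last], llen - k + 1L, substr(site, 1, k))
    genes[[g]]$ex_seq[first] <<-
      seq_replace(genes[[g]]$ex_seq[first], 1L, substr(site, k + 1L, n))
  }
  if (length(sponges) >= 3 && config$n_mirnas >= 4) {
    gid <- vapply(genes, `[[`, "", "gene_id")
    s1 <- sponges[1]; s2 <- sponges[2]; s3 <- sponges[3]
    g1 <- match(circs$gene_id[s1], gid)
    g2 <- match(circs$gene_id[s2], gid)
    g3 <- match(circs$gene_id[s3], gid)
    # circ 1: two body sites for miR-1, one lone body site for miR-4
    plant_body_site(g1, circs$first_exon[s1], 40L, "miR-1")
    plant_body_site(g1, circs$last_exon[s1], 80L, "miR-1")
    plant_body_site(g1, circs$first_exon[s1], 70L, "miR-4")
    # circ 2: one BSJ-spanning site for miR-1 (shared miRNA motif) and two
    # body sites for miR-2
    plant_bsj_site(g2, circs$first_exon[s2], circs$last_exon[s2], "miR-1")
    plant_body_site(g2, circs$first_exon[s2], 50L, "miR-2")
    plant_body_site(g2, circs$last_exon[s2], 60L, "miR-2")
    # circ 3: one BSJ-spanning site for miR-3
    plant_bsj_site(g3, circs$first_exon[s3], circs$last_exon[s3], "miR-3")
    planted_sites <- data.frame(
      circ_id = circs$circ_id[c(s1, s1, s2, s2, s3)],
      mirna = c("miR-1", "miR-4", "miR-1", "miR-2", "miR-3"),
      n_sites = c(2L, 1L, 1L, 2L, 1L),
      bsj_spanning = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  }

  ## ---- Alu elements (gene-strand bookkeeping, genomic emission later) ------
  # inverted pairs flank downregulated circRNAs, co-oriented pairs flank
  # upregulated ones; a few lone background Alus elsewhere
  alu_plan <- NULL
  add_alu_pair <- function(k, inverted) {
    up_sense <- sample(c(TRUE, FALSE), 1)
    dn_sense <- if (inverted) !up_sense else up_sense
    rbind(data.frame(circ_row = k, side = "up", sense = up_sense),
          data.frame(circ_row = k, side = "down", sense = dn_sense))
  }
  for (k in down) alu_plan <- rbind(alu_plan, add_alu_pair(k, TRUE))
  for (k in up) alu_plan <- rbind(alu_plan, add_alu_pair(k, FALSE))

  ## ---- assemble the chromosome ---------------------------------------------
  chrom <- "chr1"
  gene_rows <- NULL; exon_rows <- NULL
  gene_seq_plus <- character(config$n_genes)
  gene_start <- integer(config$n_genes)
  pos <- 1L
  alus <- NULL; alu_idx <- 0L
  gid_vec <- vapply(genes, `[[`, "", "gene_id")
  for (g in seq_len(config$n_genes)) {
    gi <- genes[[g]]
    # gene-strand offsets of exons
    pieces <- character(2L * gi$n_ex - 1L)
    pieces[seq(1, length(pieces), by = 2)] <- gi$ex_seq
    if (gi$n_ex > 1) pieces[seq(2, length(pieces), by = 2)] <- gi$in_seq
    piece_len <- nchar(pieces)
    piece_off <- cumsum(c(0L, piece_len[-length(piece_len)]))
    ex_off <- piece_off[seq(1, length(pieces), by = 2)] + 1L
    gene_len <- sum(piece_len)
    gseq <- paste(pieces, collapse = "")

    # plant flanking Alus for circRNAs hosted here (gene-strand coords)
    rows <- which(circs$gene_id == gi$gene_id)
    for (k in rows) {
      if (is.null(alu_plan)) next
      plan <- alu_plan[alu_plan$circ_row == k, , drop = FALSE]
      if (!nrow(plan)) next
      body_start_g <- ex_off[circs$first_exon[k]]
      body_end_g <- ex_off[circs$last_exon[k]] +
        gi$exon_len[circs$last_exon[k]] - 1L
      for (j in seq_len(nrow(plan))) {
        # stay inside the 1-kb flank but clear of the GT/AG signal bases
        win <- if (plan$side[j] == "up")
          c(body_start_g - 1000L, body_start_g - 3L - config$alu_len)
        else c(body_end_g + 3L, body_end_g + 1001L - config$alu_len)
        a_start <- win[1] + sample.int(win[2] - win[1] + 1L, 1) - 1L
        alu_idx <- alu_idx + 1L
        aseq <- random_dna(config$alu_len)
        ins <- if (plan$sense[j]) aseq else revcomp(aseq)
        gseq <- seq_replace(gseq, a_start, ins)
        g_strand <- gi$strand
        alu_strand <- if (plan$sense[j]) g_strand else
          c("+" = "-", "-" = "+")[[g_strand]]
        alus <- rbind(alus, data.frame(
          alu_id = sprintf("alu_%02d", alu_idx), gene_row = g,
          gstart = a_start, gend = a_start + config$alu_len - 1L,
          strand = alu_strand, rate = config$editing_rate,
          circ_id = circs$circ_id[k], side = plan$side[j]))
      }
    }
    # a lone background Alu in the first intron of some non-host genes
    if (g > n_all_circ && gi$n_ex >= 2 && (g %% 4L) == 0L) {
      alu_idx <- alu_idx + 1L
      a_start <- ex_off[1] + gi$exon_len[1] + 400L
      aseq <- random_dna(config$alu_len)
      gseq <- seq_replace(gseq, a_start, aseq)
      alus <- rbind(alus, data.frame(
        alu_id = sprintf("alu_%02d", alu_idx), gene_row = g,
        gstart = a_start, gend = a_start + config$alu_len - 1L,
        strand = gi$strand, rate = config$editing_rate,
        circ_id = NA_character_, side = NA_character_))
    }

    gene_start[g] <- pos + config$intergenic_len
    gene_seq_plus[g] <- if (gi$strand == "+") gseq else revcomp(gseq)
    genes[[g]]$gene_len <- gene_len
    genes[[g]]$ex_off <- ex_off
    pos <- gene_start[g] + gene_len
  }
  chrom_len <- pos + config$intergenic_len - 1L
  spacers <- vapply(seq_len(config$n_genes + 1L), function(i)
    random_dna(config$intergenic_len), character(1))
  body <- character(2L * config$n_genes + 1L)
  body[seq(1, length(body), by = 2)] <- spacers
  body[seq(2, length(body), by = 2)] <- gene_seq_plus
  genome <- setNames(paste(body, collapse = ""), chrom)
  stopifnot(nchar(genome) == chrom_len)

  # gene-strand offset (1-based, len) -> genomic plus-strand interval
  g2p <- function(g, off, len) {
    gi <- genes[[g]]
    if (gi$strand == "+") {
      s <- gene_start[g] + off - 1L
      c(s, s + len - 1L)
    } else {
      e <- gene_start[g] + gi$gene_len - off
      c(e - len + 1L, e)
    }
  }

  ## ---- genomic annotation tables -------------------------------------------
  for (g in seq_len(config$n_genes)) {
    gi <- genes[[g]]
    for (i in seq_len(gi$n_ex)) {
      iv <- g2p(g, gi$ex_off[i], gi$exon_len[i])
      exon_rows <- rbind(exon_rows, data.frame(
        gene_id = gi$gene_id, tx_id = gi$tx_id, chrom = chrom,
        start = iv[1], end = iv[2], strand = gi$strand, exon_rank = i,
        biotype = gi$biotype))
    }
    iv <- g2p(g, 1L, gi$gene_len)
    gene_rows <- rbind(gene_rows, data.frame(
      gene_id = gi$gene_id, tx_id = gi$tx_id, chrom = chrom,
      start = iv[1], end = iv[2], strand = gi$strand, biotype = gi$biotype))
  }

  # CDS: from mid exon 1 to mid last exon (transcript coordinates)
  cds_rows <- NULL
  for (g in seq_len(config$n_genes)) {
    gi <- genes[[g]]
    if (gi$biotype != "protein_coding") next
    tx_len <- sum(gi$exon_len)
    # UTRs may extend into the flanking internal exons (realistic gene
    # models; also keeps the localization categories non-degenerate)
    span5 <- gi$exon_len[1] %/% 2L + sample.int(gi$exon_len[2], 1)
    cds_from <- min(span5, tx_len %/% 3L)
    span3 <- gi$exon_len[gi$n_ex] %/% 2L +
      sample.int(gi$exon_len[gi$n_ex - 1L], 1)
    cds_to <- tx_len - min(span3, tx_len %/% 3L)
    # walk exons in transcript order, clip the CDS window
    t0 <- 0L
    for (i in seq_len(gi$n_ex)) {
      ts <- t0 + 1L; te <- t0 + gi$exon_len[i]
      s <- max(ts, cds_from); e <- min(te, cds_to)
      if (s <= e) {
        off <- gi$ex_off[i] + (s - ts)
        iv <- g2p(g, off, e - s + 1L)
        cds_rows <- rbind(cds_rows, data.frame(
          tx_id = gi$tx_id, chrom = chrom, start = iv[1], end = iv[2],
          strand = gi$strand))
      }
      t0 <- te
    }
  }
  model <- list(exons = exon_rows,
                cds = if (is.null(cds_rows))
                  data.frame(tx_id = character(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0)) else cds_rows)

  ## ---- genomic circRNA coordinates -----------------------------------------
  circs$chrom <- chrom
  circs$start <- NA_integer_; circs$end <- NA_integer_
  circs$strand <- NA_character_; circs$body_len <- NA_integer_
  for (k in seq_len(nrow(circs))) {
    g <- match(circs$gene_id[k], gid_vec)
    gi <- genes[[g]]
    fe <- circs$first_exon[k]; le <- circs$last_exon[k]
    iv1 <- g2p(g, gi$ex_off[fe], gi$exon_len[fe])
    iv2 <- g2p(g, gi$ex_off[le], gi$exon_len[le])
    circs$start[k] <- min(iv1[1], iv2[1])
    circs$end[k] <- max(iv1[2], iv2[2])
    circs$strand[k] <- gi$strand
    circs$body_len[k] <- sum(gi$exon_len[fe:le])
  }
  circs$junction <- junction_id(circs$chrom, circs$start, circs$end,
                                circs$strand)

  ## ---- Alu genomic coordinates & editing sites -----------------------------
  alus_out <- NULL; edit_sites <- NULL
  if (!is.null(alus)) {
    for (i in seq_len(nrow(alus))) {
      g <- alus$gene_row[i]
      iv <- g2p(g, alus$gstart[i], config$alu_len)
      alus_out <- rbind(alus_out, data.frame(
        alu_id = alus$alu_id[i], chrom = chrom, start = iv[1], end = iv[2],
        strand = alus$strand[i], rate = alus$rate[i],
        circ_id = alus$circ_id[i], side = alus$side[i]))
    }
    for (i in seq_len(nrow(alus_out))) {
      win <- substring(genome[[chrom]], alus_out$start[i], alus_out$end[i])
      ref <- if (alus_out$strand[i] == "+") "A" else "T"
      alt <- if (alus_out$strand[i] == "+") "G" else "C"
      rel <- gregexpr(ref, win, fixed = TRUE)[[1]]
      if (rel[1] != -1)
        edit_sites <- rbind(edit_sites, data.frame(
          alu_id = alus_out$alu_id[i],
          pos = alus_out$start[i] + as.integer(rel) - 1L,
          ref = ref, alt = alt, rate = alus_out$rate[i]))
    }
  }

  ## ---- design and planted counts -------------------------------------------
  n_per <- config$n_samples_per_condition
  design <- data.frame(
    sample = c(sprintf("WT_%d", seq_len(n_per)),
               sprintf("MUT_%d", seq_len(n_per))),
    condition = rep(c("WT", "MUT"), each = n_per),
    batch = sprintf("b%d", rep(rep(seq_len(config$n_batches),
                                   length.out = n_per), 2)))
  gene_abund <- config$gene_abundance * exp(rnorm(config$n_genes, 0, 0.25))
  gene_batch <- matrix(exp(rnorm(config$n_genes * config$n_batches, 0, 0.1)),
                       config$n_genes, config$n_batches)
  circ_batch <- matrix(exp(rnorm(nrow(circs) * config$n_batches, 0, 0.1)),
                       nrow(circs), config$n_batches)
  linear_lfc <- rep(0, config$n_genes)
  if (length(concordant_circ))
    linear_lfc[match(circs$gene_id[concordant_circ], gid_vec)] <- -1.5
  bn <- as.integer(sub("b", "", design$batch))
  is_mut <- design$condition == "MUT"
  circ_counts <- matrix(0L, nrow(circs), nrow(design),
                        dimnames = list(circs$circ_id, design$sample))
  for (k in seq_len(nrow(circs)))
    for (s in seq_len(nrow(design))) {
      mu <- config$circ_abundance * 2^(circs$lfc[k] * is_mut[s]) *
        circ_batch[k, bn[s]]
      circ_counts[k, s] <- rnbinom(1, mu = mu,
                                   size = 1 / config$nb_dispersion)
    }
  storage.mode(circ_counts) <- "integer"

  genes_df <- data.frame(gene_id = gid_vec,
                         tx_id = vapply(genes, `[[`, "", "tx_id"),
                         strand = vapply(genes, `[[`, "", "strand"),
                         biotype = vapply(genes, `[[`, "", "biotype"),
                         start = gene_rows$start, end = gene_rows$end,
                         abundance = gene_abund, linear_lfc = linear_lfc)

  truth <- structure(list(
    config = config, chrom = chrom, chrom_len = chrom_len,
    genes = genes_df, model = model, circs = circs,
    circ_counts = circ_counts,
    alus = alus_out, edit_sites = edit_sites,
    mirnas = mirnas, planted_sites = planted_sites,
    sponge_circs = circs$circ_id[sponges],
    concordant_circ = if (length(concordant_circ))
      circs$circ_id[concordant_circ] else character(0),
    design = design, gene_batch = gene_batch, circ_batch = circ_batch),
    class = "circfus_truth")

  alus_bed <- if (is.null(alus_out))
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0))
  else data.frame(chrom = alus_out$chrom, start = alus_out$start,
                  end = alus_out$end, name = alus_out$alu_id, score = 0,
                  strand = alus_out$strand)

  list(genome = genome, model = model, alus = alus_bed, truth = truth)
}

#' @export
print.circfus_truth <- function(x, ...) {
  cat(sprintf(
    "circfus ground truth: %d genes, %d circRNAs (+%d decoys), %d Alus, %d samples\n",
    nrow(x$genes), sum(!x$circs$decoy), sum(x$circs$decoy),
    if (is.null(x$alus)) 0L else nrow(x$alus), nrow(x$design)))
  invisible(x)
}

# spliced body sequence of a planted circRNA (transcript strand)
circ_body_seq <- function(truth, genome, k) {
  ci <- truth$circs[k, ]
  ex <- tx_exons(truth$model, ci$tx_id)
  ex <- ex[ex$exon_rank >= ci$first_exon & ex$exon_rank <= ci$last_exon, ]
  ex <- ex[order(ex$start), ]
  seq <- paste(substring(genome[[ci$chrom]], ex$start, ex$end), collapse = "")
  if (ci$strand == "-") revcomp(seq) else seq
}

#' Simulate paired-end reads with planted back-splice junction support
#'
#' For each planted circRNA and sample, exactly the planted number of pairs
#' spans the head-to-tail junction; linear fragments are drawn NB per gene;
#' Alu-covering genomic fragments (pre-mRNA stand-in) carry A-to-I editing;
#' a fraction of linear fragments shows adapter read-through and a fraction
#' of exact duplicate pairs is appended.  Fragments are emitted in unstranded
#' FR orientation.
#'
#' @param genome named character vector
#' @param truth a `circfus_truth` object
#' @param config the [sim_config()] used to build `truth`
#' @return list with named character vectors `r1` and `r2`; read names are
#'   `sample/class/origin/index` so that [split_reads_by_sample()] can
#'   recover per-sample FASTQ sets
#' @export
simulate_reads <- function(genome, truth, config) {
  set.seed(derive_seed(config$seed, 2L))
  rl <- config$read_len; fl <- config$frag_len
  design <- truth$design
  chromseq <- genome[[truth$chrom]]
  bn <- as.integer(sub("b", "", design$batch))
  is_mut <- design$condition == "MUT"

  tx_seqs <- setNames(
    vapply(truth$genes$tx_id, function(tx)
      tx_sequence(truth$model, tx, genome), character(1)),
    truth$genes$tx_id)
  body_seqs <- vapply(seq_len(nrow(truth$circs)), function(k)
    circ_body_seq(truth, genome, k), character(1))
  if (any(nchar(body_seqs) < fl))
    stop("simulation error: fragment longer than a circRNA body ",
         "(a junction read would wrap more than once)")

  acc1 <- list(); acc2 <- list()
  # fragment (plus/transcript orientation) -> unstranded FR pair
  make_pairs <- function(frag, names) {
    a <- substr(frag, 1, rl)
    b <- revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
    flip <- runif(length(frag)) < 0.5
    r1 <- ifelse(flip, b, a); r2 <- ifelse(flip, a, b)
    names(r1) <- names; names(r2) <- names
    acc1[[length(acc1) + 1L]] <<- r1
    acc2[[length(acc2) + 1L]] <<- r2
  }

  for (s in seq_len(nrow(design))) {
    sm <- design$sample[s]
    s_from <- length(acc1) + 1L
    ## planted BSJ pairs
    for (k in seq_len(nrow(truth$circs))) {
      n <- truth$circ_counts[k, s]
      if (n == 0) next
      body <- body_seqs[k]
      Lb <- nchar(body)
      doubled <- paste0(body, body)
      cpos <- sample(20:(rl - 20L), n, replace = TRUE)  # junction offset
      in_r1 <- runif(n) < 0.5
      f <- ifelse(in_r1, Lb - cpos + 1L, Lb - (fl - rl + cpos) + 1L)
      f <- pmax(1L, as.integer(f))
      make_pairs(substring(doubled, f, f + fl - 1L),
                 sprintf("%s/bsj/%s/%d", sm, truth$circs$circ_id[k],
                         seq_len(n)))
    }
    ## linear fragments per gene (with adapter read-through subset)
    for (g in seq_len(nrow(truth$genes))) {
      mu <- truth$genes$abundance[g] *
        2^(truth$genes$linear_lfc[g] * is_mut[s]) *
        truth$gene_batch[g, bn[s]]
      n <- rnbinom(1, mu = mu, size = 1 / config$nb_dispersion)
      if (n == 0) next
      tseq <- tx_seqs[[truth$genes$tx_id[g]]]
      Lt <- nchar(tseq)
      starts <- sample.int(Lt - fl + 1L, n, replace = TRUE)
      nm <- sprintf("%s/lin/%s/%d", sm, truth$genes$gene_id[g], seq_len(n))
      withad <- runif(n) < config$adapter_frac
      if (any(!withad))
        make_pairs(substring(tseq, starts[!withad],
                             starts[!withad] + fl - 1L), nm[!withad])
      if (any(withad)) {
        na <- sum(withad)
        ins <- sample(40:(rl - 1L), na, replace = TRUE)
        frag <- substring(tseq, starts[withad], starts[withad] + ins - 1L)
        pad <- substring(config$adapter, 1, rl - ins)
        a <- paste0(frag, pad); b <- paste0(revcomp(frag), pad)
        flip <- runif(na) < 0.5
        r1 <- ifelse(flip, b, a); r2 <- ifelse(flip, a, b)
        names(r1) <- nm[withad]; names(r2) <- nm[withad]
        acc1[[length(acc1) + 1L]] <- r1
        acc2[[length(acc2) + 1L]] <- r2
      }
    }
    ## Alu-covering genomic fragments (pre-mRNA stand-in) with editing
    if (!is.null(truth$alus)) {
      for (a in seq_len(nrow(truth$alus))) {
        au <- truth$alus[a, ]
        n <- rpois(1, config$alu_coverage * (config$alu_len + fl) / (2 * rl))
        if (n == 0) next
        lo <- max(1L, au$start - fl + 40L)
        hi <- min(truth$chrom_len - fl + 1L, au$end - 40L)
        starts <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
        frag <- substring(chromseq, starts, starts + fl - 1L)
        sites <- truth$edit_sites[truth$edit_sites$alu_id == au$alu_id, ]
        for (j in seq_len(nrow(sites))) {
          rel <- sites$pos[j] - starts + 1L
          hit <- rel >= 1L & rel <= fl & runif(n) < sites$rate[j]
          if (any(hit))
            substr(frag[hit], rel[hit], rel[hit]) <- sites$alt[j]
        }
        make_pairs(frag, sprintf("%s/alu/%s/%d", sm, au$alu_id, seq_len(n)))
      }
    }
    ## exact duplicate pairs
    sr1 <- unlist(acc1[seq(s_from, length(acc1))])
    sr2 <- unlist(acc2[seq(s_from, length(acc2))])
    ndup <- round(config$dup_frac * length(sr1))
    if (ndup > 0) {
      pick <- sample(length(sr1), ndup, replace = TRUE)
      d1 <- sr1[pick]; d2 <- sr2[pick]
      nm <- sprintf("%s.dup%d", names(d1), seq_len(ndup))
      names(d1) <- nm; names(d2) <- nm
      acc1[[length(acc1) + 1L]] <- d1
      acc2[[length(acc2) + 1L]] <- d2
    }
  }
  list(r1 = unlist(acc1), r2 = unlist(acc2))
}

#' Split simulated reads by sample
#' @param reads list with r1/r2 as returned by [simulate_reads()]
#' @return named list: sample -> list(r1, r2)
#' @export
split_reads_by_sample <- function(reads) {
  sm <- sub("/.*$", "", names(reads$r1))
  lapply(split(seq_along(sm), sm), function(i)
    list(r1 = reads$r1[i], r2 = reads$r2[i]))
}

#' Simulate PAR-CLIP T-to-C transition events
#'
#' Places transition events at `transition_density` per kb inside the 1-kb
#' flanks of the circRNAs in `bound_circ_ids`, and at the configured
#' background density elsewhere on the chromosome.  Every emitted position
#' holds a T on the annotated strand.
#'
#' @param truth a `circfus_truth` object
#' @param config the corresponding [sim_config()]
#' @param bound_circ_ids character vector of bound circRNA ids
#' @param genome named character vector
#' @return BED-style data.frame (chrom, start, end, name, score, strand),
#'   1-based closed coordinates
#' @export
simulate_parclip <- function(truth, config, bound_circ_ids, genome) {
  set.seed(derive_seed(config$seed, 3L))
  chromseq <- genome[[truth$chrom]]
  out <- NULL
  add_events <- function(lo, hi, strand, density) {
    lo <- max(1L, lo); hi <- min(truth$chrom_len, hi)
    if (hi < lo) return()
    n <- rpois(1, density * (hi - lo + 1L) / 1000)
    if (n == 0) return()
    win <- substring(chromseq, lo, hi)
    base <- if (strand == "+") "T" else "A"
    cand <- gregexpr(base, win, fixed = TRUE)[[1]]
    if (cand[1] == -1) return()
    pos <- lo + as.integer(sample(rep(cand, 2), min(n, length(cand)))) - 1L
    pos <- unique(pos)
    out <<- rbind(out, data.frame(chrom = truth$chrom, start = pos,
                                  end = pos, strand = strand))
  }
  bound_iv <- NULL
  for (k in seq_len(nrow(truth$circs))) {
    ci <- truth$circs[k, ]
    if (!(ci$circ_id %in% bound_circ_ids)) next
    add_events(ci$start - 1000L, ci$start - 1L, ci$strand,
               config$transition_density)
    add_events(ci$end + 1L, ci$end + 1000L, ci$strand,
               config$transition_density)
    bound_iv <- rbind(bound_iv,
                      data.frame(lo = ci$start - 1000L, hi = ci$start - 1L),
                      data.frame(lo = ci$end + 1L, hi = ci$end + 1000L))
  }
  # background: gene bodies outside bound flanks, on the gene strand
  if (config$background_transition_density > 0) {
    for (g in seq_len(nrow(truth$genes))) {
      gi <- truth$genes[g, ]
      segs <- data.frame(lo = gi$start, hi = gi$end)
      if (!is.null(bound_iv))
        for (b in seq_len(nrow(bound_iv))) {
          nsegs <- NULL
          for (si in seq_len(nrow(segs))) {
            s <- segs[si, ]
            if (bound_iv$hi[b] < s$lo || bound_iv$lo[b] > s$hi) {
              nsegs <- rbind(nsegs, s)
            } else {
              if (bound_iv$lo[b] > s$lo)
                nsegs <- rbind(nsegs,
                               data.frame(lo = s$lo, hi = bound_iv$lo[b] - 1L))
              if (bound_iv$hi[b] < s$hi)
                nsegs <- rbind(nsegs,
                               data.frame(lo = bound_iv$hi[b] + 1L, hi = s$hi))
            }
          }
          segs <- if (is.null(nsegs))
            data.frame(lo = integer(0), hi = integer(0)) else nsegs
        }
      for (si in seq_len(nrow(segs)))
        add_events(segs$lo[si], segs$hi[si], gi$strand,
                   config$background_transition_density)
    }
  }
  if (is.null(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  out <- out[order(out$start), ]
  data.frame(chrom = out$chrom, start = out$start, end = out$end,
             name = sprintf("tc_%04d", seq_len(nrow(out))), score = 1,
             strand = out$strand)
}

#' Simulate mRNA/protein fold-change, miRNA-interaction and category tables
#'
#' Emulates the downstream resources the ceRNA stage consumes: an
#' interaction table with a prediction score plus five source flags
#' (TarPmiR-style score, four corroborating databases including a validated
#' flag), mRNA and protein log2 fold-change tables with planted responder
#' targets of the sponged miRNAs, a gene-to-category map with one planted
#' enriched category, and a miRNA expression table.  Background interactions
#' are sub-threshold by construction so the planted target set is exactly
#' recoverable (see methods vignette).
#'
#' @param truth a `circfus_truth` object
#' @param config the corresponding [sim_config()]
#' @param n_universe size of the symbolic target-gene universe
#' @return list of data.frames: interactions, mrna_fc, protein_fc,
#'   categories, mirna_expr, targets (planted-truth responder targets)
#' @export
simulate_tables <- function(truth, config, n_universe = 200L) {
  set.seed(derive_seed(config$seed, 4L))
  universe <- sprintf("TG%03d", seq_len(n_universe))
  sponge_mirnas <- if (is.null(truth$planted_sites)) character(0) else
    unique(truth$planted_sites$mirna[
      truth$planted_sites$n_sites >= 2 | truth$planted_sites$bsj_spanning])
  mrna_lfc <- setNames(rnorm(n_universe, 0, 0.2), universe)
  prot_lfc <- setNames(rnorm(n_universe, 0, 0.2), universe)

  inter <- NULL; targets <- NULL
  pool <- universe
  for (m in sponge_mirnas) {
    tg <- sample(pool, 12)
    pool <- setdiff(pool, tg)
    validated <- seq_along(tg) <= 2
    score <- ifelse(validated, runif(length(tg), 0.5, 0.94),
                    runif(length(tg), 0.95, 1))
    kind <- sample(c("mrna", "protein", "both"), length(tg), replace = TRUE)
    mrna_lfc[tg[kind != "protein"]] <-
      -abs(rnorm(sum(kind != "protein"), 1, 0.3))
    prot_lfc[tg[kind != "mrna"]] <- -abs(rnorm(sum(kind != "mrna"), 1, 0.3))
    mrna_lfc[tg[kind == "protein"]] <- abs(rnorm(sum(kind == "protein"),
                                                 0, 0.05))
    prot_lfc[tg[kind == "mrna"]] <- abs(rnorm(sum(kind == "mrna"), 0, 0.05))
    inter <- rbind(inter, data.frame(
      mirna = m, gene = tg, score = round(score, 4),
      targetscan = TRUE, mirdb = runif(length(tg)) < 0.5,
      mirtarbase = runif(length(tg)) < 0.3, tarbase = validated))
    targets <- rbind(targets, data.frame(mirna = m, gene = tg,
                                         validated = validated, kind = kind))
  }
  # background interactions: sub-threshold by construction
  nbg <- 300L
  bg <- data.frame(
    mirna = sample(names(truth$mirnas), nbg, replace = TRUE),
    gene = sample(universe, nbg, replace = TRUE),
    score = round(runif(nbg, 0, 0.94), 4),
    targetscan = runif(nbg) < 0.3, mirdb = runif(nbg) < 0.3,
    mirtarbase = runif(nbg) < 0.1, tarbase = FALSE)
  key <- paste(bg$mirna, bg$gene)
  if (!is.null(inter)) bg <- bg[!key %in% paste(inter$mirna, inter$gene), ]
  inter <- rbind(inter, bg)
  inter <- inter[order(inter$mirna, inter$gene), ]
  rownames(inter) <- NULL

  # categories: one planted (enriched in miR-1 responder targets), others flat
  cats <- NULL
  if (!is.null(targets)) {
    planted <- c(head(targets$gene[targets$mirna == sponge_mirnas[1]], 10),
                 sample(setdiff(universe, targets$gene), 2))
    cats <- data.frame(category = "CAT_planted", gene = planted)
  }
  for (i in seq_len(7))
    cats <- rbind(cats, data.frame(category = sprintf("CAT_%02d", i),
                                   gene = sample(universe, 15)))
  mirna_expr <- data.frame(mirna = names(truth$mirnas), cpm = 5)

  list(interactions = inter,
       mrna_fc = data.frame(gene = universe,
                            log2fc = round(unname(mrna_lfc), 4)),
       protein_fc = data.frame(gene = universe,
                               log2fc = round(unname(prot_lfc), 4)),
       categories = cats, mirna_expr = mirna_expr, targets = targets)
}

#' Run the full simulator and optionally write all artifacts
#'
#' @param config a [sim_config()]
#' @param outdir optional directory; when given, writes genome.fa, genes.gtf,
#'   alus.bed, parclip.bed, per-sample FASTQ pairs, design.tsv and the
#'   downstream tables
#' @param bound_circ_ids circRNAs whose flanks carry planted transitions;
#'   default: the non-concordant downregulated ones
#' @return list(genome, model, alus, truth, reads, parclip, tables)
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL,
                             bound_circ_ids = NULL) {
  ref <- generate_reference(config)
  truth <- ref$truth
  if (is.null(bound_circ_ids)) {
    cc <- truth$circs
    bound_circ_ids <- setdiff(cc$circ_id[!cc$decoy & cc$lfc < 0],
                              truth$concordant_circ)
  }
  reads <- simulate_reads(ref$genome, truth, config)
  parclip <- simulate_parclip(truth, config, bound_circ_ids, ref$genome)
  tables <- simulate_tables(truth, config)
  truth$bound_circ_ids <- bound_circ_ids
  out <- list(genome = ref$genome, model = ref$model, alus = ref$alus,
              truth = truth, reads = reads, parclip = parclip,
              tables = tables)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(outdir, "genome.fa"))
    write_gtf(out$model, file.path(outdir, "genes.gtf"))
    write_bed6(out$alus, file.path(outdir, "alus.bed"))
    write_bed6(out$parclip, file.path(outdir, "parclip.bed"))
    per <- split_reads_by_sample(reads)
    for (sm in names(per)) {
      write_fastq(per[[sm]]$r1,
                  file.path(outdir, sprintf("%s_1.fastq", sm)))
      write_fastq(per[[sm]]$r2,
                  file.path(outdir, sprintf("%s_2.fastq", sm)))
    }
    write.table(truth$design, file.path(outdir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in c("interactions", "mrna_fc", "protein_fc", "categories",
                 "mirna_expr"))
      write.table(tables[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
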