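# ceRNA inference: circRNA sequence reconstruction across the back-splice
# junction, miRNA binding-site prediction, sponge calls, target filtering,
# over-representation analysis and the tripartite network.

#' Reconstruct circRNA sequences across the back-splice junction
#'
#' For each junction, candidate sequences are built per overlapping
#' expressed transcript (exonic concatenation over the circ span, 3' end
#' extended with the first 125 nt of the body); the junction's supporting
#' read pairs are aligned to each candidate and a pair supports a candidate
#' when both mates place on it and at least one mate crosses the original 3'
#' end.  The winning transcript maximises supporting pairs; the final
#' sequence retains only the first 25 nt of the extension.
#'
#' @param junctions annotated junction data.frame (needs junction_id, chrom,
#'   start, end, host_tx)
#' @param support data.frame(junction_id, pair_id) from [detect_circrnas()]
#' @param reads list(r1, r2) of the (deduplicated) mate sequences backing
#'   `support`
#' @param model gene model
#' @param genome named character vector
#' @param expressed_txs transcripts considered expressed (default: all)
#' @param ext_search extension used for read support (125 nt)
#' @param ext_keep extension retained in the final sequence (25 nt)
#' @param max_mm mismatch tolerance for support alignment
#' @return data.frame(circ_id, transcript_id, seq, bsj_offset, support);
#'   junctions with no supported candidate are dropped with a message
#' @export
reconstruct_sequences <- function(junctions, support, reads, model, genome,
                                  expressed_txs = NULL, ext_search = 125L,
                                  ext_keep = 25L, max_mm = 2L) {
  if (is.null(expressed_txs)) expressed_txs <- unique(model$exons$tx_id)
  out <- NULL
  for (j in seq_len(nrow(junctions))) {
    jr <- junctions[j, ]
    txs <- intersect(strsplit(jr$host_tx, ",")[[1]], expressed_txs)
    txs <- sort(txs)
    if (!length(txs)) next
    pairs <- unique(support$pair_id[support$junction_id == jr$junction_id])
    if (!length(pairs)) next
    mates <- c(setNames(reads$r1[pairs], paste0(pairs, "/1")),
               setNames(reads$r2[pairs], paste0(pairs, "/2")))
    mates <- mates[!is.na(mates)]
    best_tx <- NULL; best_support <- 0L; best_body <- NULL
    for (tx in txs) {
      ex <- tx_exons(model, tx)
      exs <- ex[order(ex$start), ]
      exs <- exs[exs$end >= jr$start & exs$start <= jr$end, , drop = FALSE]
      if (!nrow(exs)) next
      pieces <- substring(genome[[jr$chrom]],
                          pmax(exs$start, jr$start),
                          pmin(exs$end, jr$end))
      body <- paste(pieces, collapse = "")
      if (exs$strand[1] == "-") body <- revcomp(body)
      Lb <- nchar(body)
      cand <- paste0(body, substr(body, 1, min(ext_search, Lb)))
      pl <- align_linear(mates, c(cand = cand), max_mm = max_mm)
      if (!nrow(pl)) next
      pl$pair <- sub("/[12]$", "", pl$read_id)
      crosses <- pl$start <= Lb & pl$start + pl$width - 1L >= Lb + 1L
      ok_pairs <- intersect(
        intersect(pl$pair[endsWith(pl$read_id, "/1")],
                  pl$pair[endsWith(pl$read_id, "/2")]),
        pl$pair[crosses])
      ns <- length(ok_pairs)
      if (ns > best_support) {
        best_support <- ns; best_tx <- tx; best_body <- body
      }
    }
    if (is.null(best_tx)) {
      message("circRNA ", jr$junction_id,
              " dropped from ceRNA analysis: no candidate transcript ",
              "sequence gained read-pair support")
      next
    }
    Lb <- nchar(best_body)
    out <- rbind(out, data.frame(
      circ_id = jr$junction_id, transcript_id = best_tx,
      seq = paste0(best_body, substr(best_body, 1, min(ext_keep, Lb))),
      bsj_offset = Lb, support = best_support))
  }
  if (is.null(out))
    out <- data.frame(circ_id = character(0), transcript_id = character(0),
                      seq = character(0), bsj_offset = integer(0),
                      support = integer(0))
  out
}

# pairing score of one site: miRNA position i pairs target position
# p0 + n - i (antiparallel); Watson-Crick +5, G:U wobble +2, mismatch -4,
# seed positions 2-8 doubled.  A perfect 21-mer site scores 140.
site_score <- function(site_chars, mir_chars) {
  n <- length(mir_chars)
  tc <- site_chars[n - seq_len(n) + 1L]
  wc <- (tc == "A" & mir_chars == "T") | (tc == "T" & mir_chars == "A") |
    (tc == "G" & mir_chars == "C") | (tc == "C" & mir_chars == "G")
  gu <- (tc == "G" & mir_chars == "T") | (tc == "T" & mir_chars == "G")
  sc <- ifelse(wc, 5, ifelse(gu, 2, -4))
  sc[2:8] <- 2 * sc[2:8]
  sum(sc)
}

#' Predict miRNA binding sites on reconstructed circRNA sequences
#'
#' Seed-anchored complementarity scan in the miRanda spirit: candidate sites
#' are exact matches of the reverse complement of the miRNA seed (positions
#' 2-8); each candidate is scored over the full miRNA length (+5
#' Watson-Crick, +2 G:U, -4 mismatch, seed doubled) with a pairing-energy
#' proxy of -score/10.  Sites entirely inside the duplicated extension are
#' copies of their 5' originals and are discarded; overlapping sites of the
#' same (circRNA, miRNA) pair (> 50% of the shorter) are deduplicated
#' keeping the best score.
#'
#' @param circ_seqs data.frame from [reconstruct_sequences()]
#' @param mirnas named character vector of mature miRNA sequences (RNA or
#'   DNA alphabet, 18-26 nt)
#' @param min_score minimum reported alignment score (140)
#' @param max_energy maximum reported energy proxy (-1.0)
#' @return data.frame(circ_id, mirna, start, end, score, energy, spans_bsj)
#'   with 1-based closed offsets on the extended sequence
#' @export
predict_sites <- function(circ_seqs, mirnas, min_score = 140,
                          max_energy = -1.0) {
  mirnas <- toupper(chartr("Uu", "Tt", mirnas))
  if (any(nchar(mirnas) < 18 | nchar(mirnas) > 26))
    stop("mature miRNA sequences must be 18-26 nt")
  out <- NULL
  for (ci in seq_len(nrow(circ_seqs))) {
    seq <- circ_seqs$seq[ci]
    bsj <- circ_seqs$bsj_offset[ci]
    seq_chars <- strsplit(seq, "")[[1]]
    for (m in names(mirnas)) {
      mir <- mirnas[[m]]
      n <- nchar(mir)
      mir_chars <- strsplit(mir, "")[[1]]
      motif <- revcomp(substr(mir, 2, 8))
      occ <- gregexpr(motif, seq, fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      hits <- NULL
      for (s in as.integer(occ)) {
        p0 <- s - (n - 8L)
        if (p0 < 1L || p0 + n - 1L > nchar(seq)) next
        if (p0 > bsj) next  # entirely inside the duplicated tail: a copy
        sc <- site_score(seq_chars[p0:(p0 + n - 1L)], mir_chars)
        en <- -sc / 10
        if (sc < min_score || en > max_energy) next
        hits <- rbind(hits, data.frame(
          circ_id = circ_seqs$circ_id[ci], mirna = m,
          start = p0, end = p0 + n - 1L, score = sc, energy = en,
          spans_bsj = p0 <= bsj && p0 + n - 1L > bsj))
      }
      if (is.null(hits)) next
      # overlap dedup: keep best score, then leftmost
      hits <- hits[order(-hits$score, hits$start), ]
      kept <- hits[0, ]
      for (r in seq_len(nrow(hits))) {
        h <- hits[r, ]
        ov <- FALSE
        if (nrow(kept)) {
          shorter <- pmin(h$end - h$start + 1L, kept$end - kept$start + 1L)
          inter <- pmin(h$end, kept$end) - pmax(h$start, kept$start) + 1L
          ov <- any(inter > 0.5 * shorter)
        }
        if (!ov) kept <- rbind(kept, h)
      }
      out <- rbind(out, kept)
    }
  }
  if (is.null(out))
    out <- data.frame(circ_id = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), energy = numeric(0),
                      spans_bsj = logical(0))
  rownames(out) <- NULL
  out
}

#' Call putative miRNA sponges
#'
#' A circRNA is a putative sponge for a miRNA iff it carries at least two
#' (deduplicated) sites for it, or at least one site spanning the
#' back-splice junction.
#'
#' @param sites data.frame from [predict_sites()]
#' @return data.frame(circ_id, mirna, n_sites, has_bsj_site, is_sponge)
#' @export
call_sponges <- function(sites) {
  if (!nrow(sites))
    return(data.frame(circ_id = character(0), mirna = character(0),
                      n_sites = integer(0), has_bsj_site = logical(0),
                      is_sponge = logical(0)))
  dt <- data.table::as.data.table(sites)
  agg <- dt[, .(n_sites = .N, has_bsj_site = any(spans_bsj)),
            by = .(circ_id, mirna)]
  agg[, is_sponge := n_sites >= 2L | has_bsj_site]
  as.data.frame(agg)
}

#' Filter candidate targets of sponged miRNAs
#'
#' Keeps a (miRNA, gene) interaction iff its prediction score is at least
#' `min_score` with at least one corroborating database flag, or the
#' interaction is experimentally validated (which bypasses the score
#' threshold); and the gene is downregulated at the mRNA and/or the protein
#' level.
#'
#' @param sponge_mirnas character vector of sponged miRNA names
#' @param interactions data.frame(mirna, gene, score, targetscan, mirdb,
#'   mirtarbase, tarbase)
#' @param mrna_fc,protein_fc data.frame(gene, log2fc)
#' @param min_score TarPmiR-style score threshold (0.95)
#' @return data.frame(mirna, gene, score, validated, mrna_log2fc,
#'   protein_log2fc)
#' @export
filter_targets <- function(sponge_mirnas, interactions, mrna_fc, protein_fc,
                           min_score = 0.95) {
  it <- interactions[interactions$mirna %in% sponge_mirnas, , drop = FALSE]
  if (!nrow(it))
    return(data.frame(mirna = character(0), gene = character(0),
                      score = numeric(0), validated = logical(0),
                      mrna_log2fc = numeric(0), protein_log2fc = numeric(0)))
  src <- it$targetscan | it$mirdb | it$mirtarbase | it$tarbase
  pass_pred <- it$score >= min_score & src
  pass <- pass_pred | it$tarbase
  mlfc <- mrna_fc$log2fc[match(it$gene, mrna_fc$gene)]
  plfc <- protein_fc$log2fc[match(it$gene, protein_fc$gene)]
  down <- (!is.na(mlfc) & mlfc < 0) | (!is.na(plfc) & plfc < 0)
  keep <- pass & down
  out <- data.frame(mirna = it$mirna[keep], gene = it$gene[keep],
                    score = it$score[keep], validated = it$tarbase[keep],
                    mrna_log2fc = mlfc[keep], protein_log2fc = plfc[keep])
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis of target genes
#'
#' Per category: P(X >= overlap) with X ~ Hypergeom(|background|,
#' |category|, |targets|), categories kept at p < `p_cutoff`.
#'
#' @param targets character vector of target genes
#' @param categories data.frame(category, gene)
#' @param background character vector (must contain the targets)
#' @param p_cutoff significance cutoff (0.01)
#' @return data.frame(category, n_category, n_overlap, p_value, enriched)
#' @export
ora_enrichment <- function(targets, categories, background,
                           p_cutoff = 0.01) {
  targets <- unique(targets)
  background <- unique(background)
  stopifnot(all(targets %in% background))
  N <- length(background)
  n <- length(targets)
  cats <- split(categories$gene, categories$category)
  res <- lapply(names(cats), function(cn) {
    K <- length(intersect(cats[[cn]], background))
    k <- length(intersect(cats[[cn]], targets))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cn, n_category = K, n_overlap = k, p_value = p)
  })
  out <- do.call(rbind, res)
  out$enriched <- out$p_value < p_cutoff
  rownames(out) <- NULL
  out
}

#' Build the circRNA-miRNA-category ceRNA network
#'
#' Nodes: sponge circRNAs, sponged miRNAs and enriched categories.  Edges:
#' circRNA-miRNA weighted by the number of binding sites (with a bsj flag),
#' miRNA-category weighted by the number of that miRNA's filtered targets in
#' the category, and category-category weighted by the number of shared
#' target genes (absent when zero).
#'
#' @param sponges data.frame from [call_sponges()] (only is_sponge rows are
#'   used)
#' @param targets data.frame from [filter_targets()]
#' @param enrichment data.frame from [ora_enrichment()]
#' @param categories data.frame(category, gene)
#' @return an igraph graph with vertex attribute `type` in
#'   {circRNA, miRNA, category} and edge attributes kind/weight/bsj
#' @export
build_network <- function(sponges, targets, enrichment, categories) {
  sp <- sponges[sponges$is_sponge, , drop = FALSE]
  enr <- enrichment$category[enrichment$enriched]
  edges <- NULL
  if (nrow(sp))
    edges <- data.frame(from = sp$circ_id, to = sp$mirna,
                        kind = "sponge", weight = sp$n_sites,
                        bsj = sp$has_bsj_site)
  tg <- targets[targets$mirna %in% sp$mirna, , drop = FALSE]
  cat_genes <- split(categories$gene, categories$category)
  cat_targets <- list()
  for (cn in enr) {
    cat_targets[[cn]] <- intersect(cat_genes[[cn]], unique(tg$gene))
    for (m in unique(tg$mirna)) {
      k <- length(intersect(tg$gene[tg$mirna == m], cat_genes[[cn]]))
      if (k > 0)
        edges <- rbind(edges, data.frame(from = m, to = cn,
                                         kind = "mirna-category",
                                         weight = k, bsj = FALSE))
    }
  }
  if (length(enr) > 1) {
    cmb <- combn(enr, 2)
    for (i in seq_len(ncol(cmb))) {
      shared <- length(intersect(cat_targets[[cmb[1, i]]],
                                 cat_targets[[cmb[2, i]]]))
      if (shared > 0)
        edges <- rbind(edges, data.frame(from = cmb[1, i], to = cmb[2, i],
                                         kind = "category-category",
                                         weight = shared, bsj = FALSE))
    }
  }
  if (is.null(edges))
    return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  type <- rep("category", igraph::vcount(g))
  nm <- igraph::V(g)$name
  type[nm %in% sp$circ_id] <- "circRNA"
  type[nm %in% sp$mirna] <- "miRNA"
  igraph::V(g)$type <- type
  g
}

#' Write reconstructed circRNA sequences as FASTA
#'
#' The BSJ offset travels in the header (`id bsj_offset=<n>`), so the file
#' round-trips through [read_circ_sequences()].
#'
#' @param circ_seqs data.frame from [reconstruct_sequences()]
#' @param path output FASTA
#' @export
write_circ_sequences <- function(circ_seqs, path) {
  seqs <- setNames(circ_seqs$seq,
                   sprintf("%s bsj_offset=%d support=%d",
                           circ_seqs$circ_id, circ_seqs$bsj_offset,
                           circ_seqs$support))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60)
  invisible(path)
}

#' Read circRNA sequences written by [write_circ_sequences()]
#' @param path input FASTA
#' @export
read_circ_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  data.frame(
    circ_id = sub("\\s.*$", "", hdr),
    transcript_id = NA_character_,
    seq = unname(as.character(x)),
    bsj_offset = as.integer(sub(".*bsj_offset=(\\d+).*", "\\1", hdr)),
    support = as.integer(sub(".*support=(\\d+).*", "\\1", hdr)))
}

#' Export a ceRNA network as GraphML and SIF
#'
#' @param g igraph graph from [build_network()]
#' @param graphml_path,sif_path output files (NULL to skip)
#' @return invisible NULL
#' @export
write_network <- function(g, graphml_path = NULL, sif_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(sif_path)) {
    if (igraph::ecount(g)) {
      e <- igraph::as_data_frame(g, what = "edges")
      writeLines(sprintf("%s\t%s\t%s", e$from, e$kind, e$to), sif_path)
    } else writeLines(character(0), sif_path)
  }
  invisible(NULL)
}
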