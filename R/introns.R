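# Flanking-intron analysis: 1-kb windows around tested circRNAs, protein
# binding calls from PAR-CLIP T-to-C transitions, enrichment tests, inverted
# Alu detection and the A-to-I Alu editing index.

#' Extract 1-kb flanking windows of tested circRNAs
#'
#' Concordantly deregulated circRNAs (class both-concordant) are excluded:
#' when the linear counterpart moves the same way, direct modulation of
#' back-splicing is less likely.  Flanks are computed in genomic coordinates
#' regardless of strand and clipped at chromosome bounds.
#'
#' @param junctions data.frame with junction_id, chrom, start, end, strand
#' @param concordance data.frame from [classify_concordance()]
#' @param chrom_len named vector of chromosome lengths
#' @param flank_len window length (1000 nt)
#' @return data.frame(circ_id, chrom, strand, up_start, up_end, dn_start,
#'   dn_end, de_status)
#' @export
extract_flanks <- function(junctions, concordance, chrom_len,
                           flank_len = 1000L) {
  cc <- concordance[match(junctions$junction_id, concordance$junction_id), ]
  keep <- is.na(cc$class) | cc$class != "both-concordant"
  j <- junctions[keep, , drop = FALSE]
  cc <- cc[keep, , drop = FALSE]
  status <- rep("unaffected", nrow(j))
  dereg <- cc$class %in% c("circ-only", "both-discordant")
  status[dereg & cc$circ_log2fc < 0] <- "down"
  status[dereg & cc$circ_log2fc > 0] <- "up"
  data.frame(
    circ_id = j$junction_id, chrom = j$chrom, strand = j$strand,
    up_start = pmax(1L, j$start - flank_len), up_end = j$start - 1L,
    dn_start = j$end + 1L,
    dn_end = pmin(chrom_len[j$chrom], j$end + flank_len),
    de_status = status, row.names = NULL)
}

#' Mark flanks bound by the protein (>= 1 T-to-C transition overlap)
#'
#' @param flanks data.frame from [extract_flanks()]
#' @param transitions BED-style data.frame (1-based closed) of T-to-C events
#' @return `flanks` with logical columns up_bound, dn_bound, fus_bound
#' @export
mark_fus_bound <- function(flanks, transitions) {
  hit <- function(lo, hi, chrom)
    vapply(seq_along(lo), function(i)
      any(transitions$chrom == chrom[i] & transitions$start <= hi[i] &
            transitions$end >= lo[i]), logical(1))
  flanks$up_bound <- hit(flanks$up_start, flanks$up_end, flanks$chrom)
  flanks$dn_bound <- hit(flanks$dn_start, flanks$dn_end, flanks$chrom)
  flanks$fus_bound <- flanks$up_bound | flanks$dn_bound
  flanks
}

# one-sided (greater) Fisher exact test of a 2x2 table via the
# hypergeometric tail: P(X >= a) for table [[a, b], [c, d]]
fisher_greater <- function(a, b, c, d) {
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' One-sided Fisher tests: binding enrichment in deregulated circRNAs
#'
#' For each direction (down, up), compares the proportion of deregulated
#' circRNAs with at least one binding site in their flanking introns to the
#' proportion among unaffected circRNAs (alternative: greater).
#'
#' @param flanks data.frame from [mark_fus_bound()] (needs fus_bound,
#'   de_status)
#' @return list(down = list(p_value, table), up = list(p_value, table))
#' @export
fisher_binding_enrichment <- function(flanks) {
  res <- list()
  for (dir in c("down", "up")) {
    a <- sum(flanks$de_status == dir & flanks$fus_bound)
    b <- sum(flanks$de_status == dir & !flanks$fus_bound)
    c_ <- sum(flanks$de_status == "unaffected" & flanks$fus_bound)
    d <- sum(flanks$de_status == "unaffected" & !flanks$fus_bound)
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                  dimnames = list(c(dir, "unaffected"),
                                  c("bound", "unbound")))
    res[[dir]] <- list(p_value = fisher_greater(a, b, c_, d), table = tab)
  }
  res
}

#' Flag circRNAs with inverted Alu pairs straddling the circularised exons
#'
#' TRUE iff at least one Alu overlaps the upstream flank and at least one
#' the downstream flank with opposite orientation (partial overlap counts).
#'
#' @param flanks data.frame from [extract_flanks()]
#' @param alus BED-style data.frame (chrom, start, end, name, score, strand)
#' @return `flanks` with logical column inverted_alu
#' @export
detect_inverted_alus <- function(flanks, alus) {
  inv <- logical(nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    au <- alus[alus$chrom == flanks$chrom[i], , drop = FALSE]
    up <- au[intervals_overlap(au$start, au$end, flanks$up_start[i],
                               flanks$up_end[i]), , drop = FALSE]
    dn <- au[intervals_overlap(au$start, au$end, flanks$dn_start[i],
                               flanks$dn_end[i]), , drop = FALSE]
    inv[i] <- nrow(up) > 0 && nrow(dn) > 0 &&
      any(outer(up$strand, dn$strand, `!=`))
  }
  flanks$inverted_alu <- inv
  flanks
}

#' Hypergeometric test of the overlap between two circRNA sets
#'
#' P(X >= |A intersect B|) with X ~ Hypergeom(|U|, |A|, |B|).
#'
#' @param set_a,set_b character vectors (subsets of `universe`)
#' @param universe character vector
#' @return list(p_value, overlap, n_a, n_b, n_universe)
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  ov <- length(intersect(set_a, set_b))
  N <- length(unique(universe))
  K <- length(unique(set_a)); n <- length(unique(set_b))
  list(p_value = phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
       overlap = ov, n_a = K, n_b = n, n_universe = N)
}

#' Weighted A-to-I Alu editing index for one sample
#'
#' Reads are placed on the genome (relaxed mismatch budget so that heavily
#' edited reads are not excluded); over all reference-A positions of
#' plus-strand Alus (reference-T, counted on the reverse complement, for
#' minus-strand Alus), coverage and G (resp. C) mismatches are pooled before
#' division: index = 100 * pooled mismatches / pooled coverage.  An Alu is
#' "expressed" when at least `min_cov` of its A positions are covered;
#' only expressed Alus are pooled.  With `flanks`, only Alus overlapping a
#' flanking window are considered.
#'
#' @param reads named character vector of the sample's mate sequences
#' @param genome named character vector
#' @param alus BED-style data.frame with strand
#' @param flanks optional data.frame from [extract_flanks()] restricting the
#'   scope
#' @param min_cov expressed-Alu threshold (covered A positions)
#' @param max_mm relaxed mismatch budget for placement (large enough that
#'   heavily edited reads are not excluded from coverage)
#' @param placements optional precomputed placements (from a previous call
#'   or [align_and_split()]); when NULL, reads are aligned here
#' @return list(index, a_coverage, g_mismatches, per_alu)
#' @export
alu_editing_index <- function(reads, genome, alus, flanks = NULL,
                              min_cov = 10L, max_mm = 12L,
                              placements = NULL) {
  if (!is.null(flanks)) {
    keep <- logical(nrow(alus))
    for (i in seq_len(nrow(alus))) {
      f <- flanks[flanks$chrom == alus$chrom[i], , drop = FALSE]
      keep[i] <- any(intervals_overlap(alus$start[i], alus$end[i],
                                       f$up_start, f$up_end)) ||
        any(intervals_overlap(alus$start[i], alus$end[i],
                              f$dn_start, f$dn_end))
    }
    alus <- alus[keep, , drop = FALSE]
  }
  if (!nrow(alus))
    return(list(index = NA_real_, a_coverage = 0L, g_mismatches = 0L,
                per_alu = NULL))
  if (is.null(placements))
    placements <- align_linear(reads, genome, max_mm = max_mm)
  pl <- placements
  # plus-strand-oriented aligned sequence of each placement
  aln <- ifelse(pl$strand == "-", revcomp(unname(reads[pl$read_id])),
                unname(reads[pl$read_id]))
  per_alu <- NULL
  for (i in seq_len(nrow(alus))) {
    a <- alus[i, ]
    ref <- if (a$strand == "+") "A" else "T"
    alt <- if (a$strand == "+") "G" else "C"
    win <- substring(genome[[a$chrom]], a$start, a$end)
    rel <- gregexpr(ref, win, fixed = TRUE)[[1]]
    if (rel[1] == -1) next
    sites <- a$start + as.integer(rel) - 1L
    sel <- pl$subject == a$chrom &
      pl$start <= a$end & pl$start + pl$width - 1L >= a$start
    p <- pl[sel, , drop = FALSE]
    s <- aln[sel]
    cov <- mm <- 0L; covered_sites <- 0L
    for (site in sites) {
      r <- site - p$start + 1L
      inside <- r >= 1L & r <= p$width
      if (!any(inside)) next
      b <- substr(s[inside], r[inside], r[inside])
      cov <- cov + length(b)
      mm <- mm + sum(b == alt)
      covered_sites <- covered_sites + 1L
    }
    per_alu <- rbind(per_alu, data.frame(
      alu_id = a$name, n_sites = length(sites),
      covered_sites = covered_sites, a_coverage = cov, g_mismatches = mm,
      expressed = covered_sites >= min_cov))
  }
  if (is.null(per_alu) || !any(per_alu$expressed))
    return(list(index = NA_real_, a_coverage = 0L, g_mismatches = 0L,
                per_alu = per_alu))
  ex <- per_alu[per_alu$expressed, ]
  cov <- sum(ex$a_coverage); mm <- sum(ex$g_mismatches)
  list(index = 100 * mm / cov, a_coverage = cov, g_mismatches = mm,
       per_alu = per_alu)
}

#' Paired t-test on per-sample editing-index differences
#'
#' @param index_a,index_b numeric vectors (same samples, e.g.
#'   deregulated-flank vs unaffected-flank scope)
#' @return list(t, df, p_value, mean_diff); identical pairs give t = 0 and
#'   p = 1 by convention
#' @export
compare_editing <- function(index_a, index_b) {
  stopifnot(length(index_a) == length(index_b))
  d <- index_a - index_b
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2 || sd(d) == 0)
    return(list(t = 0, df = max(0L, n - 1L),
                p_value = if (all(d == 0)) 1 else NA_real_,
                mean_diff = mean(d)))
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d))
}

#' Report expression values for designated genes unchanged (identity)
#'
#' Pass-through used e.g. to report ADAR enzyme expression alongside the
#' editing index.
#'
#' @param expr_table data.frame with a `gene` column
#' @param genes genes to report
#' @return the matching rows of `expr_table`, in `genes` order
#' @export
expression_passthrough <- function(expr_table, genes) {
  expr_table[match(genes, expr_table$gene), , drop = FALSE]
}
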