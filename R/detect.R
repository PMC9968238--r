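# Back-splice junction detection from paired-end reads.
#
# The caller follows the anchor strategy: mates that align contiguously to
# the genome are discarded; from each remaining mate two 20-nt anchors are
# taken and placed exactly on the genome (both strands, and for both read
# orientations since the library is unstranded).  A head-to-tail event is
# called when the 3'-end anchor lands upstream of the 5'-end anchor in the
# same strand space; the two anchor alignments are then extended toward each
# other until the whole read is explained as donor suffix + acceptor prefix,
# with the breakpoint placed so that the flanking dinucleotides are GT
# (donor) and AG (acceptor).

ANCHOR_LEN <- 20L

#' Trim adapter read-through and drop short pairs
#'
#' Clips the longest read suffix that is a prefix of `adapter` (exact match,
#' minimum overlap 5 nt) and removes pairs where either mate becomes shorter
#' than `min_len`.
#'
#' @param r1,r2 named character vectors of mate sequences
#' @param adapter adapter sequence
#' @param min_len minimum mate length after trimming
#' @return list(r1, r2)
#' @export
trim_adapters <- function(r1, r2,
                          adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                          min_len = 18L) {
  trim1 <- function(x) {
    L <- nchar(x)
    cut <- rep(0L, length(x))
    for (k in seq(min(max(L), nchar(adapter)), 5L)) {
      ap <- substr(adapter, 1, k)
      hit <- cut == 0L & k <= L & substr(x, L - k + 1L, L) == ap
      cut[hit] <- k
    }
    substr(x, 1, L - cut)
  }
  t1 <- trim1(r1); t2 <- trim1(r2)
  keep <- nchar(t1) >= min_len & nchar(t2) >= min_len
  list(r1 = t1[keep], r2 = t2[keep])
}

#' Remove exact duplicate and reverse-complement exact duplicate pairs
#'
#' A pair is removed iff its (seq1, seq2) equals, or is the mate-swapped
#' reverse complement of, an earlier retained pair.
#'
#' @param r1,r2 named character vectors of mate sequences
#' @return list(r1, r2)
#' @export
dedup_reads <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop("input error: r1 and r2 have different lengths")
  if (!length(r1)) return(list(r1 = r1, r2 = r2))
  key <- paste(r1, r2)
  rckey <- paste(revcomp(r2), revcomp(r1))
  canon <- pmin(key, rckey)
  keep <- !duplicated(canon)
  list(r1 = r1[keep], r2 = r2[keep])
}

#' Remove pairs matching contaminant sequences
#'
#' Drops a pair when either mate has a full-length contiguous alignment with
#' at most `max_mm` mismatches to any contaminant sequence (rRNA, tRNA, ...).
#'
#' @param r1,r2 named character vectors
#' @param contam_db named character vector of contaminant sequences (may be
#'   empty)
#' @param max_mm mismatch tolerance (default 1)
#' @return list(r1, r2)
#' @export
filter_contaminants <- function(r1, r2, contam_db = character(0),
                                max_mm = 1L) {
  if (!length(contam_db) || !length(r1)) return(list(r1 = r1, r2 = r2))
  mates <- c(setNames(r1, paste0(names(r1), "|1")),
             setNames(r2, paste0(names(r2), "|2")))
  pl <- align_linear(mates, contam_db, max_mm = max_mm)
  bad <- unique(sub("\\|[12]$", "", pl$read_id))
  keep <- !(names(r1) %in% bad)
  list(r1 = r1[keep], r2 = r2[keep])
}

#' Align mates to the genome and split linear pairs from BSJ candidates
#'
#' A mate "maps" iff it has a full-length contiguous alignment with at most
#' `max_mm` mismatches.  Pairs where both mates map are discarded as linear;
#' every unmapped mate of the remaining pairs proceeds to anchoring.
#'
#' @param r1,r2 named character vectors
#' @param genome named character vector of chromosome sequences
#' @param max_mm mismatch tolerance
#' @return list(candidates = named character vector of unmapped mates (names
#'   suffixed `/1` or `/2`), linear_pairs = character vector of discarded
#'   pair ids, placements = data.frame of all contiguous mate placements)
#' @export
align_and_split <- function(r1, r2, genome, max_mm = 2L) {
  mates <- c(setNames(r1, paste0(names(r1), "/1")),
             setNames(r2, paste0(names(r2), "/2")))
  pl <- align_linear(mates, genome, max_mm = max_mm)
  mapped <- unique(pl$read_id)
  m1 <- mapped[endsWith(mapped, "/1")]
  m2 <- mapped[endsWith(mapped, "/2")]
  both <- intersect(sub("/1$", "", m1), sub("/2$", "", m2))
  cand <- mates[!(names(mates) %in% mapped) &
                  !(sub("/[12]$", "", names(mates)) %in% both)]
  list(candidates = cand, linear_pairs = both, placements = pl)
}

# strand spaces: plus sequence and reverse complement of every chromosome,
# so that head-to-tail geometry and the GT/AG check are strand-uniform
make_spaces <- function(genome) {
  sp <- c(setNames(unname(genome), paste0(names(genome), "|+")),
          setNames(revcomp(unname(genome)), paste0(names(genome), "|-")))
  sp
}

#' Call back-splice junctions from candidate mates
#'
#' @param candidates named character vector of candidate mates (from
#'   [align_and_split()]); names must end in `/1` or `/2`
#' @param genome named character vector
#' @param max_mm total mismatch budget when extending the two anchors
#' @param max_hits anchors with more placements than this are capped (first
#'   `max_hits` kept) and marked non-unique
#' @return list(junctions = data.frame with one row per junction, support =
#'   data.frame linking junctions to supporting pairs)
#' @export
call_backsplice <- function(candidates, genome, max_mm = 2L, max_hits = 10L) {
  empty <- list(
    junctions = data.frame(
      junction_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), span = integer(0),
      n_reads = integer(0), n_unique_reads = integer(0),
      best_anchor_quality = integer(0), splice_signal = character(0)),
    support = data.frame(junction_id = character(0), pair_id = character(0),
                         mate = character(0), unique = logical(0)))
  candidates <- candidates[nchar(candidates) >= 2L * ANCHOR_LEN]
  if (!length(candidates)) return(empty)

  spaces <- make_spaces(genome)
  space_len <- setNames(nchar(spaces), names(spaces))

  ## anchors for both read orientations (unstranded library)
  n <- length(candidates)
  fwd <- unname(candidates)
  rev_ <- revcomp(fwd)
  L <- nchar(fwd)
  anchors <- c(
    setNames(substr(fwd, 1, ANCHOR_LEN), paste0(names(candidates), "|F5")),
    setNames(substr(fwd, L - ANCHOR_LEN + 1L, L),
             paste0(names(candidates), "|F3")),
    setNames(substr(rev_, 1, ANCHOR_LEN),
             paste0(names(candidates), "|R5")),
    setNames(substr(rev_, L - ANCHOR_LEN + 1L, L),
             paste0(names(candidates), "|R3")))
  hits <- match_anchors(anchors, spaces)
  if (!nrow(hits)) return(empty)

  ht <- data.table::as.data.table(hits)
  ht[, kind := substr(anchor_id, nchar(anchor_id) - 1L, nchar(anchor_id))]
  ht[, mate := substr(anchor_id, 1L, nchar(anchor_id) - 3L)]
  ht[, orient := substr(kind, 1, 1)]
  ht[, end5 := substr(kind, 2, 2) == "5"]
  nh <- ht[, .(nhit = .N), by = anchor_id]
  ht <- merge(ht, nh, by = "anchor_id")
  ht[, uniq := nhit == 1L]
  # cap pathological multi-mappers deterministically
  ht <- ht[order(anchor_id, space, start)]
  ht <- ht[, head(.SD, max_hits), by = anchor_id]

  h5 <- ht[end5 == TRUE, .(mate, orient, space, q5 = start, uniq5 = uniq)]
  h3 <- ht[end5 == FALSE, .(mate, orient, space, q3 = start, uniq3 = uniq)]
  pairs <- merge(h5, h3, by = c("mate", "orient", "space"),
                 allow.cartesian = TRUE)
  pairs <- pairs[q3 < q5 & q5 - q3 < 100000L + max(L)]
  if (!nrow(pairs)) return(empty)

  mate_seq <- setNames(fwd, names(candidates))
  mate_rc <- setNames(rev_, names(candidates))

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i]
    R <- if (p$orient == "F") mate_seq[[p$mate]] else mate_rc[[p$mate]]
    Lr <- nchar(R)
    X <- spaces[[p$space]]
    N <- space_len[[p$space]]
    q5 <- p$q5; q3 <- p$q3
    as0 <- q3 + ANCHOR_LEN - Lr            # acceptor window offset - 1
    b_lo <- max(ANCHOR_LEN, 3L - as0)
    b_hi <- min(Lr - ANCHOR_LEN, N - q5 - 1L)
    if (b_lo > b_hi) next
    Rv <- strsplit(R, "")[[1]]
    Dv <- strsplit(substr(X, q5, q5 + Lr - 1L), "")[[1]]
    Av <- strsplit(substr(X, max(1L, as0), as0 + Lr - 1L), "")[[1]]
    if (as0 < 1L) Av <- c(rep("N", 1L - as0), Av)
    if (length(Dv) < Lr) Dv <- c(Dv, rep("N", Lr - length(Dv)))
    cum_d <- cumsum(Rv != Dv)
    suf_a <- rev(cumsum(rev(Rv != Av)))
    suf_a <- c(suf_a, 0L)
    b <- seq(b_lo, b_hi)
    mm <- cum_d[b] + suf_a[b + 1L]
    dsig <- substring(X, q5 + b, q5 + b + 1L)
    asig <- substring(X, as0 + b - 2L, as0 + b - 1L)
    ok <- mm <= max_mm & dsig == "GT" & asig == "AG"
    if (!any(ok)) next
    # maximize acceptor-side match length = smallest breakpoint
    bb <- b[ok][1]
    rows[[i]] <- data.frame(
      mate = p$mate, space = p$space,
      s0 = as0 + bb, e0 = q5 + bb - 1L,
      mm = mm[ok][1], bp = bb,
      uniq = p$uniq5 && p$uniq3,
      qual = if (p$uniq5 && p$uniq3) 40L else 3L)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  ev <- do.call(rbind, rows)

  ## space coordinates -> plus-strand genomic coordinates
  ev$chrom <- substr(ev$space, 1L, nchar(ev$space) - 2L)
  ev$strand <- substr(ev$space, nchar(ev$space), nchar(ev$space))
  N <- space_len[ev$space]
  minus <- ev$strand == "-"
  start <- ifelse(minus, N - ev$e0 + 1L, ev$s0)
  end <- ifelse(minus, N - ev$s0 + 1L, ev$e0)
  ev$start <- as.integer(start); ev$end <- as.integer(end)

  ## best event per mate: fewest mismatches, longest acceptor side (smallest
  ## breakpoint), then smallest start coordinate
  ev <- ev[order(ev$mate, ev$mm, ev$bp, ev$start, ev$end), ]
  ev <- ev[!duplicated(ev$mate), ]

  ev$pair_id <- sub("/[12]$", "", ev$mate)
  ev$junction_id <- junction_id(ev$chrom, ev$start, ev$end, ev$strand)
  ## one vote per pair; a pair is unique iff its calling mate used two
  ## uniquely placed anchors
  pr <- ev[order(ev$pair_id, -ev$uniq), ]
  pr <- pr[!duplicated(paste(pr$pair_id, pr$junction_id)), ]

  agg <- data.table::as.data.table(pr)[, .(
    chrom = chrom[1], start = start[1], end = end[1], strand = strand[1],
    n_reads = .N, n_unique_reads = sum(uniq),
    best_anchor_quality = max(qual)), by = junction_id]
  agg[, `:=`(span = end - start + 1L, splice_signal = "GTAG")]
  junctions <- as.data.frame(agg)
  junctions <- junctions[order(junctions$chrom, junctions$start,
                               junctions$end), ]
  rownames(junctions) <- NULL
  support <- data.frame(junction_id = pr$junction_id, pair_id = pr$pair_id,
                        mate = pr$mate, unique = pr$uniq)
  list(junctions = junctions, support = support)
}

#' Merge per-sample junction calls into one tested set
#'
#' Union by junction id; support statistics keep the per-sample maximum.
#'
#' @param junction_list list of junction data.frames
#' @return merged junction data.frame
#' @export
merge_junction_calls <- function(junction_list) {
  all <- do.call(rbind, junction_list)
  if (!nrow(all)) return(all)
  dt <- data.table::as.data.table(all)
  keep_first <- setdiff(names(all), c("junction_id", "n_reads",
                                      "n_unique_reads",
                                      "best_anchor_quality"))
  agg <- dt[, c(.SD[1, keep_first, with = FALSE],
                .(n_reads = max(n_reads),
                  n_unique_reads = max(n_unique_reads),
                  best_anchor_quality = max(best_anchor_quality))),
            by = junction_id]
  out <- as.data.frame(agg)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Filter junctions on support, span and anchor quality
#'
#' Keeps junctions with at least `min_unique` unique supporting pairs, a
#' span below `max_span` and a best anchor quality of at least `min_qual`
#' (unique anchors score 40, multi-placed anchors 3, so the default 35 means
#' "both anchors uniquely placed").
#'
#' @param junctions junction data.frame from [call_backsplice()]
#' @param min_unique,max_span,min_qual filter thresholds
#' @return filtered junction data.frame
#' @export
filter_junctions <- function(junctions, min_unique = 2L, max_span = 100000L,
                             min_qual = 35L) {
  keep <- junctions$n_unique_reads >= min_unique &
    junctions$span < max_span &
    junctions$best_anchor_quality >= min_qual
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads supporting linear splicing at the two junction boundaries
#'
#' For each junction boundary, counts mates whose linear (spliced,
#' transcript-space) alignment crosses that genomic coordinate: for the
#' acceptor boundary, reads spliced from the upstream exon into the first
#' circularised exon; for the donor boundary, reads spliced out of the last
#' circularised exon.  Back-splice-spanning mates have no linear alignment
#' and contribute zero.
#'
#' @param junctions filtered junction data.frame
#' @param candidates candidate mates from [align_and_split()] (only spliced
#'   mates can cross a boundary)
#' @param genome named character vector
#' @param model gene model (see [read_gtf()])
#' @param max_mm mismatch tolerance
#' @return data.frame(junction_id, linear_acceptor, linear_donor, linear)
#' @export
count_linear_support <- function(junctions, candidates, genome, model,
                                 max_mm = 2L) {
  out <- data.frame(junction_id = junctions$junction_id,
                    linear_acceptor = 0L, linear_donor = 0L)
  if (!nrow(junctions) || !length(candidates)) {
    out$linear <- out$linear_acceptor + out$linear_donor
    return(out)
  }
  txs <- unique(model$exons$tx_id)
  tx_seqs <- setNames(vapply(txs, function(tx)
    tx_sequence(model, tx, genome), character(1)), txs)
  pl <- align_linear(candidates, tx_seqs, max_mm = max_mm)
  if (!nrow(pl)) {
    out$linear <- out$linear_acceptor + out$linear_donor
    return(out)
  }
  for (j in seq_len(nrow(junctions))) {
    jr <- junctions[j, ]
    for (side in c("acceptor", "donor")) {
      B <- if (side == "acceptor") jr$start else jr$end
      crossing <- character(0)
      for (tx in txs) {
        ex <- tx_exons(model, tx)
        ex <- ex[ex$chrom == jr$chrom, ]
        if (!nrow(ex)) next
        exs <- ex[order(ex$start), ]
        hit <- if (side == "acceptor") which(exs$start == B)
               else which(exs$end == B)
        if (!length(hit)) next
        tmap <- genomic_to_tx(exs, B, B)
        if (!nrow(tmap)) next
        t1 <- tmap$tstart[1]
        strand <- exs$strand[1]
        # transcript position adjacent to the splice site, in the
        # genomically outward exon
        t0 <- if (side == "acceptor") {
          if (strand == "+") t1 - 1L else t1 + 1L
        } else {
          if (strand == "+") t1 + 1L else t1 - 1L
        }
        tx_len <- sum(exs$end - exs$start + 1L)
        if (t0 < 1L || t0 > tx_len) next
        p <- pl[pl$subject == tx, , drop = FALSE]
        if (!nrow(p)) next
        lo <- pmin(t0, t1); hi <- pmax(t0, t1)
        cross <- p$start <= lo & p$start + p$width - 1L >= hi
        crossing <- union(crossing, p$read_id[cross])
      }
      if (side == "acceptor") out$linear_acceptor[j] <- length(crossing)
      else out$linear_donor[j] <- length(crossing)
    }
  }
  out$linear <- out$linear_acceptor + out$linear_donor
  out
}

#' Annotate junctions with host genes and drop cross-gene artifacts
#'
#' Each junction is labelled with its host gene(s) and host biotype
#' (protein-coding, non-coding, or "no gene" for intergenic events).
#' Junctions whose two boundaries fall in two genes that do not overlap each
#' other are removed as likely mapping errors; intergenic junctions are
#' retained.
#'
#' @param junctions junction data.frame
#' @param model gene model
#' @return junction data.frame with host_gene, host_tx and host_biotype
#'   columns; artifact rows removed
#' @export
annotate_junctions <- function(junctions, model) {
  ex <- model$exons
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               tx_id = d$tx_id[1], biotype = d$biotype[1])))
  host_gene <- character(nrow(junctions))
  host_tx <- character(nrow(junctions))
  host_biotype <- character(nrow(junctions))
  drop <- logical(nrow(junctions))
  for (j in seq_len(nrow(junctions))) {
    jr <- junctions[j, ]
    g1 <- genes[genes$chrom == jr$chrom & genes$start <= jr$start &
                  genes$end >= jr$start, , drop = FALSE]
    g2 <- genes[genes$chrom == jr$chrom & genes$start <= jr$end &
                  genes$end >= jr$end, , drop = FALSE]
    common <- intersect(g1$gene_id, g2$gene_id)
    if (length(common)) {
      host_gene[j] <- paste(common, collapse = ",")
      host_tx[j] <- paste(genes$tx_id[match(common, genes$gene_id)],
                          collapse = ",")
      bt <- genes$biotype[match(common[1], genes$gene_id)]
      host_biotype[j] <- if (bt == "protein_coding") "protein-coding"
                         else "non-coding"
    } else if (nrow(g1) && nrow(g2)) {
      # boundaries in two distinct genes: keep only if those genes overlap
      olap <- FALSE
      for (a in seq_len(nrow(g1))) for (b in seq_len(nrow(g2)))
        if (intervals_overlap(g1$start[a], g1$end[a], g2$start[b], g2$end[b]))
          olap <- TRUE
      if (!olap) drop[j] <- TRUE
      host_gene[j] <- paste(unique(c(g1$gene_id, g2$gene_id)), collapse = ",")
      host_tx[j] <- paste(unique(c(g1$tx_id, g2$tx_id)), collapse = ",")
      host_biotype[j] <- "protein-coding"
    } else {
      host_gene[j] <- ""
      host_tx[j] <- ""
      host_biotype[j] <- "no gene"
    }
  }
  out <- junctions
  out$host_gene <- host_gene
  out$host_tx <- host_tx
  out$host_biotype <- host_biotype
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full per-sample detection pipeline
#'
#' Trimming, duplicate removal, contaminant filtering, linear splitting,
#' anchor-based back-splice calling, junction filtering, linear-support
#' counting and host-gene annotation.
#'
#' @param r1,r2 named character vectors of raw mate sequences
#' @param genome named character vector
#' @param model gene model
#' @param contam_db optional contaminant sequences
#' @param adapter adapter sequence for trimming
#' @param max_mm,max_hits,min_unique,max_span,min_qual see the stage
#'   functions
#' @return list(junctions, support, counts, placements, candidates)
#' @export
detect_circrnas <- function(r1, r2, genome, model,
                            contam_db = character(0),
                            adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            max_mm = 2L, max_hits = 10L, min_unique = 2L,
                            max_span = 100000L, min_qual = 35L) {
  tr <- trim_adapters(r1, r2, adapter)
  dd <- dedup_reads(tr$r1, tr$r2)
  fc <- filter_contaminants(dd$r1, dd$r2, contam_db)
  sp <- align_and_split(fc$r1, fc$r2, genome, max_mm = max_mm)
  bs <- call_backsplice(sp$candidates, genome, max_mm = max_mm,
                        max_hits = max_hits)
  junctions <- filter_junctions(bs$junctions, min_unique = min_unique,
                                max_span = max_span, min_qual = min_qual)
  junctions <- annotate_junctions(junctions, model)
  lin <- count_linear_support(junctions, sp$candidates, genome, model,
                              max_mm = max_mm)
  counts <- merge(
    data.frame(junction_id = junctions$junction_id,
               circ = junctions$n_reads), lin, by = "junction_id")
  support <- bs$support[bs$support$junction_id %in% junctions$junction_id, ]
  list(junctions = junctions, support = support, counts = counts,
       placements = sp$placements, candidates = sp$candidates,
       reads = list(r1 = fc$r1, r2 = fc$r2))
}
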