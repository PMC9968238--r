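# Host-region classification of circRNAs and the faux-circRNA localization
# null: circRNAs are compared against randomly sampled runs of consecutive
# internal exons (matched on the exon-count distribution) with a chi-squared
# test over the observed region-combination categories.

# transcript-space CDS range (c1, c2) or NULL for non-coding transcripts
tx_cds_range <- function(model, tx) {
  cd <- model$cds[model$cds$tx_id == tx, , drop = FALSE]
  if (!nrow(cd)) return(NULL)
  ex <- tx_exons(model, tx)
  exs <- ex[order(ex$start), ]
  rng <- range(unlist(lapply(seq_len(nrow(cd)), function(i) {
    m <- genomic_to_tx(exs, cd$start[i], cd$end[i])
    c(m$tstart, m$tend)
  })))
  rng
}

#' Classify circRNA localization relative to host-transcript regions
#'
#' Flags record which region types (5UTR, CDS, 3UTR) the circRNA's exonic
#' content overlaps in its host transcript(s); the INTRON flag is set when a
#' back-splice boundary falls inside an intron (retained intronic sequence).
#' Non-coding hosts contribute no UTR/CDS flags.
#'
#' @param circs data.frame with circ_id, chrom, start, end and host_tx
#'   (comma-separated transcript ids)
#' @param model gene model
#' @return data.frame(circ_id, utr5, cds, utr3, intron, category)
#' @export
classify_regions <- function(circs, model) {
  out <- data.frame(circ_id = circs$circ_id, utr5 = FALSE, cds = FALSE,
                    utr3 = FALSE, intron = FALSE)
  cache <- new.env(parent = emptyenv())
  tx_info <- function(tx) {
    if (!is.null(cache[[tx]])) return(cache[[tx]])
    ex <- tx_exons(model, tx)
    info <- if (!nrow(ex)) NULL else
      list(exs = ex[order(ex$start), ],
           chrom = ex$chrom[1],
           tx_len = sum(ex$end - ex$start + 1L),
           cds = tx_cds_range(model, tx))
    cache[[tx]] <- info
    info
  }
  for (i in seq_len(nrow(circs))) {
    txs <- strsplit(circs$host_tx[i], ",")[[1]]
    txs <- txs[nzchar(txs)]
    for (tx in txs) {
      info <- tx_info(tx)
      if (is.null(info) || info$chrom != circs$chrom[i]) next
      exs <- info$exs
      s <- circs$start[i]; e <- circs$end[i]
      in_exon <- function(p) any(exs$start <= p & exs$end >= p)
      within_gene <- s >= min(exs$start) && e <= max(exs$end)
      if (within_gene && (!in_exon(s) || !in_exon(e)))
        out$intron[i] <- TRUE
      tmap <- genomic_to_tx(exs, s, e)
      if (!nrow(tmap)) next
      rng <- info$cds
      if (is.null(rng)) next
      hit <- function(lo, hi) lo <= hi &&
        any(tmap$tstart <= hi & tmap$tend >= lo)
      if (hit(1L, rng[1] - 1L)) out$utr5[i] <- TRUE
      if (hit(rng[1], rng[2])) out$cds[i] <- TRUE
      if (hit(rng[2] + 1L, info$tx_len)) out$utr3[i] <- TRUE
    }
  }
  flags <- c("5UTR", "CDS", "3UTR", "INTRON")
  out$category <- apply(out[, c("utr5", "cds", "utr3", "intron")], 1,
                        function(r) {
                          k <- flags[as.logical(r)]
                          if (!length(k)) "none" else
                            paste(k, collapse = "+")
                        })
  out
}

#' Exon counts of circRNAs (averaged over compatible isoforms)
#'
#' A transcript is compatible when one of its exons starts at the circRNA's
#' acceptor boundary and one ends at its donor boundary.  CircRNAs whose
#' boundaries fall in an intron or outside a gene yield NA and are excluded
#' from the returned distribution.  Multi-isoform counts are averaged and
#' rounded half up.
#'
#' @param circs data.frame with circ_id, chrom, start, end, host_tx
#' @param model gene model
#' @return list(per_circ = data.frame(circ_id, n_exons), dist = named
#'   probability table over exon counts)
#' @export
exon_count_distribution <- function(circs, model) {
  n <- rep(NA_real_, nrow(circs))
  for (i in seq_len(nrow(circs))) {
    txs <- strsplit(circs$host_tx[i], ",")[[1]]
    txs <- txs[nzchar(txs)]
    counts <- c()
    for (tx in txs) {
      ex <- tx_exons(model, tx)
      if (!nrow(ex) || ex$chrom[1] != circs$chrom[i]) next
      s <- circs$start[i]; e <- circs$end[i]
      if (any(ex$start == s) && any(ex$end == e))
        counts <- c(counts, sum(ex$start >= s & ex$end <= e))
    }
    if (length(counts)) n[i] <- floor(mean(counts) + 0.5)  # round half up
  }
  per_circ <- data.frame(circ_id = circs$circ_id, n_exons = n)
  ok <- !is.na(n)
  tab <- table(factor(n[ok]))
  list(per_circ = per_circ, dist = tab / sum(tab))
}

#' Sample faux circRNAs: random runs of consecutive internal exons
#'
#' Draws `n` runs of consecutive internal exons (never the first or last
#' exon) from the circRNA-hosting transcripts, with the run length sampled
#' from `dist`.  A drawn length that no host can accommodate is redrawn,
#' preserving the distribution's support.
#'
#' @param model gene model
#' @param host_txs character vector of host transcript ids
#' @param dist named probability table over exon counts (names = counts)
#' @param n number of draws (5000 in the reference procedure)
#' @param seed RNG seed
#' @return data.frame(tx_id, first_exon, n_exons, chrom, start, end,
#'   host_tx)
#' @export
sample_faux_circs <- function(model, host_txs, dist, n = 5000L, seed = 7L) {
  set.seed(seed)
  host_txs <- unique(host_txs)
  ks <- as.integer(names(dist))
  exlist <- lapply(host_txs, function(tx) tx_exons(model, tx))
  names(exlist) <- host_txs
  nex <- vapply(exlist, nrow, integer(1))
  eligible <- lapply(ks, function(k) host_txs[nex >= k + 2L])
  names(eligible) <- as.character(ks)
  if (!any(lengths(eligible) > 0))
    stop("no host transcript can accommodate any drawn exon count")
  tx_v <- character(n); first_v <- k_v <- st_v <- en_v <- integer(n)
  chrom_v <- character(n)
  for (i in seq_len(n)) {
    repeat {
      k <- ks[sample.int(length(ks), 1, prob = as.numeric(dist))]
      el <- eligible[[as.character(k)]]
      if (length(el)) break
    }
    tx <- el[sample.int(length(el), 1)]
    ex <- exlist[[tx]]
    first <- 1L + sample.int(nrow(ex) - k - 1L, 1)  # in 2..(nex - k)
    run <- ex$exon_rank >= first & ex$exon_rank <= first + k - 1L
    tx_v[i] <- tx; first_v[i] <- first; k_v[i] <- k
    chrom_v[i] <- ex$chrom[1]
    st_v[i] <- min(ex$start[run]); en_v[i] <- max(ex$end[run])
  }
  out <- data.frame(tx_id = tx_v, first_exon = first_v, n_exons = k_v,
                    chrom = chrom_v, start = st_v, end = en_v)
  out$circ_id <- sprintf("faux_%04d", seq_len(n))
  out$host_tx <- out$tx_id
  out
}

#' Chi-squared test of localization preference (real vs faux circRNAs)
#'
#' Builds a 2 x k contingency table of region-combination categories
#' (restricted to combinations observed in either set) and performs a
#' chi-squared test with k - 1 degrees of freedom.
#'
#' @param real,faux data.frames from [classify_regions()] (need `category`)
#' @return list(statistic, df, p_value, table)
#' @export
localization_test <- function(real, faux) {
  stopifnot(nrow(real) > 0, nrow(faux) > 0)
  cats <- sort(union(unique(real$category), unique(faux$category)))
  O <- rbind(real = as.integer(table(factor(real$category, levels = cats))),
             faux = as.integer(table(factor(faux$category, levels = cats))))
  colnames(O) <- cats
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  use <- E > 0
  stat <- sum((O[use] - E[use])^2 / E[use])
  df <- length(cats) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, table = O)
}
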