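# Seed-and-verify read placement against small genomes / transcript sets.
#
# A full gapped aligner is out of scope: reads are first placed by exact
# full-length matching (one PDict pass with a trusted band, which handles
# variable read lengths), and the remainder by exact matching of pigeonhole
# segments (a read with <= max_mm mismatches must contain at least one exact
# segment out of max_mm + 1) followed by vectorised mismatch verification of
# the full-length contiguous alignment.  This realises the "maps / does not
# map, unique / multi" contract that the downstream junction caller consumes.

#' Place reads on a set of reference sequences
#'
#' Finds full-length contiguous alignments of each read with at most
#' `max_mm` mismatches, on both strands.  No indels are considered.  For
#' reads with an exact placement only exact placements are reported.
#'
#' @param reads named character vector of read sequences
#' @param subjects named character vector of reference sequences
#' @param max_mm maximum mismatches for a valid placement
#' @param both_strands also search the reverse strand
#' @return data.frame with columns read_id, subject, start (1-based,
#'   plus-strand), strand, nmm, width
#' @export
align_linear <- function(reads, subjects, max_mm = 2, both_strands = TRUE) {
  empty <- data.frame(read_id = character(0), subject = character(0),
                      start = integer(0), strand = character(0),
                      nmm = integer(0), width = integer(0))
  if (length(reads) == 0 || length(subjects) == 0) return(empty)
  stopifnot(!is.null(names(reads)), !is.null(names(subjects)))

  spaces <- data.frame(subject = names(subjects), strand = "+",
                       seq = unname(subjects))
  if (both_strands)
    spaces <- rbind(spaces,
                    data.frame(subject = names(subjects), strand = "-",
                               seq = revcomp(unname(subjects))))
  subj_dna <- lapply(spaces$seq, Biostrings::DNAString)
  subj_len <- nchar(spaces$seq)
  widths <- nchar(reads)
  out <- list()

  ## ---- pass 1: exact full-length placements (all widths at once) ----------
  all_set <- Biostrings::DNAStringSet(unname(reads))
  tb <- min(widths)
  pd0 <- Biostrings::PDict(all_set, tb.start = 1L, tb.end = tb)
  exact_hit <- logical(length(reads))
  for (sp in seq_len(nrow(spaces))) {
    mi <- Biostrings::matchPDict(pd0, subj_dna[[sp]], max.mismatch = 0)
    si <- Biostrings::startIndex(mi)
    nh <- lengths(si)
    if (sum(nh) == 0) next
    pat <- rep(seq_along(si), nh)
    st <- unlist(si, use.names = FALSE)
    w <- widths[pat]
    ok <- st >= 1L & st + w - 1L <= subj_len[sp]
    pat <- pat[ok]; st <- st[ok]; w <- w[ok]
    if (!length(pat)) next
    if (spaces$strand[sp] == "-")
      st <- subj_len[sp] - (st + w - 1L) + 1L
    exact_hit[unique(pat)] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      read_id = names(reads)[pat], subject = spaces$subject[sp],
      start = st, strand = spaces$strand[sp], nmm = 0L, width = w)
  }

  ## ---- pass 2: seeded mismatch search for reads without an exact hit ------
  ## fixed-width 18-nt seeds at pigeonhole block starts: one PDict for all
  ## remaining reads regardless of their length
  seedw <- 18L
  if (max_mm > 0 && !all(exact_hit)) {
    rest <- which(!exact_hit)
    rw <- widths[rest]
    nblk <- pmax(1L, pmin(max_mm + 1L, rw %/% seedw))
    seed_read <- rep(rest, nblk)
    blk <- sequence(nblk)
    wv <- rep(rw, nblk)
    nblk_rep <- rep(nblk, nblk)
    seed_off <- as.integer(floor((blk - 1L) * wv / nblk_rep))
    seed_start <- seed_off + 1L
    seeds <- substr(unname(reads[seed_read]), seed_start,
                    seed_start + seedw - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (sp in seq_len(nrow(spaces))) {
      mi <- Biostrings::matchPDict(pd, subj_dna[[sp]])
      si <- Biostrings::startIndex(mi)
      nh <- lengths(si)
      if (sum(nh) == 0) next
      pat <- rep(seq_along(si), nh)
      pos <- unlist(si, use.names = FALSE)
      cand_read <- seed_read[pat]
      cand_start <- pos - seed_off[pat]
      w <- widths[cand_read]
      ok <- cand_start >= 1L & cand_start + w - 1L <= subj_len[sp]
      cand_read <- cand_read[ok]; cand_start <- cand_start[ok]
      if (!length(cand_read)) next
      key <- paste(cand_read, cand_start)
      keep <- !duplicated(key)
      cand_read <- cand_read[keep]; cand_start <- cand_start[keep]
      w <- widths[cand_read]
      for (ww in unique(w)) {
        ci <- which(w == ww)
        win <- Biostrings::extractAt(
          subj_dna[[sp]],
          IRanges::IRanges(start = cand_start[ci], width = ww))
        wm <- as.matrix(win)
        qm <- as.matrix(Biostrings::DNAStringSet(
          unname(reads[cand_read[ci]])))
        nmm <- rowSums(wm != qm)
        hit <- which(nmm > 0 & nmm <= max_mm)
        if (!length(hit)) next
        st <- cand_start[ci][hit]
        if (spaces$strand[sp] == "-")
          st <- subj_len[sp] - (st + ww - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          read_id = names(reads)[cand_read[ci][hit]],
          subject = spaces$subject[sp],
          start = st,
          strand = spaces$strand[sp],
          nmm = as.integer(nmm[hit]),
          width = ww)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact placements of fixed-width anchors on one strand space
#'
#' Anchors are matched exactly (find_circ-style seeding).  The search is done
#' per "space": the plus strand of each reference sequence and its reverse
#' complement, with positions reported in space-local coordinates so that the
#' head-to-tail geometry test is identical on both strands.
#'
#' @param anchors named character vector, all the same width
#' @param space_seqs named character vector of space sequences
#' @return data.frame(anchor_id, space, start)
#' @keywords internal
match_anchors <- function(anchors, space_seqs) {
  empty <- data.frame(anchor_id = character(0), space = character(0),
                      start = integer(0))
  if (!length(anchors)) return(empty)
  stopifnot(length(unique(nchar(anchors))) == 1)
  pd <- Biostrings::PDict(unname(Biostrings::DNAStringSet(anchors)))
  out <- list()
  for (sp in names(space_seqs)) {
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(space_seqs[[sp]]))
    si <- Biostrings::startIndex(mi)
    nh <- lengths(si)
    if (sum(nh) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      anchor_id = rep(names(anchors), nh),
      space = sp,
      start = unlist(si, use.names = FALSE))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
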