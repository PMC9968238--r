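# Low-level helpers: sequence arithmetic, file formats, gene-model tables.
# Internal coordinates are 1-based closed (IRanges convention); BED I/O
# converts to/from 0-based half-open at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#' @param x character vector of DNA sequences
#' @return character vector of the same length
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substring replacement keeping length
seq_replace <- function(seq, at, replacement) {
  stopifnot(at >= 1, at + nchar(replacement) - 1 <= nchar(seq))
  paste0(substr(seq, 1, at - 1), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

## ---- FASTA / FASTQ ---------------------------------------------------------

#' Write sequences as wrapped FASTA text
#' @param seqs named character vector
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 60) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param seqs named character vector of read sequences
#' @param path output file
#' @export
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path input file
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

## ---- BED6 ------------------------------------------------------------------

#' Write a BED6 data.frame (internal 1-based closed -> 0-based half-open)
#' @param df data.frame with chrom, start, end, name, score, strand
#' @param path output file
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = df$name, score = df$score, strand = df$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 into internal 1-based closed coordinates
#' @param path input file
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  df <- read.delim(path, header = FALSE)
  df <- df[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  df$chrom <- as.character(df$chrom)
  df$name <- as.character(df$name)
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

## ---- GTF and gene models ---------------------------------------------------

# The internal gene model is a list with:
#   exons: data.frame(gene_id, tx_id, chrom, start, end, strand, exon_rank,
#                     biotype)   [exon_rank in transcript 5'->3' order]
#   cds:   data.frame(tx_id, chrom, start, end, strand)  (may be empty)

#' Write a gene model as GTF2.2
#' @param model gene model list (see package internals)
#' @param path output file
#' @export
write_gtf <- function(model, path) {
  ex <- model$exons
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                      ex$gene_id, ex$tx_id, ex$biotype)
  lines <- sprintf("%s\tcircfus\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start, ex$end, ex$strand, attr_str)
  if (nrow(model$cds)) {
    cd <- model$cds
    bt <- ex$biotype[match(cd$tx_id, ex$tx_id)]
    gid <- ex$gene_id[match(cd$tx_id, ex$tx_id)]
    cdl <- sprintf("%s\tcircfus\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                   cd$chrom, cd$start, cd$end, cd$strand,
                   sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                           gid, cd$tx_id, bt))
    lines <- c(lines, cdl)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF file into the internal gene model
#' @param path input file
#' @export
read_gtf <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    stop("malformed GTF at line ", bad[1])
  m <- do.call(rbind, f)
  get_attr <- function(a, key) {
    out <- sub(sprintf('.*%s "([^"]*)".*', key), "\\1", a)
    out[!grepl(sprintf('%s "', key), a, fixed = TRUE)] <- NA_character_
    out
  }
  df <- data.frame(chrom = m[, 1], type = m[, 3],
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7],
                   gene_id = get_attr(m[, 9], "gene_id"),
                   tx_id = get_attr(m[, 9], "transcript_id"),
                   biotype = get_attr(m[, 9], "gene_biotype"))
  ex <- df[df$type == "exon", ]
  # exon_rank: 5'->3' along the transcript
  ex <- ex[order(ex$tx_id, ex$start), ]
  rank_fun <- function(i) {
    if (ex$strand[i[1]] == "+") seq_along(i) else rev(seq_along(i))
  }
  idx <- split(seq_len(nrow(ex)), ex$tx_id)
  ex$exon_rank <- NA_integer_
  for (i in idx) ex$exon_rank[i] <- rank_fun(i)
  ex$biotype[is.na(ex$biotype)] <- "protein_coding"
  cds <- df[df$type == "CDS", c("tx_id", "chrom", "start", "end", "strand")]
  list(exons = ex[, c("gene_id", "tx_id", "chrom", "start", "end",
                      "strand", "exon_rank", "biotype")],
       cds = cds)
}

# exons of one transcript in transcript (5'->3') order
tx_exons <- function(model, tx) {
  ex <- model$exons[model$exons$tx_id == tx, ]
  ex[order(ex$exon_rank), ]
}

# spliced transcript sequence (transcript strand)
tx_sequence <- function(model, tx, genome) {
  ex <- tx_exons(model, tx)
  ex <- ex[order(ex$start), ]
  seq <- paste(substring(genome[[ex$chrom[1]]], ex$start, ex$end),
               collapse = "")
  if (ex$strand[1] == "-") seq <- revcomp(seq) else seq
}

# genomic interval [start,end] -> transcript coordinate intervals
# returns data.frame(tstart, tend) of the spliced positions covered
genomic_to_tx <- function(ex_sorted, start, end) {
  # ex_sorted: exons ordered by genomic start; strand constant
  strand <- ex_sorted$strand[1]
  widths <- ex_sorted$end - ex_sorted$start + 1L
  n <- nrow(ex_sorted)
  if (strand == "+") {
    offs <- cumsum(c(0L, widths[-n]))
  } else {
    offs <- rev(cumsum(c(0L, rev(widths)[-n])))
  }
  s <- pmax(start, ex_sorted$start)
  e <- pmin(end, ex_sorted$end)
  keep <- which(s <= e)
  if (!length(keep))
    return(data.frame(tstart = integer(0), tend = integer(0)))
  if (strand == "+") {
    ts <- offs[keep] + (s[keep] - ex_sorted$start[keep]) + 1L
    te <- offs[keep] + (e[keep] - ex_sorted$start[keep]) + 1L
  } else {
    ts <- offs[keep] + (ex_sorted$end[keep] - e[keep]) + 1L
    te <- offs[keep] + (ex_sorted$end[keep] - s[keep]) + 1L
  }
  res <- data.frame(tstart = ts, tend = te)
  res[order(res$tstart), , drop = FALSE]
}

# simple half-open-free overlap test on 1-based closed intervals
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

## ---- misc ------------------------------------------------------------------

# deterministic seed derivation kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * k) %% 2147483647)
}

junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d_%s", chrom, start, end, strand)
}
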