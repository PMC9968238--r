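# Detection: trimming, duplicate removal, contaminant filtering, linear
# splitting, the anchor back-splice caller, junction filters, linear support
# and host annotation.

# hand-made single-gene world: n_ex exons of exon_len nt, introns with GT/AG
# on the plus strand, flanked by pad nt of intergenic sequence
make_toy_gene <- function(seed = 42, n_ex = 5, exon_len = 200,
                          intron_len = 300, pad = 500, strand = "+") {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  ex <- replicate(n_ex, rnd(exon_len))
  it <- replicate(n_ex - 1, rnd(intron_len))
  for (i in seq_along(it)) {
    substr(it[i], 1, 2) <- "GT"
    substr(it[i], intron_len - 1, intron_len) <- "AG"
  }
  pieces <- character(2 * n_ex - 1)
  pieces[seq(1, 2 * n_ex - 1, 2)] <- ex
  if (n_ex > 1) pieces[seq(2, 2 * n_ex - 1, 2)] <- it
  gene <- paste(pieces, collapse = "")
  gplus <- if (strand == "+") gene else revcomp(gene)
  genome <- c(chrT = paste0(rnd(pad), gplus, rnd(pad)))
  off <- cumsum(c(0, nchar(pieces)[-length(pieces)]))
  ex_off_gene <- off[seq(1, 2 * n_ex - 1, 2)] + 1L
  glen <- nchar(gene)
  g2p <- function(o, len) {
    if (strand == "+") c(pad + o, pad + o + len - 1L)
    else c(pad + glen - (o + len - 1L) + 1L, pad + glen - o + 1L)
  }
  iv <- t(vapply(ex_off_gene, g2p, numeric(2), len = exon_len))
  exons <- data.frame(gene_id = "gT", tx_id = "txT", chrom = "chrT",
                      start = as.integer(iv[, 1]), end = as.integer(iv[, 2]),
                      strand = strand, exon_rank = seq_len(n_ex),
                      biotype = "protein_coding")
  list(genome = genome, model = toy_model(exons), ex_seq = ex,
       exons = exons[order(exons$start), ])
}

test_that("adapter trimming clips read-through and drops short mates", {
  ad <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  ins <- strrep("ACGT", 10)
  r1 <- c(a = paste0(ins, substr(ad, 1, 30)), b = strrep("ACGT", 25))
  r2 <- c(a = paste0(revcomp(ins), substr(ad, 1, 30)),
          b = strrep("TGCA", 25))
  tr <- trim_adapters(r1, r2, ad)
  expect_identical(unname(tr$r1["a"]), ins)
  expect_identical(unname(tr$r2["a"]), revcomp(ins))
  expect_identical(unname(tr$r1["b"]), unname(r1["b"]))  # untouched
  # trimming below 18 nt drops the pair
  r1s <- c(x = paste0("ACGTACGTACGTACGT", substr(ad, 1, 34)))
  r2s <- c(x = strrep("ACGT", 10))
  expect_length(trim_adapters(r1s, r2s, ad)$r1, 0)
})

test_that("dedup removes exact and mate-swapped reverse-complement copies", {
  a1 <- "ACGTACGTACGTACGTACGT"; a2 <- "TTTTCCCCGGGGAAAATTTT"
  r1 <- c(p1 = a1, p2 = a1, p3 = revcomp(a2))
  r2 <- c(p1 = a2, p2 = a2, p3 = revcomp(a1))
  dd <- dedup_reads(r1, r2)
  expect_identical(names(dd$r1), "p1")
  expect_error(dedup_reads(r1, r2[1:2]), "different lengths")
})

test_that("dedup matches a brute-force comparator on a random set", {
  set.seed(7)
  rnd <- function() paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                          collapse = "")
  r1 <- replicate(90, rnd()); r2 <- replicate(90, rnd())
  dup <- sample(90, 10, replace = TRUE)
  flip <- seq_along(dup) %% 2 == 0
  r1 <- c(r1, ifelse(flip, revcomp(r2[dup]), r1[dup]))
  r2 <- c(r2, ifelse(flip, revcomp(r1[seq_len(90)][dup]), r2[dup]))
  names(r1) <- names(r2) <- sprintf("p%03d", seq_along(r1))
  dd <- dedup_reads(r1, r2)
  # brute force: quadratic scan retaining first of each duplicate class
  keep <- rep(TRUE, length(r1))
  for (i in seq_along(r1)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if ((r1[i] == r1[j] && r2[i] == r2[j]) ||
          (r1[i] == revcomp(r2[j]) && r2[i] == revcomp(r1[j]))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  expect_identical(names(dd$r1), names(r1)[keep])
  expect_identical(length(dd$r1), 90L)
})

test_that("contaminant filtering removes exactly the planted rRNA pairs", {
  set.seed(11)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  rrna <- c(rRNA1 = rnd(500))
  clean1 <- replicate(95, rnd(60)); clean2 <- replicate(95, rnd(60))
  bad1 <- vapply(1:5, function(i) substr(rrna, i * 50, i * 50 + 59),
                 character(1))
  bad2 <- replicate(5, rnd(60))
  r1 <- c(clean1, bad1); r2 <- c(clean2, bad2)
  names(r1) <- names(r2) <- sprintf("p%03d", 1:100)
  fc <- filter_contaminants(r1, r2, rrna)
  expect_identical(names(fc$r1), sprintf("p%03d", 1:95))
  # empty database is the identity
  id <- filter_contaminants(r1, r2, character(0))
  expect_identical(id$r1, r1)
})

test_that("align_and_split discards linear pairs and keeps BSJ candidates", {
  toy <- make_toy_gene()
  ex <- toy$exons  # genomic order, plus strand
  inside <- substr(toy$genome[[1]], ex$start[2] + 10, ex$start[2] + 89)
  spliced <- paste0(substr(toy$genome[[1]], ex$end[1] - 39, ex$end[1]),
                    substr(toy$genome[[1]], ex$start[2], ex$start[2] + 39))
  bsj <- paste0(substr(toy$genome[[1]], ex$end[4] - 49, ex$end[4]),
                substr(toy$genome[[1]], ex$start[2], ex$start[2] + 49))
  r1 <- c(lin = inside, spl = spliced, circ = bsj)
  r2 <- vapply(r1, function(x) revcomp(x), character(1))
  names(r2) <- names(r1)
  sp <- align_and_split(r1, r2, toy$genome)
  expect_identical(sp$linear_pairs, "lin")
  expect_setequal(unique(sub("/[12]$", "", names(sp$candidates))),
                  c("spl", "circ"))
  # the spliced candidate yields no circ call; the BSJ read yields one
  bs <- call_backsplice(sp$candidates, toy$genome)
  expect_identical(nrow(bs$junctions), 1L)
  expect_identical(bs$junctions$start, ex$start[2])
  expect_identical(bs$junctions$end, ex$end[4])
  expect_identical(bs$junctions$strand, "+")
  expect_identical(bs$junctions$splice_signal, "GTAG")
})

test_that("the caller is exact on both strands and both read orientations", {
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(seed = 13, strand = strand)
    ex <- toy$exons
    # body of a circ over the three internal exons, in transcript order
    pieces <- substring(toy$genome[[1]], ex$start[2:4], ex$end[2:4])
    body <- paste(pieces, collapse = "")
    if (strand == "-") body <- revcomp(body)
    L <- nchar(body)
    read_sense <- paste0(substr(body, L - 49, L), substr(body, 1, 50))
    cands <- c("r/1" = read_sense, "q/1" = revcomp(read_sense))
    bs <- call_backsplice(cands, toy$genome)
    expect_identical(nrow(bs$junctions), 1L)
    expect_identical(bs$junctions$n_reads, 2L)
    expect_identical(bs$junctions$start, min(ex$start[2:4]))
    expect_identical(bs$junctions$end, max(ex$end[2:4]))
    expect_identical(bs$junctions$strand, strand)
  }
})

test_that("reads fully inside an exon produce no junction call", {
  toy <- make_toy_gene()
  ex <- toy$exons
  inside <- substr(toy$genome[[1]], ex$start[3] + 5, ex$start[3] + 84)
  bs <- call_backsplice(c("x/1" = inside), toy$genome)
  expect_identical(nrow(bs$junctions), 0L)
})

test_that("junction filters implement the support/span/quality thresholds", {
  j <- data.frame(
    junction_id = c("a", "b", "c", "d", "e"),
    chrom = "chr1", start = 1L,
    end = c(500L, 100000L, 99999L, 500L, 500L), strand = "+",
    n_reads = c(3L, 5L, 5L, 1L, 5L),
    n_unique_reads = c(2L, 5L, 5L, 1L, 5L),
    best_anchor_quality = c(40L, 40L, 40L, 40L, 3L))
  j$span <- j$end - j$start + 1L
  keep <- filter_junctions(j)$junction_id
  expect_setequal(keep, c("a", "c"))  # b: span 100000; d: 1 unique; e: MQ 3
})

test_that("linear support counts boundary-crossing spliced reads", {
  toy <- make_toy_gene(seed = 19)
  ex <- toy$exons
  g <- toy$genome[[1]]
  # junction over exons 2-3
  junctions <- data.frame(junction_id = "J", chrom = "chrT",
                          start = ex$start[2], end = ex$end[3],
                          strand = "+", span = ex$end[3] - ex$start[2] + 1L)
  # 9 distinct reads crossing exon1->exon2 (acceptor), 12 crossing
  # exon3->exon4 (donor)
  acc <- vapply(1:9, function(i)
    paste0(substr(g, ex$end[1] - 29 - i, ex$end[1]),
           substr(g, ex$start[2], ex$start[2] + 49 + i)), character(1))
  don <- vapply(1:12, function(i)
    paste0(substr(g, ex$end[3] - 29 - i, ex$end[3]),
           substr(g, ex$start[4], ex$start[4] + 49 + i)), character(1))
  bsj <- paste0(substr(g, ex$end[3] - 49, ex$end[3]),
                substr(g, ex$start[2], ex$start[2] + 49))
  cands <- c(setNames(acc, sprintf("a%02d/1", 1:9)),
             setNames(don, sprintf("d%02d/1", 1:12)),
             c("bsj1/1" = bsj))
  lin <- count_linear_support(junctions, cands, toy$genome, toy$model)
  expect_identical(lin$linear_acceptor, 9L)
  expect_identical(lin$linear_donor, 12L)
  expect_identical(lin$linear, 21L)
  # no candidates -> zero counts
  lin0 <- count_linear_support(junctions, character(0), toy$genome,
                               toy$model)
  expect_identical(lin0$linear, 0L)
})

test_that("annotation assigns hosts and drops cross-gene artifacts", {
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    tx_id = c("tA", "tA", "tB", "tB", "tC"),
    chrom = "chr1",
    start = c(1000L, 2000L, 9000L, 11000L, 20500L),
    end = c(1200L, 2200L, 9200L, 11200L, 20800L),
    strand = "+", exon_rank = c(1L, 2L, 1L, 2L, 1L),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "protein_coding", "lincRNA"))
  model <- toy_model(exons)
  j <- data.frame(
    junction_id = c("inA", "crossAB", "intergenic", "inC"),
    chrom = "chr1",
    start = c(1000L, 2000L, 5000L, 20500L),
    end = c(2200L, 9200L, 5400L, 20800L),
    strand = "+",
    n_reads = 5L, n_unique_reads = 5L, best_anchor_quality = 40L,
    span = 100L, splice_signal = "GTAG")
  an <- annotate_junctions(j, model)
  expect_false("crossAB" %in% an$junction_id)  # two non-overlapping genes
  expect_identical(an$host_gene[an$junction_id == "inA"], "gA")
  expect_identical(an$host_biotype[an$junction_id == "inA"],
                   "protein-coding")
  expect_identical(an$host_biotype[an$junction_id == "intergenic"],
                   "no gene")
  expect_identical(an$host_biotype[an$junction_id == "inC"], "non-coding")
})

test_that("counting conservation: circ counts equal BSJ-classified pairs", {
  det <- tiny_detect("WT_1")
  expect_identical(sum(det$counts$circ),
                   length(unique(paste(det$support$junction_id,
                                       det$support$pair_id))))
})

test_that("adding supporting reads never removes a junction", {
  toy <- make_toy_gene(seed = 23)
  ex <- toy$exons
  pieces <- substring(toy$genome[[1]], ex$start[2:4], ex$end[2:4])
  body <- paste(pieces, collapse = "")
  L <- nchar(body)
  mk <- function(q) paste0(substr(body, L - 49 - q, L),
                           substr(body, 1, 50 + q))
  base_cands <- setNames(vapply(1:3, mk, character(1)),
                         sprintf("p%d/1", 1:3))
  extra <- setNames(vapply(4:8, mk, character(1)), sprintf("q%d/1", 4:8))
  j1 <- filter_junctions(call_backsplice(base_cands, toy$genome)$junctions)
  j2 <- filter_junctions(call_backsplice(c(base_cands, extra),
                                         toy$genome)$junctions)
  expect_true(all(j1$junction_id %in% j2$junction_id))
  expect_gte(j2$n_reads[match(j1$junction_id, j2$junction_id)],
             j1$n_reads)
})

test_that("merged junction calls union per-sample sets with max support", {
  j1 <- data.frame(junction_id = c("a", "b"), chrom = "chr1",
                   start = c(1L, 5L), end = c(10L, 20L), strand = "+",
                   n_reads = c(3L, 4L), n_unique_reads = c(3L, 4L),
                   best_anchor_quality = c(40L, 40L), span = c(10L, 16L),
                   splice_signal = "GTAG")
  j2 <- data.frame(junction_id = c("b", "c"), chrom = "chr1",
                   start = c(5L, 30L), end = c(20L, 45L), strand = "+",
                   n_reads = c(9L, 2L), n_unique_reads = c(8L, 2L),
                   best_anchor_quality = c(40L, 40L), span = c(16L, 16L),
                   splice_signal = "GTAG")
  m <- merge_junction_calls(list(j1, j2))
  expect_setequal(m$junction_id, c("a", "b", "c"))
  expect_identical(m$n_reads[m$junction_id == "b"], 9L)
})
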