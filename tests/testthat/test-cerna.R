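# ceRNA stage: sequence reconstruction, site prediction, sponge calls,
# target filtering, ORA and the network.

test_that("reconstructed sequences equal planted truth and wrap correctly", {
  sim <- tiny_world()
  det <- tiny_detect("WT_1")
  cs <- reconstruct_sequences(det$junctions, det$support, det$reads,
                              sim$model, sim$genome)
  truth <- sim$truth
  for (i in seq_len(nrow(cs))) {
    k <- match(cs$circ_id[i], truth$circs$junction)
    body <- circfus:::circ_body_seq(truth, sim$genome, k)
    expect_identical(cs$seq[i], paste0(body, substr(body, 1, 25)))
    expect_identical(cs$bsj_offset[i], nchar(body))
    # wrap property
    expect_identical(substr(cs$seq[i], cs$bsj_offset[i] + 1,
                            cs$bsj_offset[i] + 25),
                     substr(cs$seq[i], 1, 25))
    expect_gt(cs$support[i], 0)
  }
})

test_that("isoform selection follows read-pair support", {
  set.seed(23)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  ex <- replicate(4, rnd(200)); it <- replicate(3, rnd(300))
  for (i in 1:3) {
    substr(it[i], 1, 2) <- "GT"; substr(it[i], 299, 300) <- "AG"
  }
  g <- paste0(rnd(300), ex[1], it[1], ex[2], it[2], ex[3], it[3], ex[4],
              rnd(300))
  genome <- c(chrI = g)
  st <- function(k) 300L + (k - 1L) * 500L + 1L
  exons <- data.frame(
    gene_id = "gI",
    tx_id = c(rep("tAll", 4), rep("tSkip", 3)),
    chrom = "chrI",
    start = st(c(1:4, 1, 2, 4)), end = st(c(1:4, 1, 2, 4)) + 199L,
    strand = "+", exon_rank = c(1:4, 1:3), biotype = "protein_coding")
  model <- toy_model(exons)
  # circ spans exons 2..4; isoform tSkip lacks exon 3 -> shorter body
  jr <- data.frame(junction_id = "J", chrom = "chrI", start = st(2),
                   end = st(4) + 199L, strand = "+",
                   host_tx = "tAll,tSkip")
  body_skip <- paste0(ex[2], ex[4])
  # plant 5 BSJ pairs from the skipped isoform
  L <- nchar(body_skip)
  r1 <- vapply(1:5, function(i)
    paste0(substr(body_skip, L - 49 - i, L), substr(body_skip, 1, 50 + i)),
    character(1))
  # the second mate spans the exon2|exon4 junction, which only exists in
  # the skipped isoform -- this is what disambiguates the two candidates
  r2 <- vapply(1:5, function(i)
    revcomp(substr(body_skip, 150, 249 + i)), character(1))
  names(r1) <- names(r2) <- sprintf("p%d", 1:5)
  support <- data.frame(junction_id = "J", pair_id = names(r1))
  cs <- reconstruct_sequences(jr, support, list(r1 = r1, r2 = r2), model,
                              genome)
  expect_identical(cs$transcript_id, "tSkip")
  expect_identical(cs$bsj_offset, nchar(body_skip))
  expect_identical(cs$support, 5L)
})

test_that("unsupported circRNAs are dropped with a logged reason", {
  sim <- tiny_world()
  det <- tiny_detect("WT_1")
  jr <- det$junctions[1, , drop = FALSE]
  empty_support <- data.frame(junction_id = character(0),
                              pair_id = character(0))
  expect_identical(
    nrow(reconstruct_sequences(jr, empty_support, det$reads, sim$model,
                               sim$genome)), 0L)
})

test_that("site prediction recovers planted motifs exactly once", {
  set.seed(27)
  backbone <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  site <- revcomp(mir)
  seq <- backbone
  substr(seq, 100, 120) <- site
  body <- seq
  circ <- data.frame(circ_id = "c1", transcript_id = "t",
                     seq = paste0(body, substr(body, 1, 25)),
                     bsj_offset = nchar(body), support = 5L)
  hits <- predict_sites(circ, c(m = mir))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 100L)
  expect_identical(hits$end, 120L)
  expect_identical(hits$score, 140)
  expect_false(hits$spans_bsj)
})

test_that("BSJ-spanning sites appear once and carry the flag", {
  set.seed(28)
  mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  site <- revcomp(mir)
  body <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  # last 10 nt of the body + first 11 nt hold the split site
  substr(body, 291, 300) <- substr(site, 1, 10)
  substr(body, 1, 11) <- substr(site, 11, 21)
  circ <- data.frame(circ_id = "c1", transcript_id = "t",
                     seq = paste0(body, substr(body, 1, 25)),
                     bsj_offset = 300L, support = 5L)
  hits <- predict_sites(circ, c(m = mir))
  expect_identical(nrow(hits), 1L)    # found once, not re-found in the tail
  expect_true(hits$spans_bsj)
  expect_identical(hits$start, 291L)
  # a site planted at the body start is not double counted via the tail copy
  body2 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(body2, 3, 23) <- site
  circ2 <- data.frame(circ_id = "c2", transcript_id = "t",
                      seq = paste0(body2, substr(body2, 1, 25)),
                      bsj_offset = 300L, support = 5L)
  hits2 <- predict_sites(circ2, c(m = mir))
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$start, 3L)
})

test_that("random sequences produce no sites at the default threshold", {
  set.seed(29)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  circs <- data.frame(circ_id = sprintf("r%02d", 1:20), transcript_id = "t",
                      seq = replicate(20, rnd(525)), bsj_offset = 500L,
                      support = 1L)
  mirs <- setNames(replicate(10, rnd(21)), sprintf("m%02d", 1:10))
  hits <- predict_sites(circs, mirs)
  expect_identical(nrow(hits), 0L)
})

test_that("mature sequences in the RNA alphabet are accepted", {
  mir_dna <- "TGAGGTAGTAGGTTGTATAGT"
  mir_rna <- chartr("T", "U", mir_dna)
  body <- paste0(strrep("C", 100), revcomp(mir_dna), strrep("C", 100))
  circ <- data.frame(circ_id = "c", transcript_id = "t",
                     seq = paste0(body, substr(body, 1, 25)),
                     bsj_offset = nchar(body), support = 1L)
  expect_identical(predict_sites(circ, c(m = mir_rna))$start, 101L)
  expect_error(predict_sites(circ, c(m = "ACGU")), "18-26")
})

test_that("sponge rule: two sites or one BSJ-spanning site", {
  sites <- data.frame(
    circ_id = c("a", "a", "b", "c"),
    mirna = c("m1", "m1", "m1", "m1"),
    start = c(10L, 60L, 5L, 5L), end = c(30L, 80L, 25L, 25L),
    score = 140, energy = -14,
    spans_bsj = c(FALSE, FALSE, TRUE, FALSE))
  sp <- call_sponges(sites)
  expect_true(sp$is_sponge[sp$circ_id == "a"])   # two sites
  expect_true(sp$is_sponge[sp$circ_id == "b"])   # one BSJ site
  expect_false(sp$is_sponge[sp$circ_id == "c"])  # one off-BSJ site
})

test_that("target filtering applies score, source and downregulation rules", {
  inter <- data.frame(
    mirna = "m1",
    gene = c("g1", "g2", "g3", "g4", "g5"),
    score = c(0.96, 0.96, 0.80, 0.96, 0.99),
    targetscan = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    mirdb = FALSE, mirtarbase = FALSE,
    tarbase = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  mrna <- data.frame(gene = sprintf("g%d", 1:5),
                     log2fc = c(-0.5, 0.2, 0.1, 0.3, -0.2))
  prot <- data.frame(gene = sprintf("g%d", 1:5),
                     log2fc = c(0.1, -0.5, -0.5, 0.2, -0.1))
  tg <- filter_targets("m1", inter, mrna, prot)
  expect_true("g1" %in% tg$gene)    # score + source + mRNA down
  expect_false("g2" %in% tg$gene)   # no corroborating source
  expect_true("g3" %in% tg$gene)    # validated bypasses the score threshold
  expect_false("g4" %in% tg$gene)   # not downregulated anywhere
  # monotonicity: raising the threshold never adds targets
  tg_hi <- filter_targets("m1", inter, mrna, prot, min_score = 0.98)
  expect_true(all(tg_hi$gene %in% tg$gene))
})

test_that("ORA equals exact tail summation and applies the 0.01 cutoff", {
  bg <- sprintf("g%02d", 1:40)
  targets <- bg[1:10]
  cats <- rbind(
    data.frame(category = "hit", gene = bg[1:8]),      # mostly targets
    data.frame(category = "miss", gene = bg[31:38]),   # disjoint
    data.frame(category = "mid", gene = bg[6:15]))
  ora <- ora_enrichment(targets, cats, bg)
  for (cn in c("hit", "miss", "mid")) {
    row <- ora[ora$category == cn, ]
    expect_lt(abs(row$p_value -
                    brute_hyper_tail(row$n_overlap, 40, row$n_category, 10)),
              1e-12)
  }
  expect_true(ora$enriched[ora$category == "hit"])
  expect_false(ora$enriched[ora$category == "miss"])
  expect_identical(ora$p_value[ora$category == "miss"], 1)
})

test_that("the network encodes sponges, categories and shared genes", {
  sponges <- data.frame(circ_id = c("cA", "cB", "cC"),
                        mirna = c("m1", "m1", "m2"),
                        n_sites = c(2L, 1L, 1L),
                        has_bsj_site = c(FALSE, TRUE, FALSE),
                        is_sponge = c(TRUE, TRUE, FALSE))
  targets <- data.frame(mirna = c("m1", "m1", "m2"),
                        gene = c("g1", "g2", "g3"),
                        score = 0.96, validated = FALSE,
                        mrna_log2fc = -1, protein_log2fc = -1)
  enrichment <- data.frame(category = c("K1", "K2"), n_category = 5L,
                           n_overlap = 2L, p_value = 0.001, enriched = TRUE)
  cats <- data.frame(category = c("K1", "K1", "K2"),
                     gene = c("g1", "g2", "g2"))
  g <- build_network(sponges, targets, enrichment, cats)
  nm <- igraph::V(g)$name
  expect_setequal(nm[igraph::V(g)$type == "circRNA"], c("cA", "cB"))
  expect_false("cC" %in% nm)  # not a sponge
  e <- igraph::as_data_frame(g)
  # shared-miRNA motif: both circRNAs connect to m1
  expect_setequal(e$from[e$to == "m1" & e$kind == "sponge"], c("cA", "cB"))
  # sponge edge weights conserve the total site count
  expect_equal(sum(e$weight[e$kind == "sponge"]), 3)
  # category-category edge weighted by shared target genes (g2)
  cc <- e[e$kind == "category-category", ]
  expect_identical(nrow(cc), 1L)
  expect_equal(cc$weight, 1)
  # empty input -> empty graph
  g0 <- build_network(sponges[0, ], targets[0, ], enrichment[0, ], cats)
  expect_identical(as.integer(igraph::vcount(g0)), 0L)
  # exports
  gml <- tempfile(fileext = ".graphml"); sif <- tempfile(fileext = ".sif")
  write_network(g, gml, sif)
  expect_true(file.size(gml) > 0)
  expect_identical(length(readLines(sif)), as.integer(igraph::ecount(g)))
})
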