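---
title: "circfus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circfus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`circfus` re-implements, at desk scale, a circular RNA (circRNA) analysis
pipeline of the kind used to study how an ALS-linked RNA-binding-protein
mutation perturbs back-splicing in motor neurons: back-splice junction (BSJ)
detection from paired-end total RNA-seq, negative-binomial differential
expression of circular and cognate linear splicing events, analysis of the
1-kb intronic regions flanking circularised exons (protein-binding calls
from PAR-CLIP T-to-C transitions, inverted Alu repeats, the A-to-I Alu
editing index), and competing-endogenous-RNA (ceRNA) inference ending in a
circRNA–miRNA–category network.  Every stage is exercised on synthetic data
with planted ground truth; no external data sets are required.

# The back-splice caller

Back-splicing joins a downstream donor (5' splice site) to an upstream
acceptor (3' splice site), so a read crossing the head-to-tail junction
cannot be aligned contiguously.  The caller follows the anchor strategy:

1. mates are trimmed (exact adapter-suffix clipping, minimum length 18 nt),
   exact and mate-swapped reverse-complement duplicate pairs are removed,
   and pairs matching a contaminant database are dropped;
2. mates are aligned separately to the genome; pairs where both mates have
   a full-length contiguous alignment with at most `max_mm` (default 2)
   mismatches are discarded as linear;
3. from each remaining mate, 20-nt anchors are taken from both ends and
   placed exactly on the genome.  Because the library is unstranded, both
   the read and its reverse complement are anchored, and the genome is
   searched in two "strand spaces" (the plus sequence and its reverse
   complement) so the geometry test is identical on both strands;
4. a head-to-tail event is called when the 3'-end anchor lands upstream of
   the 5'-end anchor in the same space; the anchors are extended toward
   each other until the whole read is explained as donor suffix +
   acceptor prefix, with the breakpoint placed so the flanking
   dinucleotides are GT (donor) and AG (acceptor).  Among valid
   breakpoints the caller prefers fewest mismatches, then the longest
   acceptor-side match, then the smallest start coordinate — a
   deterministic tie-break;
5. events are aggregated by (chromosome, start, end, strand), counting
   supporting *pairs*, and filtered: at least two uniquely-placed
   supporting pairs, span below 100 kb, and a best anchor quality of at
   least 35.

Mapping quality is a surrogate: a uniquely placed anchor scores 40, a
multi-placed one 3, so the threshold of 35 means "both anchors unique",
mirroring how the corresponding Bowtie 2 threshold is used in practice.
The full aligner is replaced by an exact-seed (PDict) index with
mismatch-tolerant verification; on synthetic genomes the contract the
pipeline consumes — maps or does not map, unique or multi — is identical,
and a gapped aligner would add nothing testable.

**Linear support.**  The cognate linear count of a junction is the number
of reads "mapping linearly to each of the two coordinates" of the BSJ.
Mature spliced reads never cross an exon/intron boundary contiguously in
genome space, so we count mates whose *transcript-space* (spliced) linear
alignment crosses the boundary: for the acceptor, reads spliced from the
upstream exon into the first circularised exon; for the donor, reads
spliced out of the last circularised exon.  BSJ-spanning reads have no
linear alignment and contribute zero.  This matches the substance of the
original procedure (linear splice events reported at the same splice
sites) while staying well defined on spliced reads.

**Coordinates.**  Internally everything is 1-based closed (the native
IRanges convention); BED files are read and written 0-based half-open, GTF
1-based closed, and junction ids are rendered 1-based as
`chrom:start-end_strand`.

# Differential expression

The count matrix has two rows per junction (circular; linear = sum of the
two boundary counts).  Events lacking two or more reads in at least the
minimum replicate number of samples are removed.  Library sizes are the
raw column sums of the full event matrix (no TMM or quantile
normalisation), CPM = count / library size × 1e6, and a circRNA is called
expressed in a condition when its average circular CPM there is ≥ 1.

Per event we fit an additive negative-binomial GLM with log link,
log-library-size offsets and `~ batch + condition` covariates, and test
the condition coefficient with a 1-df likelihood-ratio (deviance) test.
Significance thresholds are 0.05 for circular and 0.1 for linear events —
raw p-values, not FDR, matching the low counts involved; a BH-FDR column
is exposed for convenience.  A circRNA and its linear counterpart are
*concordant* when both are significant at their thresholds with the same
log2FC sign; the concordance summary reports the share of deregulated
circRNAs that are concordant, rounded to the nearest percent.

Dispersion is estimated as in the standard NB machinery: a common
dispersion maximises the Cox–Reid adjusted profile likelihood summed over
events (subsampled to at most 500 events for speed — the estimate is
already stable well below that), and per-event values are method-of-moments
estimates shrunk toward the common value with a prior weight of 50
residual degrees of freedom, floored at 1e-8 (the prior is heavy because
at ~2 residual degrees of freedom the moment estimator is biased low,
which would make the LRT liberal).  Exact numerical parity with
any particular DE package is *not* a contract; calibration (type-I error
within [0.03, 0.07] at α = 0.05), power and parameter recovery are, and
are tested.

# Flanking introns

For every circRNA tested for differential expression — excluding the
concordantly deregulated ones, whose change is plausibly transcriptional —
we take the 1-kb genomic windows upstream and downstream of the
circularised exons (clipped at chromosome bounds).  A flank is *bound*
when at least one PAR-CLIP T-to-C transition overlaps it.  One-sided
Fisher tests (exact hypergeometric tails) compare the bound proportion of
down- (up-) regulated circRNAs with the unaffected ones; a hypergeometric
test assesses the overlap between the bound set and the circRNAs carrying
an inverted Alu pair (one Alu per flank, opposite orientations, partial
overlap counting).

The **Alu editing index** is a weighted average: over all reference-A
positions of plus-strand Alus (reference-T, read on the reverse
complement, for minus-strand Alus), coverage and G (resp. C) mismatches
are pooled *before* division — index = 100 × pooled mismatches / pooled
coverage.  An Alu enters the pool when at least `min_cov` (default 10) of
its A positions are covered.  Reads are placed with a deliberately relaxed
mismatch budget (default 12) because an edited read *is* a mismatched
read: with the detection budget of 2, heavily edited reads would be
excluded and the index biased downward.  With the relaxed budget the
residual exclusion (reads whose every 18-nt seed block carries an edit) is
below 1%.

# ceRNA inference

Circular sequences are reconstructed per junction: for each overlapping
expressed transcript, the exonic sequence over the circ span is extended
at its 3' end with the first 125 nt of itself; the junction's supporting
read pairs are aligned to each candidate, a pair counting when both mates
place and at least one crosses the original 3' end; the winning transcript
maximises supporting pairs and the final sequence retains only the first
25 nt of the extension (sites are therefore reported only up to
body + 25 nt; the asymmetric 125/25 rule is preserved as specified).

miRNA sites are predicted with a seed-anchored complementarity scorer in
the miRanda spirit: candidate positions are exact matches of the reverse
complement of the miRNA seed (positions 2–8); the full miRNA is then
scored ungapped, antiparallel (+5 Watson–Crick, +2 G:U wobble, −4
mismatch, seed positions doubled), with an energy proxy of −score/10.  A
perfect 21-mer site scores 5·14 + 10·7 = 140, which is the default
reporting threshold (energy ≤ −1.0).  This is a documented scorer, not a
thermodynamics engine; the measured false-positive rate on random
21-mers versus random 500-nt sequences at the default threshold is zero in
the packaged null test.  Sites falling entirely inside the duplicated
25-nt tail are copies of their 5' originals and are discarded; overlapping
sites of one (circRNA, miRNA) pair (> 50% of the shorter) are
deduplicated keeping the best score.

A circRNA is a putative **sponge** for a miRNA when it carries at least
two sites, or one site spanning the BSJ.  Candidate targets of sponged
miRNAs are kept when the interaction score is ≥ 0.95 with at least one
corroborating database flag — the five web resources become columns of one
interaction table (score + targetscan/mirdb/mirtarbase/tarbase flags), and
experimentally validated rows bypass the score threshold — and the gene is
downregulated at the mRNA and/or protein level.  Over-representation
against a gene→category table uses hypergeometric upper tails at
p < 0.01.  The exported network connects circRNAs to miRNAs (edge weight =
number of sites, with a BSJ flag), miRNAs to enriched categories (weight =
targets in the category) and categories to each other (weight = shared
target genes).

# The localization null

CircRNAs whose junctions fall inside protein-coding transcripts are
classified by the regions their *exonic content* overlaps (5'UTR, CDS,
3'UTR), with an INTRON flag when a junction boundary falls inside an
intron (retained intronic sequence).  The exonic-content rule — rather
than a raw genomic-span intersection — is what makes a two-exon CDS circ
read "CDS" instead of "CDS+INTRON"; both real and faux circRNAs are
classified identically, so the test is internally consistent.  The null
model draws 5000 runs of consecutive *internal* exons (never the first or
last) from the circRNA-hosting transcripts, run lengths sampled from the
observed circ exon-count distribution (multi-isoform counts averaged and
rounded half up; an infeasible drawn length is redrawn, preserving the
support).  A 2×k chi-squared over the observed flag combinations tests
preferential localization.

# The synthetic world

The generator's defaults state one desk-scale world (~20 genes, one 500-kb
chromosome, ~40k read pairs over 6 samples), chosen once:

* genes of 4–8 exons (150–400 nt) and introns of 2.8–4 kb, GT/AG written
  on the gene strand; a configuration error is raised when introns cannot
  host the requested flanking Alus (2×Alu length + 2 kb).  CDS boundaries
  fall inside the flanking internal exons so that 5'UTR/CDS/3'UTR
  combinations actually occur — without that, the localization null is
  degenerate;
* 15 circRNAs over runs of internal exons, log2 fold changes planted as
  (−2, 0, +2) repeating, 20 BSJ pairs per junction per sample on average,
  NB dispersion 0.1, batch-structured multipliers across 3 experiments ×
  2 conditions × 3 replicates; 2 decoy junctions carry AT..AC signals and
  must be rejected; one downregulated circRNA's host gene is itself
  downregulated (log2FC −1.5), planting a concordant case;
* inverted Alu pairs flank the downregulated circRNAs, co-oriented pairs
  the upregulated ones, plus lone background Alus; all Alus edit at a
  per-site rate of 0.1; intronic coverage comes from Alu-targeted genomic
  fragments standing in for pre-mRNA reads (`alu_coverage`, default 15×);
* T-to-C transitions at 5/kb in the flanks of (non-concordant)
  downregulated circRNAs, 0.05/kb elsewhere in gene bodies, always on a T
  of the annotated strand;
* three sponge circRNAs (cytoplasmic, downregulated): two body sites for
  miR-1; a BSJ-spanning miR-1 site on a second circ (the shared-miRNA
  motif) plus two miR-2 sites; a BSJ-spanning miR-3 site; and one lone
  off-junction site as a negative control.  Responder targets get
  negative mRNA and/or protein log2FCs; background interactions are
  sub-threshold *by construction* so the planted target set is exactly
  recoverable — the behaviour of the target filter at the threshold is
  covered by constructed unit fixtures instead;
* 5% adapter read-through (on linear fragments), 5% appended exact
  duplicates, unstranded FR orientation; fragments must not wrap a circle
  more than once (error otherwise).

What a green test does **not** establish: the simulator has no sequencing
errors beyond editing, no quality-score structure, no GC or coverage bias,
single-isoform genes (multi-isoform logic is tested on constructed
fixtures), and desk-scale event counts — so library-size estimation from a
30-row event matrix is noisier than in real data, and the paper-scale
numbers (thousands of circRNAs) are out of reach by design.

# Numerical choices and degenerate inputs

* IRLS: log link, eta clamped to ±30, convergence on relative deviance
  change < 1e-8, 50 iterations; non-converged fits are flagged with p = 1.
* Identical pairs in the paired t-test give t = 0 and p = 1 by convention.
* Zero pooled coverage yields a missing editing index, not zero.
* `round half up` is used wherever the procedure says "rounded to the
  nearest integer" (determinism across platforms).
* Junctions whose boundaries fall in two genes that do not overlap each
  other are removed as mapping artifacts; intergenic junctions are kept
  with host biotype "no gene".
* Faux sampling is transcript-first uniform (transcript uniform among
  those that can host the drawn length, then start index uniform).

# Known limitations

The aligner is exact-seeded and ungapped — adequate for clean synthetic
genomes, not for real reads with indels.  Per-sample junction tables
zero-fill junctions that fell below the per-sample filter instead of
re-counting the merged set against the raw output.  The miRanda-style
scorer is ungapped.  The Fisher/hypergeometric machinery assumes
circRNA-level (not flank-level) units, as the procedure's wording implies.
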