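---
title: "Methods: from splice junctions to a splicing-expression network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from splice junctions to a splicing-expression network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

splicelink implements an integrative bulk RNA-seq analysis built around a
simple biological hypothesis: a regulator that changes the alternative
splicing of transcription factors can, through those TFs, reshape the
expression of the TFs' target genes. The pipeline therefore chains five
analyses — alternative-splicing event detection and testing, differential
expression, promoter motif enrichment, TF matching, and correlation network
construction — and ships a synthetic-data generator with planted truth so
that every stage can be validated end to end.

## Splicing events from junction reads

Events are enumerated from annotated isoform pairs, not discovered de novo.
For each gene, every pair of exon chains is compared after trimming the
common flanking exons; the remaining "difference region" is matched against
a classification grammar that assigns exactly one of ten labels:

* **ES / CassetteExon** — a single junction skips exactly one (ES) or two or
  more consecutive (CassetteExon) internal exons. The two labels partition
  skipping events by skipped-exon count.
* **A5SS / A3SS** — the two chains share one splice site of an intron and
  shift the other. Donor (5') versus acceptor (3') is resolved in transcript
  orientation: a shifted right boundary is a donor on the plus strand and an
  acceptor on the minus strand.
* **A5SS&ES / A3SS&ES** — one alternative junction simultaneously shifts a
  splice site and skips at least one exon.
* **MXE** — two internal, non-overlapping exons used mutually exclusively
  between shared flanks.
* **5pMXE / 3pMXE** — mutually exclusive first/last exons: the chains start
  (or end) in different, non-overlapping terminal exons spliced to a shared
  neighbour.
* **IR** — one chain splices an intron that the other retains inside a
  single exon.

Differences matching no rule are labelled `complex` and excluded (their
count is reported). The grammar is symmetric in isoform order, and mirroring
all coordinates swaps A5SS with A3SS and 5pMXE with 3pMXE while fixing the
strand-neutral types — both properties are enforced by tests.

Quantification is junction-read based. Each event carries an *alternative*
and a *model* junction set; per sample the splicing ratio is

    ratio = alt_reads / (alt_reads + model_reads)

summed over each set. Intron retention has no alternative junction, so its
alternative evidence is the sum of reads over the two exon–intron boundary
intervals of the retained intron, with the spliced junction as the model —
this convention is used consistently by the quantifier and the simulator.
Ratios supported by fewer than `min_total = 10` reads are undefined:
below that, a ratio moves by ~0.1 per read and carries more noise than
signal. The value is a package default, not an external convention.

Group differences are tested per event with a pooled-variance two-sample
Student's t-test (appropriate at n = 3 + 3, where Welch's correction
mostly costs degrees of freedom), two-sided, with Benjamini–Hochberg
adjustment across events. Regulated events (RASEs) are selected at raw
p < 0.05 by default; an FDR mode (`use_fdr = TRUE`) selects on q < 0.05
instead. Both conventions circulate for junction-ratio screens, so both are
exposed rather than hard-wiring one. Genes with at least one selected event
are the regulated splicing genes (RASGs). Degenerate inputs are handled
explicitly: groups with fewer than two defined ratios are skipped with a
reason code; zero-variance groups with equal means give p = 1; zero
variance with unequal means is flagged and assigned the smallest positive
double rather than zero.

## Differential expression

Counts are normalised with trimmed-mean-of-M-values (TMM) factors computed
against the sample whose library size is closest to the mean, with the
method's published trim fractions (30% on M, 5% on A) and precision
weighting; factors are scaled to geometric mean one. The test is a
conditional negative-binomial exact test: after scaling all samples to a
common effective library size, the two group sums are compared conditional
on their total, and the two-sided p-value sums the probabilities of all
splits as or less probable than the observed one. As dispersion goes to
zero this reduces to a conditional binomial test (verified against an
independent binomial oracle to 1e-6). Dispersions are method-of-moments
estimates shrunk toward the all-gene mean with a prior weight of ten
pseudo-genes — a deliberately simple, documented moderation rather than
full empirical Bayes; at 3 + 3 replicates the shrinkage dominates and is
what keeps the null calibrated. DEGs require fold change ≥ 2 or ≤ 0.5
*and* BH q < 0.05, with fold changes computed from normalised group means
plus a 0.5 pseudocount. FPKM (fragments per kilobase per million counted
fragments, using the matrix's own column sums as totals) is computed
alongside for reporting and for the network stage.

## Promoter motifs and the TF overlap

Position frequency matrices are read from JASPAR-style text. Scores are
log2 odds against a background (uniform by default) with a total
pseudocount of 0.8 per column distributed by the background composition.
Both strands are scanned, and a window is a hit when its score reaches
`min + 0.8 × (max − min)` — the conventional 80%-of-score-range PWM
cutoff. Enrichment is assessed per motif in three symmetric TSS windows
(±1, 2, 3 kb): a gene *has* a motif if it carries at least one hit inside
the window, and over-representation of the target set (down-regulated DEGs)
against the background universe (all genes) uses the upper-tail
hypergeometric test at p < 0.01. The *consistent* set comprises motifs
enriched in all three windows — multi-scale agreement guards against
window-specific artefacts. Motifs are matched to splicing-regulated TFs by
case-insensitive TF name, with multi-PFM TFs contributing all their motifs.

The significance of the overlap between TF motifs and consistently enriched
motifs is an upper-tail hypergeometric probability. `overlap_test()`
defaults to the inclusive tail P(X ≥ k); published analyses sometimes
report the exclusive tail P(X > k), available via `inclusive = FALSE`, and
the acceptance script reports both conventions.

## The correlation network

Candidate pairs are (selected TF splicing event, DEG target) where the
target promoter carries at least one hit of any of that TF's motifs. An
edge requires Pearson |r| ≥ 0.95 and p ≤ 0.005 (t-distribution closed
form on n − 2 df) between the event's per-sample ratios and the target's
FPKM across all six samples. The absolute value is deliberate: a repressive
TF isoform correlates negatively with its targets; a signed mode is
available. Events with any undefined ratio are skipped, as are zero-variance
vectors. One edge is emitted per (event, target) pair because one TF can
carry several regulated events. Exports: TSV, SIF and GraphML (node roles
and directions, edge r and p) for Cytoscape.

When we assess the network against a permutation null, sample labels of the
expression matrix are shuffled *excluding* permutations that preserve the
two-group partition in either orientation: the identity-like relabelings
and the full group swap reproduce the alternative hypothesis (the swap
gives |r| ≈ 1 under the absolute-value rule), so they are not null draws.

## The synthetic study

The generator emulates a two-condition, three-replicate bulk RNA-seq
experiment: 80 genes on one synthetic chromosome, the ten event types
planted cyclically (about seven genes per type, alternating strands, with
minus-strand genes built by coordinate mirroring so every type occurs on
both strands), plus constitutive genes. Per event and sample a Poisson
total (mean 300 reads, typical of well-covered junctions) is split
binomially between the alternative and model sets at the planted group
ratio (0.5 control, ±0.3 shift in treatment for 30% of event genes,
alternating sign); reads are spread multinomially across a set's junctions.
Gene counts are negative binomial (dispersion 0.1) around log-normal
baselines (median 500, sdlog 0.5) with ~10% log-normal library-size
variation; 25% of genes carry a planted ±1.5 log2 fold change.

The spread of the baselines is kept moderate on purpose: with only 80
genes, heavy-tailed baselines would let one or two genes dominate the
library totals, and their counting noise would contaminate every FPKM value
through the per-sample normalisation — an artefact genome-scale data does
not have. The same reasoning sets the driven targets at a higher baseline
(4 × 500): the planted regulatory signal should dominate Poisson noise the
way it would for strongly expressed signalling genes.

The planted network designates the first splicing-regulated gene as a TF
whose *realised* per-sample splicing ratio r linearly represses ten target
genes, mu ∝ max(2.8 − 3 r, 0.1) — about 1.3 in control and 0.4 in
treatment, i.e. a fold change of ~0.31, comfortably on the repressed side
of the 0.5 DEG cutoff even after ratio jitter propagates through the drive.
Driven targets use near-Poisson dispersion (1e-3), modelling tight
regulatory coupling. Five TF genes receive synthetic PFMs (length 14,
consensus weight 0.97 per column — high-information-content motifs in the
JASPAR-core range; at the 80% threshold this admits two mismatches,
giving ~99% per-instance recovery and a background rate of ~3 hits per
megabase and strand) plus ten decoy PFMs naming no gene. Every
down-regulated DEG promoter is a candidate for every TF motif at plant rate
0.8; network targets always carry their driving TF's canonical consensus
site (forced plantings use the consensus — a guaranteed high-affinity site
— while rate-based plantings sample from the PFM). Promoters are 6 kb of
i.i.d. uniform background with the TSS at the centre, and planted offsets
fall within ±1 kb so instances lie inside every enrichment window.

Every stage draws from its own RNG stream derived from the master seed by a
fixed offset, so changing one stage's parameters does not perturb another's
draws, and all outputs are byte-identical under a fixed seed.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: read-level alignment artefacts, GC and mappability
bias, overdispersed junction counts, isoform-level expression coupling
between events of one gene, correlated replicates, annotation errors, and
genome-scale multiple-testing burdens. The planted-truth checks validate the
statistical machinery, not robustness to those real-data complications.

## Problem sizes and numerical choices

Calibration studies run at the sizes a single CPU handles in seconds: null
type-I error on 2000 simulated events (depth 100, 3 vs 3) and 2000 NB genes
(dispersion 0.1), power on 500 events / 200 genes with planted effects, and
100 label permutations for the network null. The exact-test tail sum is
computed in log space with a 1e-12 relative tie tolerance; BH adjustment
uses `stats::p.adjust`; hypergeometric tails use `stats::phyper` (checked
against exhaustive enumeration for all universes up to 12). Ties in the PWM
scan threshold are kept (score ≥ threshold). GTF coordinates are converted
to the internal 0-based half-open convention at exactly one boundary
(`read_gtf()`/`write_gtf()`), which keeps off-by-one errors out of the
event grammar.

## Known limitations

The event grammar covers pairwise isoform differences with a single
difference region; genes whose isoforms differ in several regions at once
yield one event per pairwise difference region only when regions are
separable after flank trimming, otherwise `complex`. The NB exact test
rounds scaled group sums to integers rather than quantile-adjusting
individual samples. The dispersion moderation is intentionally simple and
will under-fit gene-specific dispersion trends. The PWM scanner assumes a
fixed background composition per scan. None of these limitations affect the
planted-truth validation, but all would matter for production use on real
genomes.
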