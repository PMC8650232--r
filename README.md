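# splicelink

Bulk RNA-seq experiments that perturb a single regulator often change two
layers of the transcriptome at once: which genes are expressed, and how
their transcripts are spliced. When some of the splicing-regulated genes
are themselves transcription factors, the two layers may be causally
linked — the regulator reshapes TF isoforms, and the TFs reshape their
targets' transcription. splicelink is an R package for analysts who want to
test that hypothesis in a two-condition, replicated design. It takes gene
models (GTF), splice-junction counts, gene counts, promoter sequences
(FASTA) and a JASPAR-style motif collection, and chains five analyses:

1. **Splicing events.** Pairwise isoform comparison classifies each
   structural difference into one of ten types (ES, CassetteExon, A5SS,
   A3SS, A5SS&ES, A3SS&ES, MXE, 5pMXE, 3pMXE, IR). Each event is
   quantified per sample as the junction-read ratio
   `alt / (alt + model)`; intron retention uses exon–intron boundary reads
   as its alternative evidence. Group differences are tested with a
   pooled-variance Student's t-test, BH-adjusted; significant events are
   RASEs and their genes RASGs.
2. **Differential expression.** TMM normalisation, moderated
   method-of-moments dispersions, a conditional negative-binomial exact
   test, and DEG calls at fold change ≥ 2 or ≤ 0.5 with FDR < 0.05.
   FPKM is computed alongside.
3. **Promoter motifs.** Log-odds PWM scanning of both strands at the
   80%-of-score-range threshold; per-motif hypergeometric enrichment of
   down-regulated DEG promoters in three TSS windows (±1/2/3 kb); the
   consistent set = motifs enriched in all three.
4. **TF matching and overlap.** Motifs are matched to RASGs by TF name,
   and the overlap between TF motifs and enriched motifs is scored with an
   upper-tail hypergeometric test (`overlap_test()`).
5. **Network.** For every (TF splicing event, motif-supported DEG target)
   pair, Pearson correlation between splicing ratios and target FPKM
   across all samples; edges at |r| ≥ 0.95, p ≤ 0.005; export to
   TSV/SIF/GraphML for Cytoscape.

A deterministic synthetic-data generator (`simulate_dataset()`) emulates
the whole study — planted event types, ratio shifts, DE genes, promoter
motif instances and a TF→target regulatory drive — and writes every
standard-format file plus a truth table, so the entire pipeline is
validated against known ground truth.

## Worked example

```r
library(splicelink)

sim <- simulate_dataset(sim_config(seed = 1), dir = "demo")
pc <- pipeline_config(
  gtf = sim$paths$gtf, promoters = sim$paths$promoters,
  junctions = sim$paths$junctions, gene_counts = sim$paths$gene_counts,
  gene_lengths = sim$paths$gene_lengths, pfms = sim$paths$pfms,
  groups = sim$groups, out_dir = "demo_out")
res <- run_pipeline(pc)
cat(res$report, sep = "\n")
```

```
splicelink run report
genes: 80, events: 73 (complex excluded: 0)
RASEs selected: 23 in 23 RASGs (IR 2 / non-IR 21)
DEGs: 6 up / 13 down of 80 genes
motif hits: 106; consistently enriched motifs: 5
matched TFs: 5; motif overlap 5 (p = 0.000333)
network edges: 43 (candidates 55)
```

All 73 planted events are detected with their planted types (the 80-gene
study plants ~22 ratio shifts; 23 events pass p < 0.05, i.e. the planted
ones plus expected false positives). The five TF motifs are enriched in
down-DEG promoters in every window, and the network recovers the planted
TF→target edges:

```r
head(res$edges[, c("tf_gene", "event_id", "target_gene", "r", "p")], 4)
```

```
  tf_gene          event_id target_gene          r            p
1    G001 G001|ES|1166-1719        G006 -0.9983123 4.269895e-06
2    G001 G001|ES|1166-1719        G007 -0.9979064 6.570271e-06
3    G001 G001|ES|1166-1719        G008 -0.9924830 8.454625e-05
4    G001 G001|ES|1166-1719        G009 -0.9983208 4.227401e-06
```

Negative r is expected: the TF isoform shift represses these targets. Every
stage's table (events, ratios and tests, DEGs, FPKM, motif hits and
enrichment, TF–motif map, edge list, SIF/GraphML) is written to `out_dir`
with a plain-text run report.

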