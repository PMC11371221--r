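# orstrat

Phylostratigraphy, tandem-array detection and antennal-expression set logic
for insect odorant-receptor (OR) repertoires.

Ant genomes carry hundreds of odorant receptors, and the subset that detects
cuticular hydrocarbons — the nestmate-recognition cues — is thought to sit in
the nine-exon OR subfamily. Narrowing that subset down combines three
analyses that this package implements as one tested toolkit:

1. **Node-distance phylostratigraphy.** Every focal protein is searched
   against reference proteomes (externally computed BLAST tabular hits, or
   the built-in deterministic Smith–Waterman search for synthetic panels).
   After reducing to the best hit per species (lowest e-value), a protein's
   age is the *node distance* of its most distant hit species: the number of
   internal nodes on the tree path between the focal tip and that species
   (sister species = 1, self = 0). Proteins with no non-self hit at the
   e-value threshold (default `1e-5`) are *taxonomically restricted proteins*
   (TRPs). Category-by-stratum tables are compared with Pearson χ² and
   Benjamini–Hochberg adjustment.
2. **Tandem-array detection.** Genes on the same scaffold and strand, sorted
   by start coordinate, are chained into arrays whenever the gap
   `start(next) − end(previous)` is strictly below 20 kbp. Singletons are
   size-1 arrays, so the result is a partition. Array-size histograms and a
   category × array-size χ² test whether nine-exon ORs spread across arrays
   in proportion to their repertoire share.
3. **Tissue-enrichment set logic.** Raw transcript counts are pruned of
   genes detected in ≤ 1 sample; a gene is *upregulated in the antennae* when
   `log2FC > 0` and `padj < .05` against **every** other tissue (upset-style
   exclusive intersections are reported); a gene is *expression-restricted*
   when its raw count is `< 10` in every non-antennal sample. OR enrichment
   in these sets uses a two-sided Fisher exact test computed by full
   hypergeometric enumeration,
   `p = Σ_{x : P(x) ≤ P(obs)} dhyper(x)`.

A seeded synthetic-data generator (ladder species trees, gene families with
planted birth nodes, genome layouts with planted arrays, negative-binomial
counts with planted antennal effects) records its ground truth so every
stage is testable end to end without external data. The
negative-binomial DE test included for synthetic runs uses median-of-ratios
size factors, trend-moderated method-of-moments dispersion and a Wald t
test; real analyses can instead supply externally fitted DE tables
(`read_de_table()`).

## Worked example

The `analysis/` scripts run the whole workflow on synthetic data
(`Rscript analysis/01_simulate.R` … `05_report.R`). In miniature:

```r
library(orstrat)

sim  <- simulate_species_set(seed = 1, n_species = 12)
fam  <- simulate_gene_families(sim$tree, n_genes = 50, mode = "direct_hits", seed = 1)
best <- best_hit_per_species(fam$hits)
asg  <- assign_strata(best, sim$tree, fam$truth$gene_id)
format_ratio(length(find_trps(asg)), nrow(asg))
#> [1] "5/50, 10.0%"

report <- run_pipeline(pipeline_config(seed = 1))
summarize_report(report)
#> pipeline run: seed 1, config f2d775898d8fb2905a0b2670bb678c6c
#> phylostrat: 50 proteins age-assigned; TRPs 5/50, 10.0%; stratum recovery 100.0%
#> arrays: 29 arrays over 60 genes; planted partition recovered: yes
#> expression: 40 genes pruned; 140 upregulated-vs-all; planted recovery 100.0%; false inclusion 0.0%
```

Each line pairs a recovered quantity with the generator's planted truth:
all 50 planted birth nodes are recovered exactly, the 29 planted tandem
arrays are detected as a partition, and every planted antennae-upregulated
gene passes the three-way DE conjunction with no background gene admitted.
The 140 upregulated calls exceed the 100 planted effects because the 40
antennae-restricted genes are genuinely antennae-biased by construction.

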