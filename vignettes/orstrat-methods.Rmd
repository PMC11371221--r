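---
title: "Methods: node-distance phylostratigraphy, tandem arrays and antennal expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node-distance phylostratigraphy, tandem arrays and antennal expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orstrat)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open.

## The scientific setting

Odorant-receptor (OR) repertoires in ants are large and fast-evolving, and
the nine-exon OR subfamily is the leading candidate for detecting the
cuticular hydrocarbons that mediate nestmate recognition. Three questions
shape the analyses here: which genes are preferentially expressed in the
antennae, the main olfactory organ; how ORs are physically organized into
tandem arrays in the genome; and how old OR genes are relative to the rest
of the proteome.

## Node-distance phylostratigraphy

Each focal protein is compared against a panel of reference proteomes and
retained hits (e-value ≤ threshold, default `1e-5`) are reduced to the best
hit per species — the record with the lowest e-value, ties broken by higher
bitscore and then lexicographic subject id so the reduction is
deterministic. The protein's age is then the **node distance** of the most
distant hit species.

The node-distance convention needed a decision: counting "nodes between"
two tips does not by itself fix the endpoints. We count internal nodes on
the unique tip-to-tip path, including the MRCA and excluding both tips, so
that a sister species is at distance 1 and the focal species itself at 0.
This yields a metric that is zero for self, strictly increasing with
divergence depth, and well defined on multifurcating trees (the path walk
does not assume binarity).

Focal-species self-hits are excluded from the maximum — otherwise every
protein would trivially hit itself and no protein could be taxonomically
restricted. A protein with no non-focal hit at all is a **taxonomically
restricted protein** (TRP): node distance 0, no deepest species. Whether
the per-species best-hit reduction happens before or after taking the
maximum is immaterial (the max over species is unchanged), so the package
accepts any hit table.

Stratum distributions of two gene categories are compared with Pearson χ²
(no continuity correction) on the 2 × k category-by-stratum table, after
optional binning of integer distances into clade-style labels; raw integer
strata are always retained alongside. The test refuses tables with an
expected cell below 1 and asks for coarser bins instead of silently
computing an unreliable statistic. Families of comparisons run through
`stratum_enrichment()` are adjusted with Benjamini–Hochberg; the procedure
behind "adjusted p" was an open choice and BH is the standard FDR control.

## The similarity stand-in

Real analyses feed externally computed BLAST tabular files. For synthetic
end-to-end runs the package carries a deterministic local-alignment search:
exact Smith–Waterman affine-gap alignment (a gap of length L costs
`gap_open + L·gap_extend`, defaults 10 and 1, BLOSUM62) over all
query × subject pairs, with scores mapped to e-values by the Karlin–Altschul
form `E = K·m·n·exp(−λS)` with fixed `K = 0.041`, `λ = 0.267` (the usual
gapped-BLOSUM62 constants). The constants are deliberately frozen:
determinism matters more than statistical fidelity here, because only
threshold-crossing behaviour feeds downstream. No seeding, masking or
composition adjustment is attempted — panels are small enough for exact DP.
Two ranking modes exist for best-hit association because the use cases
differ: phylostratigraphy ranks by e-value, while associating
hand-annotated ORs with reference proteins ranks by percent identity under
an e-value gate (`rank_by = "pident"`).

## Tandem arrays

Genes are partitioned by (scaffold, strand) and chained whenever the gap
`start(next) − end(previous)` — 1-based inclusive coordinates, no −1
correction — is **strictly** below `max_gap` (default 20 000 bp). A gap of
exactly 20 000 bp does not chain. Unchained genes are size-1 arrays, making
the output a partition of the input, which is what the size histograms
assume. Three open points were settled as follows:

* an intervening gene on the opposite strand does not break a chain,
  because the strand partition comes first; the alternative reading is
  available as `break_on_opposite_strand = TRUE`;
* gaps are measured between adjacent genes of whatever set is passed in, so
  OR-only adjacency (ignoring intervening non-OR genes) is obtained by
  subsetting before the call;
* overlapping gene models chain rather than error, with a warning — near-
  adjacent models are common inside real OR arrays and an error would make
  genuine annotations unusable.

The category × array-size χ² uses gene counts (each gene under its array's
size), expected counts from the marginals, and demands expected cells ≥ 1.

## Expression filters and set logic

Counts are raw and may be fractional (pseudo-alignment output); filters
compare the real values, never rounded. Pruning removes genes detected
(count > 0) in at most one sample across all samples, all-zero rows
included. "Upregulated in the antennae versus all tissues" is the
conjunction of `log2FC > 0` and `padj < α` (strict, default .05) over every
comparison; upset counts use exclusive signatures, so each gene is counted
exactly once and the signature counts sum to the union. The
expression-restriction rule is applied per sample — raw count below 10 in
*every* non-focal sample — which is the stricter of the two readings of
"counts < 10 in other tissues"; tissue-mean semantics and an additional
focal-expression requirement are available as flags but are not defaults.

Fisher exact tests are computed by full hypergeometric enumeration of the
2×2 table (two-sided: the sum of point probabilities not exceeding the
observed one, with the conventional 1e-7 relative tolerance for
floating-point ties), and the reported odds ratio is the sample odds ratio
`ad/bc` — infinite when `bc = 0` — not the conditional MLE.

## The built-in NB differential-expression test

The DE engine of record for real data is external; the package consumes DE
tables as first-class input. The built-in test exists so synthetic
end-to-end runs need no external fit, and is deliberately transparent:

* median-of-ratios size factors (geometric-mean reference over genes
  positive in all samples; library-size ratios as fallback);
* per-gene method-of-moments dispersion from the pooled within-group
  variance of normalized counts (`variance = μ + αμ²`), floored at 1e-8;
* moderation of that noisy per-gene estimate toward a fitted
  mean-dispersion trend `α(μ) = a₀ + a₁/μ`, weighting the gene estimate by
  its residual degrees of freedom against a prior weight of 10 — with 3–4
  replicates a raw per-gene dispersion is far too variable, and shrinkage
  toward a trend is the standard remedy;
* a Wald test on `log2FC` (delta-method standard error through a 0.5
  pseudocount that keeps all-zero groups finite), referred to a t
  distribution whose degrees of freedom add the prior weight to the
  residual df;
* BH adjustment within each comparison.

Measured on the generator's own conditions, the null false-positive rate at
p < .05 sits near 0.04 and planted four-fold effects at 3–4 replicates are
recovered essentially completely; the acceptance script recomputes both.

## The synthetic-data generator

The generator emulates the statistical structure each stage assumes, with
truth recorded: a rooted **ladder** tree (focal tip nested deepest) so that
every node distance 1..n−1 is realized by exactly one species; gene
families with planted birth distances, emitted either as direct hits
(e-value 1e-50 for all species within the birth distance — recovery must be
exact) or as mutated homolog sequences (per-site substitution probability
`1 − exp(−r·d)`, default `r = 0.03` per node, no indels, protein lengths
120–360) so the similarity search must do real work; genome layouts whose
intra-array gaps are drawn below 20 kbp and inter-array gaps at or above
it, so the planted partition is the unique correct answer at the default
rule; and negative-binomial counts (mean-dispersion form, baselines
log-uniform on 20–2000, dispersion 0.05) over an
antennae/head/thorax/leg design with 3/4/4/3 replicates, with planted
four-fold antennae effects (5% of genes), single-sample-detected genes (2%)
to exercise pruning and antennae-restricted genes (2%, non-focal mean 0.3)
to exercise the restriction filter. The four planted classes are disjoint.

What the generator does **not** emulate: read-level error, alignment
ambiguity, correlated gene-gene expression, isoform structure, GC or length
biases, indels, domain shuffling, or annotation error. Passing tests
therefore demonstrate the correctness of the implemented logic under its
stated model, not robustness to every artifact of real sequencing data.
Note that antennae-restricted genes are genuinely antennae-biased by
construction, so evaluations of the upregulation conjunction count them
neither as planted effects nor as false inclusions.

## Numerical and reporting conventions

Coordinates are 1-based inclusive throughout; no half-open conversion
occurs anywhere. Ratio strings follow the reporting style `k/n, p%`:
one-decimal percentages truncate toward zero while integer percentages
round to nearest — the pair of conventions consistent with the reported
values they reproduce (e.g. 125/367 → "34.0%", 376/4288 → "9%"). Strict
inequalities are used exactly where stated: gap < 20 kbp, raw count < 10,
padj < .05. Problem sizes in the tests and acceptance script (50-gene
families, 12-species trees, 2000-gene count matrices, 1000-rep
calibrations) were chosen as the smallest sizes at which the asymptotic
tests are calibrated and recovery rates are stable across seeds.

## Known limitations

The Karlin–Altschul constants are not re-estimated per matrix, so absolute
e-values from the built-in search are approximate (thresholding behaviour,
which is what downstream code uses, is robust to this). The NB test is not
a replacement for a mature DE engine on real data — it has no outlier
handling, no independent filtering, and a linear dispersion trend. Node
distance treats tree topology only; branch lengths are ignored by design,
matching the age metric it implements.
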