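---
title: "Methods: ranked expression enrichment in brain atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranked expression enrichment in brain atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasenrich)
```

## The problem

Candidate gene lists for brain disorders come from assays with no spatial
resolution: differential expression in patient-derived neural cell models,
proximity to GWAS loci, rare-variant burdens from exome sequencing. To ask
*where in the brain* such genes act, `atlasenrich` projects them into
reference transcriptomic atlases of the normal human brain sampled at the
level of named nuclei and subfields, and scores every region for specific
expression of the list. The same polygenic logic is deliberately
threshold-free: no gene in the list needs to be individually remarkable;
the question is whether the list as a whole sits high in a region's
genome-wide expression ranking.

## Building the reference matrix

Each donor contributes a probe × sample matrix of normalized log-intensity
values, a sample → region annotation and a probe → gene annotation. The
per-donor chain is:

1. **Probe collapsing** — a gene's value in a sample is the arithmetic mean
   of its mapped probes, ignoring missing values; unmapped probes are
   dropped.
2. **Region aggregation** — samples with the same (whitespace-trimmed)
   region label are mean-averaged into one profile. Left/right homologues
   carry identical labels in the supported layouts and therefore pool
   automatically. A *merge map* defines composite regions (for example a
   subgenual cingulate profile assembled from several fine cortical
   labels); composites pool all member samples before averaging, so
   members with more samples weigh more. The alternative — an unweighted
   mean of member means — is available as
   `composite_method = "mean_of_means"`, but pooling is the default because
   it treats the composite exactly like any other named region whose
   samples happen to carry several labels.
3. **Within-region ranking** — each region column is replaced by ascending
   midranks (lowest expression = rank 1, ties get the average of their
   positions). Midranks are the tie convention of the Mann–Whitney U
   statistic used downstream, which keeps the two stages mutually
   consistent.
4. **Cross-region z-scoring** — each gene row is centred and scaled over
   its non-missing regions with the sample (n−1) standard deviation. A
   zero-variance row becomes all-zero (neutral) rather than being dropped,
   which keeps the gene vocabulary stable for set matching; a gene seen in
   fewer than two regions becomes missing. Both cases are flagged on the
   returned object.
5. **Donor averaging** — per-donor z matrices are averaged cell-wise over
   the donors in which each (gene, region) cell is present, and the
   per-cell donor count is recorded. Requiring all donors would discard
   most of a prenatal-style atlas, where individual donors cover only part
   of the region vocabulary.

The rank-then-z-then-average order is a genuine design choice: ranking
first makes each donor's regional profile scale-free before donors are
mixed, so a donor with globally brighter arrays cannot dominate the
average. The pipeline is deterministic — identical inputs give bit-identical
reference matrices — and every stage's invariants (midrank sums, row means
within 1e-9 of zero, row SDs within 1e-9 of one) are asserted in the test
suite.

## The enrichment statistic

For a region *r* with scores for *N* genes, of which *n_S* belong to the
matched query set and *n_B* to the background, the scores are re-ranked
within the region and

$$U = \sum_{g \in S} \mathrm{rank}(g) - \frac{n_S(n_S+1)}{2}, \qquad
\mathrm{AUROC} = \frac{U}{n_S\, n_B}.$$

AUROC is the probability that a randomly drawn set gene out-ranks a
randomly drawn background gene, with tied pairs counting one half; 0.5 is
the null, above 0.5 is region-specific (enriched) expression, below 0.5
depleted expression. Significance uses the Mann–Whitney null:

* **exact** (full enumeration of the rank-sum null) when the combined
  sample is at most 20 with no ties — this matters for desk-scale sets of
  half a dozen genes;
* otherwise the **normal approximation** with tie-corrected variance and a
  0.5 continuity correction. The approximation is accurate away from
  degenerate designs; with the smaller group at four or more observations
  its two-sided error against full enumeration stays below 0.02 at a
  combined n of 12 (and shrinks rapidly with n), while designs smaller
  than that never reach the approximate path under the default threshold.

Tests are two-sided by default, with the direction read from the AUROC
(sets can be significantly depleted, not only enriched); `alternative`
exposes one-sided variants. P-values are Benjamini–Hochberg-adjusted over
the regions of one reference matrix, and regions are ranked brain-wide by
descending AUROC with ties broken by region name so that output order is
reproducible. Set genes with no data in a region are excluded from that
region's test, and the per-region effective set size is reported.

For small pre-specified panels (feeding-circuit nuclei, neurostimulation
targets), `enrich_regions_of_interest()` reports the uncorrected p plus the
region's brain-wide rank from the full run. The pipeline driver applies
this mode automatically when fewer than `roi_threshold` (default 20) genes
match the reference, because the power of the AUROC test is driven by the
number of genes; with a handful of genes a brain-wide FDR claim would be
uninformative. The summary table then never marks such lists as brain-wide
significant.

## Gene-set handling

Symbols are normalized by stripping one trailing `-AS<k>` / `-IT<k>`
suffix — mapping antisense and intronic transcripts to their protein-coding
host — and upper-casing human symbols; mouse symbols keep their case. The
suffix rule is applied once, not recursively, matching the nomenclature it
mirrors. Lists with per-gene p-values can be reduced by a Bonferroni
filter with a configurable number of assumed tests (default 20,000, the
conventional genome-wide estimate) and an inclusive alpha boundary.

Overlap tests between lists, and scans against cell-type marker sets, use
the hypergeometric upper tail P(X ≥ k) after both sets are intersected with
an explicit universe, with FDR over the marker sets of a scan. The
universe is a first-class argument rather than a constant because overlap
p-values are only interpretable relative to a stated universe; the natural
default is the intersection of the expression platform's vocabulary with
the marker resource's vocabulary. Cross-species scans map the query
through a two-column homolog table first.

## Fasting differential expression

The single-cell analysis compares fed and food-deprived cells within each
(dataset, batch) stratum — batches are never mixed, because condition is
confounded with batch in the supported designs. Per gene and stratum both
one-sided Mann–Whitney tails are computed from the same U (deprived > fed
and deprived < fed), then combined across strata with Fisher's method,
separately per direction, giving meta p-values for up- and for
down-regulation. BH correction is applied per direction over all tested
genes (the joint alternative over both directions is a configuration
choice left to the caller); a gene's direction is called from the smaller
meta p when either direction's FDR clears alpha. Genes absent from a
stratum combine over their available strata with df = 2 × (available k).
Because the test is rank-based, input expression can be on any monotone
log-like scale and the two datasets need not be scale-compatible.
P-values are clamped at 1e-300 before the log so Fisher's statistic stays
finite; at the scales involved this has no numerical effect.

Gene filtering before testing: require a homolog-table entry (for
cross-species interpretation), nonzero expression in at least one cell and
nonzero variance across cells; each criterion's removal count is logged.

## What the generators emulate — and what they do not

`simulate_atlas()` draws one set of baseline gene means shared across
donors, adds a region intercept and Gaussian sample noise (default SD 1 on
the log-like scale, three samples per region, three donors, 5,000 genes,
40 regions, two probes per gene with fixed small offsets), and shifts a
planted gene set by `effect × noise_sd` in one region only. Incomplete
donor coverage is emulated by dropping (donor, region) blocks at a
configurable rate. `simulate_sc()` draws lognormal-style baseline means,
batch intercepts, Gaussian cell noise (SD 1), floors at zero and applies
dropout (default 30% zero-inflation — a typical sparsity for normalized
single-cell matrices), with planted ±`log_effect` shifts in the deprived
condition. `simulate_gene_lists()` plants an exact overlap between two
lists drawn from a shared universe.

These generators match what the pipeline *consumes* (already-normalized
continuous values), not how real data arise: there is no negative-binomial
count layer, no spatial or co-expression correlation between regions or
genes, no donor-specific array effects, and dropout is independent of
expression level. Passing the planted-recovery tests therefore
demonstrates that the statistics recover signals of the stated form at the
stated sizes — it does not certify performance under correlated noise or
platform artefacts, which only real atlas data can probe. All generators
are seed-deterministic, and a base seed is expanded into per-component
substreams so adding one consumer of randomness does not perturb another.

## Numerical and validation choices

* AUROC agreement with an exhaustive pairwise-comparison oracle is asserted
  to 1e-12 over 500 random instances with and without ties.
* Exact Mann–Whitney p-values are compared with full label enumeration for
  every design with combined n ≤ 12 and every achievable U.
* BH adjustment is compared with an independent step-up implementation to
  floating-point agreement on 1,000 random vectors; the hypergeometric
  tail with a log-binomial summation to 1e-10 relative error on exhaustive
  small grids and spot checks to N = 10,000.
* Calibration: on a null synthetic atlas (5,000 genes × 40 regions × 3
  donors) the fraction of 2,000 random-set tests with p < 0.05 must lie in
  [0.03, 0.07] and the mean AUROC in [0.49, 0.51]. Recovery: a 200-gene
  set planted at 2 noise-SD must take brain-wide rank 1 with FDR < 0.05 in
  at least 95 of 100 seeds; in the single-cell analysis (3 batches, 150
  cells per arm, 100 planted genes at log-effect 1.0) at least 90% of
  planted genes must be recovered at direction-specific FDR < 0.05 with at
  most 7% of null genes called and no sign errors, and the null meta-p
  distribution must pass a Kolmogorov–Smirnov uniformity check. These
  problem sizes were chosen as the smallest at which the planted effects
  are comfortably identifiable while a full validation sweep still runs in
  a few minutes.
* Ties everywhere follow the midrank convention; brain-wide rank ties break
  by region name; all analysis stages are seed-free, with randomness
  confined to the generators.

## Known limitations

Probe re-annotation is out of scope: the probe → gene map is taken as
given, and its quality bounds the reference matrix. Composite-region
pooling weights members by sample count, which is a modelling choice, not
a ground truth. The enrichment test treats genes as exchangeable and
independent within a region's ranking; co-expressed gene sets violate this
and can inflate significance, as with any rank-based gene-set statistic.
The fasting analysis assumes strata are independent, which dissects
technical batches but cannot remove within-batch confounding. Finally,
symbol matching is by normalized string equality — full nomenclature
history mapping is deliberately not attempted.
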