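---
title: "Multi-region immune and mutational analysis of metastatic cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region immune and mutational analysis of metastatic cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mima)
```

## The analytical problem

When several metastases of the same patient are sequenced, every somatic
mutation (and every expanded T-cell clone) can be placed on the patient's
metastatic lineage: *stem* events are present in every metastasis, *clade*
events in some but not all, and *private* events in exactly one.  This
three-way partition is the organizing axis of `mima`.  Around it the
package implements the quantitative procedures such a study needs:

* detection and validation rules for targeted resequencing of WES calls;
* 96-channel mutational profiles, signature refitting by non-negative
  least squares with an attribution threshold, and residual/entropy
  diagnostics, stratified by lineage;
* a simulation-based immunoediting test comparing observed neo-epitope
  yield with context-matched expectations;
* TCR repertoire clonality, overlap, CDR3 Jaccard clustering, and
  concordance of repertoire trees with genomic sample trees;
* tumor-microenvironment scores: cytolytic activity, immunophenogram/IPS
  and k-nearest-neighbour cell densities.

Real multi-region cohorts of this kind are controlled-access, so the
package is built around a seeded synthetic cohort generator
(`cohort_config()`, `generate_cohort()`) that reproduces the statistical
structure every stage assumes and carries a full ground-truth manifest.
All empirical statements below are the ones the test suite computes.

## The synthetic cohort generator

A cohort is drawn case by case from a single integer seed (one derived
stream per case, so cohorts are reproducible byte for byte).  Per case:

* **Topology.** Metastasis count is uniform over `metastases_range`
  (default 5–20) and the samples are partitioned into up to `n_clades`
  clades (default 3) by random recursive bipartition — multi-region
  breast-cancer studies typically observe only a handful of clades, so
  no topology inference is emulated.
* **Mutations.** Poisson counts are placed on the root edge (stem, mean
  200), each clade edge (mean 120) and each leaf (private, mean 25),
  giving per-case burdens of a few hundred mutations, in line with
  published multi-metastasis burdens.  Each mutation draws a signature
  from the configured mixture, a 96-channel class from that signature,
  and a genomic position that actually carries the drawn trinucleotide
  context: gene proportional to a reference catalog's relative rate,
  position proportional to a per-base coverage weight.  Because channels
  are drawn first and placed second, the marginal spectrum of a large
  case converges to the configured mixture (tested at cosine ≥ 0.98 for
  5,000 mutations).
* **Reads.** Depth is Poisson (mean 150); alt reads are Binomial(depth,
  purity × CCF / 2), the diploid heterozygous expectation.  A configured
  fraction of stem/clade mutations is subclonal (CCF ~ U(0.2, 0.7)).
* **Expression.** Mutant-allele expression log2(TPM × RNA-VAF + 1) is
  normal around a configurable stem > clade > private gradient.  A
  clade-structured immune level scales immune-gene TPM, repertoire size
  and lymphocyte density jointly, which is what makes CD3–TCR
  correlation and organ-structured repertoires emergent rather than
  wired in.
* **TCR.** Each site carries a Poisson number of clones around
  `tcr_clones_per_site`; a fraction is shared case-wide (stem) or
  clade-wide.  Clone sizes follow a truncated discrete power law
  (exponent 2), with stem clones expanded.  Per-site clone richness is
  deliberately Poisson-variable: exactly constant richness produces
  degenerate two-valued Jaccard matrices that no real repertoire shows.
* **Immunoediting.** Peptide binding is decided by a deterministic
  hash predicate (`hash_binder()`) with a configurable binder rate, a
  reproducible predictor-free surrogate with the same interface as an
  affinity-predictor adapter.  With `depletion_strength < 1`, missense
  mutations whose mutant 9-mers bind a case allele are retained only
  with that probability and otherwise re-placed at a context-matched
  non-binding position — the generator's model of neo-antigen depletion.
* **HLA, centroids.** Six synthetic class-I alleles per case; a
  configurable number of cases receives an allele with copy number
  < 0.5 and p < 0.05 (the LOH calling rule).  Per-sample centroid point
  sets are uniform or Gaussian-clustered with cancer/stromal/lymphocyte
  labels.

What the generator does **not** emulate: sequencing error and mapping
artefacts, copy-number variation (CCF is an input concept, not
inferred), indels, TCR sequencing error networks (so clusters equal
vertices and the cluster-level Gini is degenerate at 0), and any real
binding-affinity landscape.  Tests passing on this cohort therefore
validate the *procedures*, not performance on raw patient data.

## Lineage classification and landscape rules

`classify_lineage()` is the literal definition above; it refuses
single-sample cases.  Presence calls from reads use alt ≥ 3 and
VAF ≥ 0.02 (configurable; `presence_calls()`).  The targeted-sequencing
rules in `ts_detect()` are: coverage ≥ 500×, AF ≥ mean + 3 SD of the
locus controls, AF ≥ 1%, and a sample-level QC failure when > 90% of a
sample's mutations sit below 5% AF.  `validation_metrics()` computes
sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
and accuracy, with undefined denominators reported as `NaN` rather
than 0.  Germline concordance uses the Jaccard fraction with a strict
> 0.90 relatedness rule (the denominator is configurable to
min(|A|,|B|) because the original definition does not fix the base).
Posterior binarization maps p ≥ 0.5 to 1 — only entries strictly below
0.5 become 0 — after removing rows below 0.5 everywhere.  The
prevalence-cluster filters apply, in order: drop clusters never
exceeding 0.1 prevalence; call presence per sample when ≥ 40% of member
mutations have VAF > 0.01; and, if several clusters are present in all
samples, keep only the most prevalent.  Mutant-allele expression is
z-scored within case (per-case rather than per-cohort normalization,
since the plotted quantity is a within-patient contrast), with z = 0
when the SD degenerates.

## Signature analysis

Profiles use the canonical pyrimidine-centred 96-channel order;
purine-reference records are collapsed by reverse complement.  Exposure
refitting solves min ‖m − S·e‖² with e ≥ 0 by Lawson–Hanson NNLS (no
sum constraint, so exposures are in mutation units; cross-checked in
the tests against an independent NNLS implementation).  The attribution
threshold is max(3% of the sample total, 10 mutations) — the published
wording ("a minimum of either 3% … or at least 10") is ambiguous, and
the max() reading is the conservative one that prevents spurious
attribution in large samples; min() is available as a switch.  The
threshold is applied iteratively (drop, refit, repeat) until stable,
since the original text does not say whether filtering precedes or
follows refitting.  De novo extraction uses multiplicative-update NMF
under generalized KL divergence (200 iterations, relative tolerance
1e-6, uniform random initialization) on bootstrap resamples of the
sample set, with consensus signatures formed by greedy cosine
clustering at 0.8.  Profile diversity is the Shannon entropy of the
normalized 96-channel profile (natural log; uniform = ln 96 ≈ 4.564).
For two-profile similarity the observed cosine is referred to a
label-swap null (pool the mutations, resplit at the observed totals);
small p means the profiles are more similar than pooling allows.

## The immunoediting test

Simulated mutation sets preserve each observed mutation's substitution
and trinucleotide context exactly (up to strand), reassigning gene
(∝ relative background rate among context-bearing genes, renormalized)
and position (∝ coverage weight).  The context multiset invariant is
asserted on every run.  Neo-epitopes are counted per mutation: a
missense mutation scores 1 when ≥ 1 of its mutant 9-mers (from a
17-residue mutant-centred window, truncated at protein ends) binds ≥ 1
allele at IC50 ≤ 500 nM under the predicate, and gene and transcript
RPKM both exceed 1.  The per-sample statistic is the set of 100
observed/expected ratios; the empirical p is (k+1)/(n+1) with k the
number of ratios ≥ 1.  The pseudo-count reproduces the ≈ 0.01 value
that a sample with all 100 ratios below one receives; the raw
"fraction larger than 1" would give an impossible exact 0.  Ratio
conventions: expected = 0 with observed > 0 counts toward k;
observed = expected = 0 is defined as ratio 1 (also toward k) — both
conservative against false depletion claims.  Under the null generator
the p-values are approximately uniform (the suite checks
frac(p ≤ 0.05) ∈ [0.02, 0.10] over 200 independent samples at ~135
mutations each); at depletion strength 0.15 the per-sample power at
α = 0.05 is essentially 1.  Grouped analyses compare the observed mean
ratio with 20 nulls, each built by simulating a pseudo-observed set per
sample and 100 inner simulations against it.

## TCR repertoire statistics

UMI groups must match the TNNNNTNNNNTNNNNT template and exceed 80%
mean pairwise identity to emit a majority-vote consensus.  Clones are
identical CDR3 nucleotide sequence + V gene (+ J by default; the
`key = "v"` dialect matches the network definition that names only V).
Public clones — shared between patients or present in an external
database (nucleotide matching) — are removed everywhere.  Clonality
metrics are means over 20 subsamples of 1,000 reads drawn without
replacement (samples below depth are excluded, not exhausted): vertex
and cluster Gini by the mean-absolute-difference formula without
small-sample correction, and mean/largest clone sizes in two dialects —
percent of subsample reads (default) and the as-printed
per-cluster-count form, both emitted because the printed formulas'
denominators cannot yield the reported percentage units.  The overlap
coefficient is C_ij / (½(C_i + C_j)) on subsampled clone sets.  CDR3
amino-acid Jaccard similarity feeds complete-linkage clustering;
cophenetic distances on edge-weighted trees are path sums of edge
weights, and tree concordance reports the Pearson correlation of those
path-sum vectors plus the Robinson–Foulds bipartition distance, with a
leaf-label permutation p.

The organ test deserves its own paragraph.  Reshuffling TCR reads
uniformly across metastases (preserving per-sample totals) destroys
*all* site structure, not just organ structure; when sites carry
private clonal expansions — as real metastases and the generator both
do — statistics computed on reshuffled trees have a different noise
scale than the observed one, and an organ-concordance p built on that
null is bimodal even when organ labels are assigned at random.  The
package therefore separates two questions.  `p_organ` asks whether
organ labels align with repertoire similarity: the organ-separation
statistic (mean between-organ minus mean within-organ Jaccard
distance) is referred to permutations of the organ labels, which is
exactly valid by exchangeability and approximately uniform under
random organ assignment (verified in the suite).  `p_structure` asks
the reshuffling question: the reshuffled trees are compared among
themselves and with the observed tree by cophenetic correlation, and
the observed tree is called structured when it is more atypical among
the reshuffled trees than they are among each other.  An RF distance
to an organ-grouping reference tree under the reshuffle null
(`p_rf`) is reported as well.

## Microenvironment scores

Cytolytic activity is √((GZMA + 0.01)(PRF1 + 0.01)); the 0.01
pseudocount is configurable.  The immunophenogram z-scores genes
across samples, averages member genes into 26 parameters (equal
weights within a parameter, as the published description does not fix
them), averages parameters within the four categories, and aggregates
the ±1-weighted parameter scores; IPS maps the aggregate with
`round(z·10/3)` clipped to 0–10, which reproduces the published
anchors (z ≥ 3 → 10, z ≤ 0 → 0) and interpolates linearly between
them.  The packaged panel is a synthetic stand-in with the published
structure (20 single factors + 6 cell types over MHC/CP/EC/SC) and can
be replaced by any CSV with the same columns.  Cell density at a
centroid is N/(π·d_N²) with N = 50 by default, d_N the distance to the
Nth nearest neighbour within the density-defining class (self
excluded, ties broken by point index); the implementation chunks the
distance computation and is tested against an O(n²) oracle.

## Numerical choices and degenerate inputs

Single-element or constant z-score vectors are defined as 0.  NNLS
falls back to an all-zero exposure fit (rmse = rms of the profile,
flagged) when the attribution threshold removes every signature.
Empirical p-values always use the (k+1)/(n+1) pseudo-count and ties
count toward the numerator.  Complete-linkage merge ties are resolved
by `stats::hclust`'s deterministic ordering with lexicographic sample
labels.  All randomness flows through one seed argument per entry
point; library code never perturbs the caller's RNG state.

## Problem sizes used by the tests

The suite runs entirely on generated data: a 2-case fixture cohort
(5–8 metastases, ~150–300 mutations per case), a 200-sample null
cohort and a 10-sample depleted cohort for the immunoediting
calibration and power checks, 120 samples for planted-signature NMF
recovery, 20 + 8 seeded runs for organ-test calibration and power, and
500–10,000 points for density oracles.  These sizes were chosen to
estimate each property with comfortable statistical margin while
keeping a full run in a few minutes on one CPU.

## Known limitations

The binding predicate is a surrogate: absolute neo-epitope counts are
not comparable to predictor-based pipelines, only the observed/expected
contrasts are.  The cluster-level Gini is uninformative on error-free
synthetic repertoires.  Coordinates live in gene space (CHROM = gene,
POS = CDS position), so genome-browser interoperability needs a
liftover the package does not provide.  The grouped immunoediting null
is expensive (20 × 100 simulations per sample) and is run at reduced
replicate counts in examples.
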