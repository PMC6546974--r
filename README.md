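# mima — Multi-region Immune and Mutational Analysis

`mima` analyses patients with **multiple sequenced metastases**. Its
organizing idea is the metastatic lineage of every somatic event: a
mutation or an expanded T-cell clone is **stem** when present in all of a
patient's metastases, **clade** when present in some but not all, and
**private** when confined to one. Around that partition the package
implements, as tested reusable functions:

* **Mutation landscape** — lineage classification from presence
  matrices; targeted-resequencing detection rules (≥ 500× coverage,
  AF ≥ control mean + 3 SD, AF ≥ 1%, sample QC at 90%/5%);
  WES-vs-TS sensitivity/specificity/precision/accuracy; mutant-allele
  expression z-scores by lineage; germline concordance (> 90% ⇒
  related); posterior binarization and prevalence-cluster filters that
  prepare tree-inference inputs.
* **Mutational signatures** — 96-channel pyrimidine-centred profiles;
  exposure refitting by non-negative least squares,
  min ‖m − S·e‖² s.t. e ≥ 0, with the attribution threshold
  max(0.03 · total, 10 mutations); KL-divergence NMF extraction with
  bootstrap consensus; cosine matching; residual RMSE, Shannon entropy
  and bootstrap similarity diagnostics, stratified by lineage.
* **Immunoediting** — mutant-centred 9-mer enumeration with the
  IC50 ≤ 500 nM / RPKM > 1 filters (counting per mutation); simulation
  of context-preserving mutation sets (gene ∝ background rate,
  position ∝ coverage); the observed/expected neo-epitope ratio test
  with empirical p = (k+1)/(n+1) over 100 replicates; grouped
  mean-ratio nulls; HLA LOH accounting (CN < 0.5 and p < 0.05).
* **TCR repertoires** — UMI consensus (TNNNNT... template, > 80%
  identity); clones as CDR3nt + V(+J); public-clone removal; sharing
  classification; subsampled Gini/MCS/LCS at 1,000 reads × 20 repeats;
  overlap O(i,j) = C_ij / (½(C_i + C_j)); CDR3aa Jaccard clustering
  (complete linkage); organ permutation tests; path-sum cophenetic and
  Robinson–Foulds tree concordance; CD3–TCR-read correlation.
* **Microenvironment** — cytolytic score √(GZMA · PRF1) (0.01
  pseudocount); immunophenogram/IPS (aggregate z ≥ 3 → 10, ≤ 0 → 0);
  kNN cell density Σ_N = N/(π·d_N²) with N = 50.
* **Synthetic cohorts** — `generate_cohort()` draws seeded
  multi-metastasis cohorts with ground-truth lineages, exposures, TCR
  sharing, HLA LOH and an optional neo-epitope depletion effect, so the
  entire pipeline is testable without controlled-access data.
  `run_pipeline()` orchestrates all stages end to end.

## Worked example

```r
library(mima)
cfg <- cohort_config(n_cases = 2, metastases_range = c(5, 8),
                     stem_mean = 80, clade_mean = 50, private_mean = 15,
                     tcr_clones_per_site = 60, cells_per_sample = 200,
                     seed = 7)
cohort <- generate_cohort(cfg)
case <- cohort$cases$CASE01

classify_lineage(case$presence)$counts
#>    stem   clade private
#>      73      91      98
```

Of this case's 262 mutations, 73 are carried by all six metastases, 91
by a subset, and 98 by one site only. Refitting the 96-channel profile
against the cohort's four-signature catalog:

```r
fit_exposures(build_profile96(case$mutations), cfg$signature_catalog)
#> exposure_fit
#> SBS_S1 SBS_S2 SBS_S3 SBS_S4
#>  59.72  65.93  74.87  68.95
#> rmse: 1.3107; attributed: SBS_S1, SBS_S2, SBS_S3, SBS_S4
```

All four signatures clear the max(3%, 10) attribution threshold; the
exposures are in mutation units and sum to ≈ the profile total. The
immunoediting test for the first metastasis compares its neo-epitope
count with 100 context-matched simulations:

```r
rates <- build_gene_rates(cohort$reference_catalog)
mut1 <- case$mutations[case$presence[, 1], ]
observed_expected_test(mut1, rates, cohort$gene_model, case$hla,
                       hash_binder(cfg$binder_rate), seed = 1)
#> neoepitope_test: observed 42, mean expected 41.01, p = 0.6139 (100 reps)
```

p ≈ 0.61: the observed yield is unremarkable — this cohort was drawn
with `depletion_strength = 1` (no immunoediting), so that is the
correct call. TCR sharing and the concordance of the repertoire tree
with the genomic sample tree:

```r
round(colMeans(classify_tcr_sharing(case$repertoires)$site_fractions), 3)
#>    stem   clade private
#>   0.200   0.099   0.701

jt <- jaccard_tree(case$repertoires)
tree_concordance(case$tree, jt$tree, n_perm = 1000, seed = 1)
#> genomic vs TCR tree: cophenetic r = 0.871, RF = 1, p = 0.0200
```

A fifth of each site's TCR reads sit in case-wide (stem) clones, and
the CDR3-Jaccard tree mirrors the genomic clade structure (r = 0.87,
label-permutation p = 0.02). Microenvironment scores:

```r
immunophenogram(case$tpm)$ips
#> CASE01_M01 CASE01_M02 CASE01_M03 CASE01_M04 CASE01_M05 CASE01_M06
#>          1          1          0          0          0          0

median(knn_density(case$pointsets[[1]], N = 50))
#> [1] 6e-05   # cells per square pixel at site 1
```

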