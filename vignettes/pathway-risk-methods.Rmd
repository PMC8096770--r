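---
title: "Methods: pathway-level dissection of polygenic disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level dissection of polygenic disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpes)
```

pathpes asks a single question five different ways: *is the genetic risk of
a complex disease concentrated in particular biological pathways?* The
motivating disease is Parkinson disease (PD), but nothing in the machinery
is PD-specific. This vignette explains each statistical component, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical choices
a maintainer would want written down.

## 1. Pathway-specific polygenic effect scores

For each gene set in a collection (e.g. MSigDB "Canonical Pathways" in
GMT format), the scan restricts GWAS summary statistics to variants lying
inside member-gene bodies — deliberately *not* flanking regulatory
windows, so the score measures coding-adjacent risk only. The stack is:

1. **Pre-filter**: keep variants with association `p <= 0.05` (inclusive)
   and MAF strictly above 1%. The fixed 0.05 ceiling avoids per-set
   threshold tuning and the overfitting it invites when thousands of sets
   are compared.
2. **LD clumping** (`ld_clump()`): greedy; the most significant remaining
   variant becomes an index, and candidates within 250 kb on the same
   chromosome with dosage `r^2 >= 0.1` are discarded. `r^2` is computed on
   the analysis cohort's own dosages — there is no external reference
   panel, and p-value ties break by genomic position so results are
   reproducible.
3. **Scoring** (`compute_pes()`): `score_i = sum_j beta_j dose_ij / m_i`,
   the per-SNP average of effect-allele doses weighted by the reference
   log-odds. Averaging over the `m_i` non-missing variants (rather than
   the raw sum) keeps scores comparable across samples with different
   missingness; `normalize = "sum"` switches to the raw sum. Alleles are
   harmonized to the panel's counted allele, so the score is invariant to
   which allele a file happens to count.
4. **Association** (`fit_pes_association()`): logistic regression of
   status on the standardized score plus covariates (age at onset for
   cases / age at examination for controls, sex, and principal
   components; 20 PCs by default, capped at what the phenotype table
   carries). Nagelkerke's pseudo-R² comes from the full versus
   covariate-only likelihoods.
5. **Permutation p** (`permutation_pvalue()`): case/control labels are
   permuted with covariates staying attached to their samples; the
   statistic is the absolute Wald z of the score term (a statistic, not a
   p-value, so separation in a permuted fit cannot poison the null
   distribution), and `p = (1 + #{|z*| >= |z|}) / (n_perm + 1)`. The
   empirical p can therefore never drop below `1/(n_perm + 1)` — with the
   conventional 1000 permutations, the floor is just under 0.001.
6. **Liability conversion** (`liability_r2()`): the Lee et al. (2012)
   transformation to the liability scale given population prevalence `K`
   (default 0.005, an aged-population PD estimate) and the sample case
   proportion.

**Two-phase replication.** Sets whose training empirical p falls below the
scan-wide Bonferroni line `alpha / n_sets` are re-evaluated, with the
identical procedure, on an independent testing cohort; a set is
*replicated* when it passes the same line there. The Bonferroni
denominator is the number of sets *scanned*, including sets that end up
with zero usable variants — a set that cannot be tested was still part of
the family of hypotheses. Both the scan-wide line and the
replication-stage line `alpha / n_advanced` are reported
(`scan_thresholds()`), because downstream rare-variant analyses
conventionally use the latter.

## 2. Rare-variant burden: SKAT-O

`skat_o()` implements the optimal unified test from first principles.
The null model is the covariates-only logistic regression; per-variant
weights are `Beta(maf; 1, 25)` densities (up-weighting rarer alleles);
and the family statistic interpolates the variance-component (SKAT) and
burden score statistics, `Q_rho = (1 - rho) Q_SKAT + rho Q_burden`, over
the conventional grid `rho ∈ {0, 0.1², ..., 0.5², 0.5, 1}`.

Numerics worth recording:

- Tail probabilities of the weighted chi-square forms are computed by
  **exact characteristic-function inversion** (Imhof's integral via
  adaptive quadrature), with the kurtosis-corrected **Liu moment-matching
  approximation** as fallback when the inversion fails or the tail is
  below ~1e-9, where inversion loses relative accuracy. The reported
  object records which route was taken.
- The omnibus p integrates the minimum-p event over the shared
  chi-square(1) mixture component (48-node Gauss–Legendre after the
  substitution `x = u²`, which removes the density's square-root
  singularity at zero). `rho = 1` is capped at 0.999 inside this
  integration only, as the mixture representation degenerates there.
- A single-element `rho` grid short-circuits to the exact component test:
  `rho = 0` is plain SKAT, `rho = 1` the weighted burden test. These
  reductions are tested to 1e-10 against independently coded closed
  forms.
- Missing genotypes are mean-imputed per variant before kernel
  construction (standard for score tests); MAFs and MACs are computed in
  the combined case + control panel.

`scan_burden()` crosses gene sets with masks — three functional
categories (missense, loss-of-function, CADD > 12) × two frequency
ceilings (MAF ≤ 3%, MAF ≤ 1%), all with minor allele count ≥ 3. The
annotation table is long-format, so a variant may legitimately carry
several category labels at once. Empty masks yield `NA` rows, mirroring
how such cells are conventionally reported. Gene-level prioritization
reuses the same scan with `singleton_collection()`.

## 3. Case-only co-expression communities

The transcriptome map asks which genes are co-regulated *within cases*:

1. `z_transform_genes()` standardizes each gene (population SD, i.e.
   divisor n; zero-variance genes are dropped and counted).
2. `select_discriminative_genes()` ranks genes by
   extremely-randomized-trees importance (ranger, `extratrees` split
   rule) for case/control classification and keeps those above the mean
   importance. The selector is pluggable (`importance_fun`) because the
   mean-importance rule, while conventional, is arbitrary.
3. `case_correlation_graph()` drops controls and keeps edges with Pearson
   `r >= 0.8` (inclusive). Only strong positive correlations survive by
   construction; edge weight is the correlation itself. Louvain runs
   weighted — the thresholded graph could also be treated as binary
   (`weighted = FALSE`), and with the threshold this high the difference
   is small.
4. `detect_communities()` is igraph's Louvain (resolution 1 by default,
   exposed as config), seeded for reproducible node order; the returned
   modularity is *recomputed* by `graph_modularity()`, an independent
   implementation of the weighted Newman formula, and the two must agree
   to 1e-12 — a standing cross-check between the igraph backend and the
   package's own arithmetic.
5. `community_enrichment()` uses the one-sided upper-tail hypergeometric
   (over-representation only) with Bonferroni correction over *all*
   community × pathway tests performed. The enrichment universe defaults
   to the post-selection gene list — the genes actually eligible to enter
   communities — because testing against the whole genome would count the
   case/control selection step itself as "enrichment". A wider universe
   can be passed explicitly.

## 4. Cell-type specificity deciles

Specificity is the fraction of a gene's total expression attributable to
one cell type (`compute_specificity()`; rows sum to 1). Per cell type,
genes with nonzero specificity are ranked and cut into ten equal-count
bins (ties share their mean rank's bin; an all-tied column is a
"degenerate specificity" error). Zero-specificity genes are excluded
before binning — the alternative convention of a dedicated zero bin is
available by prefiltering, but exclusion keeps bins comparable across
cell types. Per decile, the polygenic R² is computed by exactly the
pathway stack of Section 1 restricted to the decile's gene bodies, then
`decile_trend_test()` regresses the ten liability-R² values on the decile
index with the per-decile SNP count as covariate, one-sided for an
*increasing* trend. A constant SNP-count covariate is dropped, and an
exactly flat profile (zero residual variance) resolves to `p = 0.5`
rather than 0/0. A cell type is reported only when the one-sided p is
below 0.05 in both the training and the testing phase. Bin count is
configurable (`n_bins`); deciles are the default.

## 5. SMR and HEIDI

`smr_test()` uses each gene's top cis-eQTL as a single instrument:
`b_smr = b_GWAS / b_eQTL` is the change in log odds per SD of expression,
with `T_SMR = z²_GWAS z²_eQTL / (z²_GWAS + z²_eQTL)` on one chi-square
degree of freedom. `heidi_test()` then asks whether *other* cis SNPs tell
the same story: under a single shared causal variant all `b_xy(i)`
estimates agree; under linkage of distinct causal variants they do not.
Eligible SNPs have LD `0.05 < r² < 0.9` with the top SNP (near-copies
carry no independent information; near-independent SNPs are not
instruments for the same signal), at most 20 are used (strongest eQTLs
kept), and fewer than 3 makes the test "not assessable" rather than a
pass or fail. The heterogeneity statistic is the sum of squared
standardized deviations, referred to its weighted chi-square null via the
same characteristic-function inversion as SKAT-O; a singular covariance
falls back to moment matching and is flagged. Genes pass overall when
`p_smr` clears the Bonferroni line over the genes tested and
`p_heidi >= 0.01`. Per-set enrichment of passing genes uses a 1-df
goodness-of-fit chi-square against a background rate, reported one-sided:
excesses get the upper tail, deficits report `p >= 0.5` (a depleted set
is not "enriched"). The published multi-SNP SMR variant is *not*
implemented; "multi" here means Bonferroni summarization over the genes
of a set, and the multi-SNP extension is a possible future addition.

## 6. What the synthetic data emulates — and what it does not

Every generator is a pure function of its arguments and seed, and the
defaults *are* the study conditions the test suite runs under.

- **Genotypes** (`sim_genotypes()`): Gaussian threshold copula — latent
  compound-symmetric blocks thresholded at each variant's MAF, two
  independent haplotypes summed. This yields exact Hardy–Weinberg
  genotypes with controllable block LD, but not realistic human LD decay,
  allele-frequency spectra, or recombination maps.
- **Phenotypes** (`sim_case_control()`): liability threshold with
  prevalence `K = 0.2` by default. The epidemiological PD prevalence
  (0.005) would leave a few cases per thousand samples at desk scale;
  the liability-conversion formula itself is exercised at `K = 0.005` in
  its own tests. Age/sex covariates are attached but carry no
  confounding; PCs are computed from the simulated genotypes and are
  essentially noise — the pipeline adjusts for them to exercise the
  plumbing, not because stratification is simulated.
- **Reference summary statistics** (`sim_summary_stats()`): vectorized
  logistic score test with one-step effect estimates, the statistic
  large-cohort GWAS engines use. This makes reference cohorts of tens of
  thousands of samples cheap, which matters because weight noise — not
  cohort size — is the binding constraint on synthetic score power.
- **The pathway-scan study** (`sim_pes_study()`): 50 disjoint sets over
  100 single-gene LD blocks, heritability 0.3 concentrated in one planted
  set, training n = 2000. Under the global null the scan's empirical
  p-values are uniform; with the planted set the scan ranks it first.
- **The cell-type study** (`sim_celltype_study()`): 400 genes × 4
  variants, reference n = 20 000, training/testing n = 3000/2500,
  h² = 0.9, twelve cell types with Dirichlet(3) specificity rows, and
  effect SDs `∝ (0.15 + specificity_planted)`. Three choices here are
  deliberate and worth explaining. First, the *baseline* term: a purely
  proportional coupling makes realized per-gene heritability so
  heavy-tailed (chi-square with few degrees of freedom scaled by tiny
  specificities) that the planted decile gradient drowns in realization
  noise at any desk-scale gene count; a polygenic baseline with the
  specificity gradient on top is also the biologically sensible reading
  of "risk is enriched in, not exclusive to, a cell type". Second,
  twelve cell types: Dirichlet rows are compositional, so any other
  column is negatively correlated with the planted one by construction
  (−1/(k−1)); at k = 12 that leak is ≈ −0.09 and the null cell types'
  trend p-values stay uniform. Third, the decile scores run with
  `p_max = 1` (no summary-p pre-filter): at synthetic reference-cohort
  scale the 0.05 filter passes more SNPs in high-specificity deciles,
  making the SNP-count covariate — which the trend regression must adjust
  for — nearly collinear with the decile index and destroying power;
  with baseline effects on every variant the filter removes nothing but
  information.
- **eQTL/GWAS pairs** (`sim_eqtl()`): summary statistics drawn from their
  exact asymptotic distribution (marginal effects through an AR(1) LD
  matrix; estimation noise multivariate normal with covariance `se²R`
  within each study). The trait side is a liability-scale quantitative
  trait: a logistic case/control GWAS would attenuate `b_smr` below the
  planted `b_xy` and turn an effect-recovery check into a calibration of
  the attenuation factor, which is not the property under test.

Consequently, passing tests demonstrate internal statistical correctness
(calibration, exactness of closed forms, recovery of planted structure)
— they do not demonstrate robustness to the things real cohorts add:
population stratification, relatedness, genotyping batch effects,
realistic LD, expression normalization artifacts, or winner's-curse in
published summary statistics.

## 7. Problem sizes and runtime

The test suite's simulation scales were chosen so the whole suite runs in
well under half an hour on one CPU: the null-calibration scan uses 50
sets × 2000 samples × 100 permutations; SKAT-O's size check uses 2000
null replicates at n = 500 × 15 variants; the cell-type power check uses
20 replicates of the study above; SMR/HEIDI checks use 200 genes per
scenario. `run_pathway_analysis()` defaults to a 10-set demonstration
configuration (about half a minute end-to-end) with 500 permutations —
enough for the empirical-p floor (1/501) to clear its own Bonferroni line
(0.05/10).

## 8. Known limitations

- Clumping r² comes from the analysis cohort, not an external LD
  reference; with very small cohorts the pruning is noisy.
- The permutation floor ties significance to `n_perm`; scans of thousands
  of sets need ≥ `20 × n_sets` permutations for the floor to clear the
  Bonferroni line, which is the real cost driver.
- SKAT-O p-values below ~1e-9 rest on the Liu approximation rather than
  exact inversion; for genome-wide-significant burden signals the
  reported magnitude, not the ranking, should be treated cautiously.
- HEIDI inherits the single-instrument SMR assumptions; weak instruments
  (small `z_eqtl`) inflate `b_smr` variance and the delta-method
  covariance is first-order only.
- The Louvain backend is greedy and seed-dependent on near-degenerate
  graphs; the seeded interface makes runs reproducible, not optimal.
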