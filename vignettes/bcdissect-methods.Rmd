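---
title: "Methods: virtual microdissection and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual microdissection and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Bulk tumor expression is a mixture of tumor cells, stroma, infiltrating
leukocytes and residual normal tissue. When two tumor cohorts are compared —
here, a younger, pre-menopausal-enriched cohort ("A") against an older
benchmark cohort ("B") — a gene that looks differentially expressed may be so
because tumor cells regulate it differently, because the cohorts differ in
tissue composition, or because of cohort-level batch artifacts. This package
implements a pipeline that separates these explanations: it calls intrinsic
subtypes, quantifies mutational processes, decomposes bulk expression into
tissue-compartment factors by NMF ("virtual microdissection"), and attributes
each differential-expression signal to a compartment class before any biology
is claimed.

All stages are exercised end to end on a seeded synthetic compendium with
known ground truth, so every recovery claim made by the test suite is a
measurement, not an assumption.

# Subtype calling

Receptor status per marker (ESR1, PGR, ERBB2) is modelled as a two-component
univariate Gaussian mixture over `log2(TPM+1)`, fit by EM
(`fit_marker_mixture()`). The cohort's immunohistochemistry (IHC) positive
rate is the prior: the mixing weight starts there and the component means at
the means below/above the corresponding quantile split. The component with
the larger mean is "positive"; a sample is positive when its posterior
exceeds 0.5 (exact ties are negative, for determinism). EM runs to a
log-likelihood tolerance of 1e-6 (at most 1000 iterations) and the
log-likelihood is asserted non-decreasing at every iteration; component
standard deviations are floored at 1e-3 so a tight cluster cannot collapse
the likelihood.

The naive molecular classifier (`call_nmc()`) combines the three marker
calls: hormone-receptor positivity is ESR1-positive OR PGR-positive (the
clinical HR+ convention; the combiner is our design choice), and HER2
positivity is the expression call OR copy number >= 6 (the amplification
threshold used throughout). Copy number acts as a hard override rather than a
mixture feature — a declared choice where the method description names both
inputs without a rule.

Consensus (`consensus_subtype()`) votes in clinical-subtype space. PAM50
labels vote through their compatibility sets (LumA -> ER+; LumB -> ER+,
ER+/HER2+; Her2 -> ER+/HER2+, HER2+; Basal -> TN; Normal -> none), so a
many-valued PAM50 vote can support but never decide alone. With IHC present,
a subtype reaching two votes wins, ties resolving to IHC; a three-way
disagreement falls back to IHC; missing IHC falls back to the molecular
classifier.

# Mutational signatures

Somatic SNVs are tabulated into the 96 trinucleotide channels
(`build_profile()`), reverse-complementing purine-reference records to the
pyrimidine convention. Ingestion stores contexts on the reference strand as
read, so the raw tables stay lossless and normalisation happens exactly once.

`refit_exposures()` solves non-negative least squares of the normalised
96-channel frequency vector against all 30 catalog signatures, renormalises
to the simplex, zeroes weights below 0.06 (the pruning default of the
standard refitting tool; configurable) and renormalises again. All 30
signatures always enter the fit, because excluding a similar signature
inflates the survivors. Per-sample fits come first; the cohort prevalence
filter (retain a signature iff present — nonzero after pruning — in at least
20% of samples in at least one cohort) is applied afterwards and remaining
weights renormalised. Homologous-recombination deficiency is called when the
signature-3 weight strictly exceeds 0.2.

The shipped 30 x 96 catalog is synthetic (`synthetic_signature_catalog()`):
deterministically generated, row-stochastic, with distinct dominant channels
per signature so refitting is well conditioned. It is not the published
catalog; real analyses load one with `read_signature_catalog()`.

Verification is dual-route: the NNLS solution is checked against a
brute-force simplex-grid oracle (step 0.01, up to three active signatures)
and against multinomial resampling at 2000 mutations per sample, where
exposures must be recovered within 0.05 mean absolute error.

# Virtual microdissection

`nmf_fit()` factorises the non-negative `log2(TPM+1)` compendium as `V ~ WH`
by multiplicative updates for the generalised Kullback-Leibler objective (the
"brunet" scheme), with 30 independent random restarts and the lowest final
objective kept. The objective is checked non-increasing within each run;
convergence is a 1e-5 relative change checked every 10 iterations, capped at
500 iterations. Rank `k` is a configuration parameter: for the synthetic
compendium it equals the number of planted factors (10); there is no
automatic rank selection.

Exemplar genes use the entropy specificity score
`1 + sum_j p_j log2 p_j / log2 k` over a gene's factor loadings: 1 for a
one-factor gene, 0 for a uniform one. A gene is an exemplar when its score
exceeds `median + 3 * mad` of all scores (R's `mad`, scaled) and its largest
loading exceeds the median of all `W` entries; it is assigned to its argmax
factor.

For cross-factor comparison, `W` columns are rescaled to sum to one (a
diagonal matrix `S`) with `H` rescaled inversely so `WH` is unchanged, and
per-sample fractions are renormalised to sum to one — over non-cohort factors
for reporting, and over all factors wherever cohort-specific factors must
stay visible (attribution and association).

Compartment attribution (`attribute_compartments()`) codifies, as an ordered
rule engine over group means of the per-sample fractions, reasoning that is
otherwise done by eye on a heatmap: (1) cohort-specific if one cohort's tumor
mean is at least twice every other group mean; (2) adjacent/healthy normal if
that normal group's mean is the global maximum; (3) TIL if tumor means exceed
adjacent-normal which exceeds cell-line, and the factor is the best CYT-score
correlate (r >= 0.5); (4) tumor-intrinsic, labelled by the maximal tumor
subtype group, if cell lines carry at least the median group mean; (5) stroma
if tumors exceed both normal groups and cell lines are minimal (within an
absolute slack of 0.02, since fitted weights are never exactly zero);
(6) otherwise unassigned. Every decision emits its numeric comparisons so a
human can audit or override via configuration. Two numerical choices matter
here: the CYT score (geometric mean of GZMA and PRF1 TPM, offset 0.01) is
correlated on the log scale, because factor weights live in log-expression
space and TPM-scale CYT is exponentially right-skewed; and the ratio (2) and
correlation floor (0.5) are configurable defaults.

# Differential expression and compartment attribution

Genes are filtered by removing the lowest-mean quartile and then the
lowest-variance quartile (ties broken lexicographically, so the filter is
deterministic). Per feature, an ordinary least-squares model
`feature ~ cohort + subtype + purity` is fit on log2-scale values; the cohort
coefficient's t-test p is Benjamini-Hochberg corrected. Genes pass at
FDR < 0.01 and fold-change > 2 or < 0.5; pathway scores pass at FDR < 0.01
and |effect| > 0.2. Moderated (empirical-Bayes) t-statistics are deliberately
not used: at the simulated sample sizes shrinkage is immaterial, and the
contribution here is the attribution machinery, not the variance estimator.

Pathway scores are a documented rank-based stand-in for single-sample
enrichment: within each sample, gene ranks are z-scored and a pathway scores
the mean z of its members (the all-genes set scores exactly 0 everywhere).
Externally computed score matrices can be substituted wherever scores are
consumed.

`associate_features()` correlates each feature with each factor's sample
fractions; the statistic is the maximum correlation over factors — signed by
default, following the method description literally (an absolute-value mode
is provided, since a negative marker correlation would otherwise be missed).
The null pools the max-correlation of every feature over 10 sample-reshuffled
copies of the feature matrix; the empirical p is add-one smoothed,
`(1 + #null >= obs) / (1 + N)`, which avoids zero p at 10 permutations.
Genes associate with their argmax factor at FDR <= 0.05; pathways require
max r >= 0.6. At 1000 permutations the pooled permutation p agrees with the
analytic max-of-correlations p on orthonormalised Gaussian cases to better
than 0.01 mean absolute difference, and under a pure-noise feature matrix at
most 7% of features are flagged at FDR 0.05.

Categorisation takes class maxima over the labelled factors — tumor-intrinsic,
TME (TIL, stroma, both normals), cohort-specific — and assigns exactly one
category per feature with 0.2 margins: tumor-intrinsic if
`max_r_tumor - max_r_TME > 0.2` and `max_r_tumor > 0.2`; symmetrically for
TME; cohort-specific if the cohort maximum clears both by 0.2; else
ambiguous.

# Cohort statistics

`fisher_2x2()` implements the two-sided exact test by minimum-likelihood
summation of hypergeometric probabilities entirely in log space, so tables
with p near 1e-76 (and far beyond) are computed without underflow; it matches
direct enumeration on every table with total at most 40 and the reference
implementation on random tables. `welch_from_summary()` computes the Welch
statistic with Satterthwaite degrees of freedom from printed summaries and
returns log10 p for values below double precision.

Prevalence comparison keeps the method description's construction verbatim —
cohort status as the logistic response, the binary feature as the main
factor, covariates as terms — even though modelling prevalence as the
response would be conventional. Complete separation is flagged, the adjusted
p left undefined, and the direction reported as the continuity-corrected
log-odds.

`variable_usage()` resamples the cohort with replacement 500 times, fits an
elastic-net-penalised logistic regression (mixing 0.5, penalty by 5-fold
internal cross-validation; both configurable — the source method names only
the estimator and the bootstrap count) and reports the percentage of
bootstraps selecting each feature. Two selection-stability choices are
deliberate and configurable: the penalty is taken at the parsimonious
`lambda.1se`, and the cross-validation loss is misclassification error
rather than deviance — with a strong predictor present, the deviance curve
keeps falling toward vanishing penalty and chance-correlated noise features
would be selected in a quarter or more of the bootstraps, whereas the flatter
classification-error curve keeps noise usage in single digits while true
predictors stay at 100%. Internal standardisation makes usage invariant to
feature scaling; constant features get usage 0.

# The synthetic compendium

`simulate_compendium()` plants, in log2(TPM+1) space, `V = W H` with
factor-exclusive marker blocks (25 markers per factor; 550 diffuse background
genes), exponentiates to TPM and applies multiplicative lognormal noise
(sigma 0.3). Noise is multiplicative on TPM rather than count-level Poisson
because every downstream method operates on TPM; raw counts never enter the
pipeline. Default sizes are 120 + 120 tumors, 10 + 10 adjacent normals, 20
healthy-tissue samples and 20 cell lines — a desk-scale stand-in for a
compendium two orders of magnitude larger, chosen so the full pipeline runs
in minutes on one core while keeping every group large enough for stable
group means.

The planted factors are: one tumor-intrinsic factor per clinical subtype
(cell lines load only on these), a TIL factor (highest in tumors, cohort A
mean 0.70 vs cohort B 0.40, intermediate in adjacent normals, zero in cell
lines, carried by GZMA/PRF1 so the CYT score tracks it), a stroma factor
(zero in cell lines, present in all tissues), healthy- and adjacent-tissue
factors, and one batch factor per tumor cohort (tumors only). Subtype mixes
(A: 54/16/10/20; B: 79/6/3/12 percent ER+/ER+HER2+/HER2+/TN) mirror the
enrichment directions of the study cohorts without copying exact values.
ESR1/PGR load on both hormone-receptor-positive factors and ERBB2 on both
HER2-positive factors, which is what makes the mixture classifier's inputs
bimodal. Planted differential expression has two origins: TIL markers differ
between cohorts through the factor means (TME origin), and six markers per
tumor factor get a +2 log2 shift in cohort A tumors (tumor-intrinsic origin).

Mutation catalogs draw per-sample burdens from a Poisson with log-linear age
slope (base 120 at age 50, slope 0.015/yr) and 96-channel counts from a
multinomial over the subtype template mixture (TN weighted 0.65 to the HRD
signature; HER2-positive templates weighted to the APOBEC pair), realising
each mutation as a concrete ref/alt/flank record on a random strand.
Genotypes add age- and cohort-enriched BRCA-like carriers, ERBB2
amplification (CN >= 6) in HER2-positive samples with 2% leakage, and TP53
mutations at subtype-dependent prevalences.

What the generator does not emulate: realistic genome coordinates, indels,
copy-number segmentation, count-level sampling noise, correlated gene
modules within factors, or survival. Passing tests therefore demonstrate
that the algorithms recover the structure they assume, at realistic
signal-to-noise — not that real cohorts satisfy those assumptions.

# Degenerate inputs and tie-breaks

Readers reject (rather than coerce) negative expression, duplicated
identifiers, context/reference mismatches and out-of-range purity; unknown
categorical levels become an explicit `"missing"` with a warning, and every
stage decides its own exclusion rule. Zero-variance features are flagged,
never silently dropped mid-test. Exact posterior ties call negative; exact
mean/variance ties in the gene filter resolve lexicographically; the
assignment between fitted and planted factors is solved exactly (Hungarian
algorithm) rather than greedily.

# Known limitations

The EM mixture assumes bimodality; a cohort with one receptor class almost
absent will fit poorly (the prior is clamped away from 0 and 1). KL-NMF
restarts guard against local minima but cannot make a genuinely
non-identifiable decomposition unique — near-collinear factor weight
patterns (a flat stroma factor versus cohort batch factors) are the failure
mode, which is why attribution emits its numeric traces. The permutation
null at 10 permutations leans on pooling across features, which assumes
approximately exchangeable feature statistics; the categorisation margins
(0.2) are inherited conventions, not estimated quantities.

# Reproducing a full run

```{r}
library(bcdissect)
res <- run_pipeline(list(seed = 1), outdir = "run1")
res$model                 # factor model with compartment labels
head(res$associations_genes)
res$usage                 # elastic-net variable usage (%)
```

Two runs with the same seed are byte-identical; the manifest records the
configuration and its hash.
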