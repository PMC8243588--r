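---
title: "Methods: weighted co-expression networks with clinical trait inference"
author: "coexpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-expression networks with clinical trait inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpnet)
```

# Scope and model

`coexpnet` implements a clinical weighted gene co-expression analysis for
RNA-seq cohorts such as chronic lymphocytic leukemia (CLL) transcriptome
studies: patients are profiled on an RPKM scale, annotated with binary and
quantitative clinical traits (Binet stage, relapse status, sex, age),
censored overall survival and relapse-free survival (RFS), and the goal is
to find **modules** — sets of co-expressed genes — whose summary expression
tracks clinical outcomes, and to turn module genes into relapse/survival
biomarkers.

The analysis chain is:

1. **Preprocessing.** Genes with exact-zero RPKM in at least half the
   samples are removed (the boundary is inclusive: a gene with zeros in
   exactly 50% of samples is dropped). Expression becomes
   $\log_2(\mathrm{RPKM} + 0.05)$. Outlier samples are removed iteratively:
   per iteration, each sample's connectivity
   $k_i = \sum_{j \ne i} \mathrm{cor}(s_i, s_j)$ is z-scored across samples
   and every sample with $|z.k| \ge 3$ is dropped (all offenders together,
   making the result independent of sample order); this repeats until no
   outliers remain. A PCA on the cleaned matrix provides a quality check.

2. **Network construction.** Gene–gene association uses the biweight
   midcorrelation (bicor), a robust correlation that down-weights
   observations beyond nine median absolute deviations from the median via
   Tukey biweights; a vector with zero MAD (e.g. a 0/1 trait) falls back to
   plain mean-centering for that vector only. The **signed** adjacency is
   $a_{ij} = ((1 + c_{ij})/2)^\beta$, so anti-correlated genes are
   unconnected. The topological overlap matrix (TOM) measures shared
   neighbourhoods, and average-linkage clustering on $1 - \mathrm{TOM}$
   followed by a static height cut yields modules. Each module is summarized
   by its **eigengene** (ME): the first principal component of the module's
   gene-standardized expression, unit variance, sign-aligned with mean
   expression. Gene–ME correlations (kME) identify hubs (kME $\ge 0.7$ and
   highest in the gene's own module). Modules whose eigengenes correlate
   above $1 - \texttt{merge\_height}$ are merged iteratively.

3. **Module–trait inference.** ME–trait association uses bicor (binary
   traits 0/1-coded behave as point-biserial correlations) with two-sided
   Student p-values from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. Samples cluster
   on their z-scored ME profiles (Euclidean distance, average linkage);
   clusters with a relapse fraction above 80% are flagged relapse-enriched.
   Per-unit variance is partitioned across covariates by sequential sums of
   squares averaged over covariate orderings.

4. **Differential expression.** One-way ANOVA across the four Binet-stage
   × relapse groups, Tukey–Kramer post-hoc p-values from the studentized
   range distribution, and a log2 fold change for the focal pair
   (stage-A-relapse vs stage-A-no-relapse). Hub biomarkers require
   $p < 0.05$ (strict), kME $\ge 0.7$ and $|\mathrm{LFC}| \ge 0.5$
   (both inclusive).

5. **Enrichment.** One-sided hypergeometric (Fisher) over-representation of
   module gene lists against GMT collections, with Benjamini–Hochberg
   adjustment and an analytic z-score.

6. **Preservation.** Whether reference modules retain density and
   connectivity in a second cohort, via permutation Z-statistics
   (see below).

7. **Prognostics.** Nonparametric ROC/AUC (Mann–Whitney with Hanley–McNeil
   standard errors), prognostic-ratio gene-combination screening at fixed
   RFS horizons, Kaplan–Meier product-limit curves, log-rank tests with
   Pike hazard ratios, and optimal expression cutpoints.

# Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `max_zero_fraction` | 0.5 | proportion | inclusive removal boundary for zero-inflated genes |
| `offset` | 0.05 | RPKM | log2 offset; round-trips with the synthetic generator |
| `z_threshold` | 3 | SDs | outlier-sample boundary on z-scored connectivity |
| `beta` | 5.5 | exponent | soft-thresholding power; `pick_soft_threshold()` is advisory, the configured value is authoritative |
| `min_module_size` | 30 | genes | smallest reportable module |
| `merge_height` | 0.25 | ME dissimilarity | modules with ME correlation ≥ 0.75 merge |
| `cut_fraction` | 0.95 | fraction of max height | static tree cut (see below) |
| `kme_prune_threshold` | 0.3 | correlation | members below this own-module kME return to grey |
| `min_variance_explained` | 0.1 | proportion | coherence floor for detected clusters |
| `max_block_size` | 25,000 | genes | blockwise decomposition cap |
| `n_perm` | 100 | draws | preservation null size |
| RFS horizons | 456/548/1095/1826 | days | 15/18 months (30.44-day months), 3/5 years (365.25-day years) |

# Design choices in the open

**Static cut height (0.95, not 0.99).** The tree cut is a static fraction of
the dendrogram's maximum merge height. At 0.99 of the maximum, background
(non-module) genes attach to genuine modules before the cut on realistic
synthetic cohorts and recovery collapses (adjusted Rand index ≈ 0.4); at
0.95 recovery is essentially exact across seeds while pure-noise inputs
still produce zero modules, because a noise dendrogram's merges concentrate
just below the maximum height. 0.95 is therefore the default.

**Module cleaning.** A static cut (unlike the hybrid dynamic cut used by
the reference implementation of this methodology) can leave residual
background genes as a large but incoherent cluster, and can sweep individual
background genes into real modules. Two standard cleaning steps compensate:
clusters whose eigengene explains under 10% of member variance are dissolved
(a genuine co-expression module has a dominant first principal component,
while a noise cluster's PC1 fraction sits near the Marchenko–Pastur level),
and members whose own-module kME falls below 0.3 are returned to grey
(the reference method's `minKMEtoStay` convention). Unassigned genes with
kME ≥ 0.7 to a unique best module are adopted by it.

**Blockwise decomposition.** Above `max_block_size` genes, the gene set is
pre-clustered by k-means on the leading principal components of standardized
gene profiles into blocks under the cap, detection runs per block, and
modules are merged across blocks by eigengene correlation. Because k-means
can split a module across blocks, per-block detection uses half the module
size floor so fragments survive to the merge; the full floor is enforced
afterwards.

**Tukey rather than genome-wide FDR.** Pairwise p-values carry Tukey's
family-wise adjustment over the group pairs only; no cross-gene correction
is applied by default (Benjamini–Hochberg is available through
`bh_adjust()`), matching how such per-gene ANOVA tables are conventionally
reported in this literature.

**"Wilcoxon t-test" = rank-sum.** Group comparisons are between independent
patients, so the two-group test is the Mann–Whitney rank-sum (exact by
enumeration when both groups have ≤ 10 observations, tie-corrected normal
approximation with continuity correction otherwise), not the signed-rank
test, which would require pairing.

**Prognostic ratio as a difference of set means.** Scores contrast the mean
z-scored expression of relapse-up genes against relapse-down genes. A
literal ratio of z-score means is ill-posed whenever the denominator crosses
zero, so the default score is
$\bar z_{\mathrm{num}} - \bar z_{\mathrm{den}}$ — monotone in the same
contrast and stable everywhere; `mode = "literal_ratio"` retains the ratio
(with an $\varepsilon$ guard and stability warning) for fidelity.

**Preservation statistics.** A declared subset of the reference battery:
density is the mean within-module correlation in the test cohort;
connectivity is the correlation of intramodular connectivities (from the
signed adjacency restricted to the module) and of kME vectors between the
cohorts. Nulls come from `n_perm` random same-size gene sets drawn without
replacement from the shared universe excluding the module's genes (falling
back to the full shared universe, with a warning, if a module exceeds the
non-module universe); $Z = (\mathrm{obs} - \mu_0)/\sigma_0$,
$Z_\mathrm{connectivity}$ averages the kIM and kME z-scores, and
$Z_\mathrm{summary}$ averages density and connectivity.
$Z_\mathrm{summary} < 2$ is reported as not preserved, 2–10
weak-to-moderate, > 10 strong — reporting labels only. `median_rank` is the
median of the per-statistic preservation ranks.

**Variance partitioning.** Fixed-effect sequential sums of squares averaged
over all covariate orderings (up to five covariates; the declared input
order beyond that), not the original mixed-model fractions: deterministic,
exactly decomposing total variance, and sufficient for coarse statements
like "sex and age explain under 10%".

**Optimal cutpoints are selection-biased.** The scan maximizes the log-rank
chi-square over admissible splits (each group ≥ 10% of samples, ties to the
lower cutpoint) and reports the winning split's test as-is, flagged, without
multiplicity correction — matching common usage of cutpoint tools while
making the bias explicit.

# The synthetic cohort: what it emulates, what it does not

`generate_cohort()` plants disjoint gene modules: module gene $g$ in module
$m$ is $\mu_g + \lambda_g z_m + \varepsilon$ on the log2 scale, with
eigengene signal $z_m \sim N(0,1)$ per sample, loadings
$\lambda_g \sim U(0.5, 0.9)$ and noise SD 0.5. Values are emitted as
$2^x - 0.05$ floored at zero, so the preprocessing transform round-trips
exactly. Background genes are independent noise with a configurable
fraction (default 0.3) of exact-zero cells. Relapse follows a logistic link
on the first module's eigengene (default 1.5 log-odds per SD, baseline rate
0.45), overall survival is exponential with a proportional log-hazard on the
second module's eigengene (baseline median 2,000 days) and independent
censoring (default 25%, censor times uniform before the event), and relapse
intervals shorten with the relapse eigengene. Sex (Bernoulli 0.57), age
(Normal(62, 10) truncated at 25) and an A-majority Binet stage (179:15)
mirror the clinical table structure such cohorts report. Sex and age enter
every gene at a fixed variance share (default 5%); the planted eigengene
signals are orthogonalized against sex and age in-sample so that
`confounder_frac` is a true cap rather than an in-expectation statement.

Defaults (5,000 genes × 150 samples, six modules of 50–300 genes) were
chosen once for testability; the generator does **not** emulate read-level
sequencing noise, gene length effects, real gene identities, chromosomal
structure, heavy-tailed per-gene dispersions, or trait missingness patterns
of real cohorts. A green planted-recovery test therefore establishes that
the pipeline recovers block-correlated structure with known effect sizes —
not that it would recover modules in any particular real dataset.

# Numerical conventions

- Correlations are clamped to $[-1, 1]$ after floating-point accumulation.
- `bicor` falls back to mean-centering per vector when that vector's MAD is
  zero; two constant vectors raise an undefined-correlation error.
- Eigengene sign: non-negative correlation with the module's average
  standardized expression; ties in module relabeling break by original
  label; modules are numbered by decreasing size (M1 largest).
- Exact zeros in p-value formulas are reported as computed (e.g. AUC = 1
  yields $p = 0$ from a degenerate SE); nothing is truncated to zero.
- All randomness in the pipeline derives from the single config seed via
  stage-name-hashed sub-seeds kept below $2^{31}$.
- Degenerate inputs (constant matrices, single-class labels, empty groups,
  no admissible cutpoint split) raise typed errors or explicit status
  fields rather than returning NaN.

# Known limitations

- The static height cut has a detection limit: in large cohorts the
  smallest modules' topological overlap is diluted by the background and a
  small module (e.g. 50 genes among 5,000) can fall back to grey while all
  larger modules are recovered exactly. The hybrid dynamic tree cut is the
  documented extension point.
- Preservation permutation draws assume the shared gene universe is large
  relative to each module.
- The AUC z-test uses the Hanley–McNeil normal approximation; exact
  permutation inference is out of scope.
- No covariate-adjusted survival modeling, time-dependent ROC, KM
  confidence bands, mixed-model variance fractions, ontology-graph pruning,
  or consensus/signed-Nowick TOM variants.

Every empirical claim above is recomputed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) from seeded synthetic
cohorts; the vignette states no result the tests do not compute.
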