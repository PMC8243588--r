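# coexpnet

Weighted gene co-expression network analysis with clinical trait inference
and survival prognostics, for RNA-seq patient cohorts.

## The problem this package addresses

In cohort transcriptome studies of indolent blood cancers such as chronic
lymphocytic leukemia (CLL), the clinically urgent questions — who will
relapse after first-line therapy, and who has poor survival odds — are not
answered well by single-gene tests. A systems approach groups genes into
**co-expression modules**, summarizes each module by one per-sample value,
relates those summaries to clinical traits, and then drills into module
member genes for biomarkers. `coexpnet` implements that full chain as a
tested, reproducible pipeline:

- **Preprocessing**: remove genes with zero RPKM in ≥ 50% of samples,
  transform to log2(RPKM + 0.05), iteratively remove samples whose
  z-scored connectivity satisfies |z.k| ≥ 3, PCA quality check.
- **Network**: biweight midcorrelation (bicor), signed adjacency
  `a_ij = ((1 + c_ij)/2)^β` (default β = 5.5, advisory scale-free fit scan
  included), topological overlap (TOM), average-linkage clustering with a
  static cut plus minimum module size 30, module eigengenes (ME = first PC
  of the standardized module), kME hub statistics, ME-based module merging,
  and blockwise decomposition above 25,000 genes.
- **Trait inference**: bicor ME–trait correlations with Student p-values,
  ME relatedness dendrogram, sample clustering on ME profiles with a
  \>80% relapse-enrichment flag, covariate variance partitioning.
- **Differential expression**: four-group (Binet stage × relapse) one-way
  ANOVA with Tukey–Kramer post-hoc, Mann–Whitney two-group tests, log2 fold
  changes, and the hub-biomarker gate (p < 0.05, kME ≥ 0.7, |LFC| ≥ 0.5).
- **Enrichment**: one-sided Fisher (hypergeometric tail) tests of module
  gene lists against GMT collections, Benjamini–Hochberg adjusted.
- **Preservation**: permutation Z-statistics (Z_density, Z_connectivity,
  Z_summary, median rank) testing whether reference modules recur in an
  independent cohort.
- **Prognostics**: nonparametric ROC/AUC (Mann–Whitney, Hanley–McNeil SE,
  z-test against 0.5), prognostic-ratio gene-combination screening at fixed
  relapse-free-survival horizons (456/548/1095/1826 days), Kaplan–Meier
  product-limit curves, log-rank tests with Pike hazard ratios, and optimal
  expression cutpoints.
- **Synthetic cohorts**: `generate_cohort()` plants modules with known
  eigengene signals, trait effects, censored survival and RPKM-like
  zero inflation, so every stage is verifiable against ground truth.

The statistic at the core: for genes i, j with expression correlation
c_ij, the signed network weighs edges by a_ij = ((1 + c_ij)/2)^β, the
topological overlap

    TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

measures shared neighbourhoods, modules are branches of the 1 − TOM
dendrogram, and each module's eigengene E_m (unit-variance first principal
component) is tested against traits by robust correlation with
t = ρ√((n−2)/(1−ρ²)).

## Worked example

```r
library(coexpnet)

cfg <- cohort_config(n_genes = 1200, n_samples = 120,
                     module_sizes = c(120, 100, 80, 60, 50, 40),
                     relapse_effect = 1.5, seed = 42)
cohort <- generate_cohort(cfg)

pre <- preprocess(cohort$expression)
net <- build_network(pre$expr, network_config(beta = 5.5))
print(net)
#> network_model: 1200 genes, 6 modules (beta = 5.5, signed)
#> module sizes: M1=120 M2=100 M3=80 M4=60 M5=50 M6=40
#> unassigned: 750

truth <- truth_assignment(cohort$truth, rownames(cohort$expression))
adjusted_rand_index(truth[names(net$assignment)], net$assignment)
#> [1] 1

mt <- module_trait_correlation(net$eigengenes,
                               cohort$traits[, c("relapse", "sex", "age")])
round(cbind(rho = mt$rho[, "relapse"], p = mt$p[, "relapse"]), 4)
#>        rho      p
#> M1  0.4602 0.0000
#> M2  0.0326 0.7247
#> M3 -0.0927 0.3160
#> M4 -0.0332 0.7196
#> M5 -0.0277 0.7645
#> M6  0.1705 0.0637
```

One sample was removed as a connectivity outlier, all six planted modules
were recovered exactly (adjusted Rand index 1.0), and only the module that
was generated with a relapse effect (M1, planted at 1.5 log-odds per
eigengene SD) correlates with the relapse flag (ρ = 0.46, p < 1e-4); the
other modules and both confounders stay at noise level. Drilling into M1's
hub genes:

```r
rel <- setNames(cohort$traits$relapse, rownames(cohort$traits))[colnames(pre$expr)]
hub <- names(which(is_hub_gene(net$kme, net$assignment)))[1]
roc_auc(pre$expr[hub, names(rel)], rel, marker_name = hub)
#> hub gene G00001: relapse AUC 0.727 (z = 4.92, p = 8.8e-07)

tr <- cohort$traits[colnames(pre$expr), ]
os <- data.frame(time = tr$survival_days, event = tr$vital_status,
                 row.names = rownames(tr))
optimal_cutpoint(setNames(pre$expr[hub, rownames(os)], rownames(os)), os)
#> optimal cutpoint 3.73: log-rank chi2 7.09, p = 0.00776, HR(low vs high) 1.93
```

A hub of the relapse-linked module predicts the relapse flag with AUC 0.73,
and splitting patients at the optimal expression cutpoint separates overall
survival (log-rank p = 0.008) — the synthetic analogue of the biomarker
tables such cohort studies report. The `run_pipeline()` orchestrator runs
all stages from TSV inputs and writes per-stage tables plus a checksummed
reproducibility manifest; `inst/cli/coexpnet.R` exposes the same stages as
subcommands (`simulate`, `preprocess`, `network`, `traits`, `enrich`,
`preserve`, `prognose`, `pipeline`).

## Package layout

- `R/synthetic_data.R` — planted-module cohort generator (+ validation
  cohorts with scrambled modules)
- `R/preprocessing.R`, `R/bicor.R`, `R/network.R` — cleaning and network
  construction
- `R/trait_stats.R`, `R/diffexp.R`, `R/enrichment.R` — inference stages
- `R/preservation.R`, `R/prognostics.R` — cross-cohort and survival stages
- `R/io.R`, `R/pipeline.R` — I/O contracts and orchestration
- `vignettes/coexpnet-methods.Rmd` — the model, parameter rationale, design
  decisions and known limitations
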