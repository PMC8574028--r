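# overlapnet

Identify treatment-responsive genes from paired control/treatment RNA-seq
and phenotype data, using overlapping co-expression modules.

Many plant-stress studies measure genotypes of a crop under control and
treatment (e.g. salt stress) conditions, recording both RNA-seq read
counts and phenotype traits. `overlapnet` implements a network workflow
that works on the *changes* between conditions rather than the expression
levels: per-genotype log2 fold changes (LFC) of every gene, and log2
ratios of every trait. It then

1. normalizes counts with median-of-ratios size factors, averages
   replicates, filters uninformative genes, and computes the LFC matrix;
2. builds a co-expression network from `|Pearson|` similarity of LFC
   profiles, soft-thresholded (`a_ij = s_ij^beta`) with `beta` chosen as
   the smallest power whose connectivity distribution is approximately
   scale-free (log–log regression R² ≥ 0.8);
3. hard-thresholds the network and detects **overlapping** gene modules
   with Hierarchical Link Clustering: links are clustered by the Jaccard
   similarity of their endpoint neighborhoods, and the single-linkage
   dendrogram is cut at maximum partition density
   `D = (2/|E|) Σ_c |E_c| (|E_c|−|V_c|+1) / ((|V_c|−1)(|V_c|−2))`,
   so a gene can belong to several modules;
4. summarizes each module by its eigengene (first principal component of
   the module's standardized LFC submatrix) and selects trait-associated
   modules per trait with cross-validated LASSO
   (`min Σ(y − Xα)² + λ‖α‖₁`);
5. flags selected genes with `max |LFC| ≥ 2` as differentially expressed
   and validates the selection with one-sided Fisher exact enrichment
   tests.

A synthetic-data generator (`simulate_study()`) emulates the whole study
design — planted overlapping modules, negative-binomial counts with known
size factors, traits driven by known causal modules — so every stage is
testable without external data.

## Worked example

```r
library(overlapnet)

sim <- simulate_study(synthetic_config(seed = 2))
fit <- overlapnet(sim$counts, sim$phenotypes, seed = 2)
print(fit)
#> overlapnet fit
#>   gene funnel: 1000 -> 465 (expression filter) -> 461 (LFC filter) -> 354 (network) -> 290 (modules) -> 52 (selected)
#>   beta = 5 (scale-free R^2 = 0.869), cutoff = 0.2, 58 modules (D = 0.911)
#>   52 selected genes, DEG fraction 0.73, Fisher p = 6.98e-18
```

The funnel counts genes surviving each stage: 1,000 simulated genes, 461
after the expression and LFC-variability filters, 354 connected in the
thresholded network, 290 in modules of at least 3 genes, and 52 in the
modules the LASSO associates with at least one trait. `beta = 5` is the
chosen soft-threshold power (scale-free fit R² = 0.87), 58 overlapping
modules were detected at partition density 0.91, and the selected genes
are strongly enriched for differential expression (73% with |LFC| ≥ 2
versus the background rate, one-sided Fisher p ≈ 7·10⁻¹⁸) — the expected
behavior when trait-associated modules carry real treatment response.

Inspect results with `summary(fit)` (per-trait modules and penalties),
`coef(fit)` (standardized LASSO coefficients), `plot(fit)` (scale-free
scan, cutoff scan, CV curves), and persist everything with
`write_outputs(fit, "out/")` (normalized matrix, LFC, edge list, module
TSV/GMT, eigengenes, selection JSON, gene report, run summary). With real
data, start from `read_counts("counts.tsv", "samples.csv")` and
`read_phenotypes("phenotypes.csv")`; a thin command-line wrapper lives in
`inst/cli/overlapnet.R` (`simulate` and `run-all` subcommands, YAML
config).

Recovery of planted structure is scored with `score_recovery()`:

```r
rec <- score_recovery(sim$truth, fit$affiliation, fit$selection)
round(rec$mean_module_jaccard, 2)
#> [1] 0.73
```

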