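---
title: "Methods: overlapping co-expression modules associated with treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlapping co-expression modules associated with treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapnet)
```

## The problem and the model

`overlapnet` identifies genes whose *response* to a treatment — not their
expression level — co-varies across genotypes and is associated with
phenotypic responses. The input is a paired design: raw RNA-seq read counts
for `m` genotypes under control and treatment conditions with `r`
biological replicates each, plus one control and one treatment measurement
of each of `p` phenotype traits per genotype.

The analysis proceeds in five stages.

**(a) Preprocessing.** Counts are normalized with median-of-ratios size
factors: for sample $j$, $s_j = \mathrm{median}_i \; c_{ij} / (\prod_k
c_{ik})^{1/2mr}$ over the genes $i$ with strictly positive counts in every
sample. Replicates are averaged arithmetically. Genes are filtered on the
averaged matrix: low variance (75th/25th percentile ratio below 1.5) and
low expression (more than 80% of columns below 10 normalized counts). The
working signal is the per-genotype log fold change $\ell_{ij} = \log_2
\frac{t_{ij} + 1}{c_{ij} + 1}$, further filtered on its interquartile
range (genes with IQR at or below 0.25 removed in the default
`remove_low_variance` mode). Phenotypes are reduced the same way:
$\log_2(\text{treatment}/\text{control})$ per genotype and trait.

**(b) Network construction.** Similarity is the absolute Pearson
correlation of LFC profiles, $s_{ij} = |\mathrm{cor}(\ell_{i\cdot},
\ell_{j\cdot})|$, so strong negative co-response counts as strongly as
positive. The weighted adjacency is $a_{ij} = s_{ij}^\beta$, with $\beta$
the smallest integer power greater than 1 whose soft connectivity
distribution ($k_i = \sum_{j \ne i} a_{ij}$) is approximately scale-free:
the $R^2$ of the regression of $\log_{10}$ bin frequency on $\log_{10}$
mean bin connectivity reaches 0.8. If no power qualifies, the best-fitting
power is used and flagged.

**(c) Overlapping module detection.** The weighted network is hard
thresholded (entries strictly above the cutoff become edges; isolated genes
are dropped) and Hierarchical Link Clustering groups the *links*: the
similarity of two links sharing a node $k$ is the Jaccard index of the
inclusive neighborhoods of their non-shared endpoints,
$S(e_{ik}, e_{jk}) = |\eta(i) \cap \eta(j)| / |\eta(i) \cup \eta(j)|$ with
$\eta(v) = \{v\} \cup N(v)$. Single-linkage agglomeration over links builds
a dendrogram, cut at the level maximizing the partition density
$$D = \frac{2}{|E|} \sum_c |E_c| \,
\frac{|E_c| - |V_c| + 1}{(|V_c| - 1)(|V_c| - 2)},$$
where community $c$ has $|E_c|$ links over $|V_c|$ induced nodes. $D = 1$
when every community is a clique on at least 3 nodes and $D = 0$ when every
community is a tree. A gene inherits the communities of its incident links,
so genes can belong to several modules — the overlap that motivates the
method. Modules with fewer than 3 genes are dropped.

**(d) Trait association.** Each module is summarized by its eigengene: the
first right singular vector of the module's gene-wise z-scored LFC
submatrix (unit norm; sign aligned with the mean standardized profile, or
with the first gene's profile when the mean is numerically zero). Per
trait, the LASSO
$$\min_\alpha \sum_{i=1}^m \Big(y_i - \sum_{j=1}^c \alpha_j x_{ij}\Big)^2
+ \lambda \sum_{j=1}^c |\alpha_j|$$
is fit by cyclic coordinate descent with eigengenes as predictors
(standardized internally) and the trait's log ratio as response. The
penalty is chosen by seeded 10-fold cross-validation on a 100-point
log-spaced grid from $\lambda_{\max} = 2 \max_j |x_j^\top y|$ (the smallest
all-zero penalty) down to $10^{-4}\lambda_{\max}$. Modules with nonzero
coefficients form the selected set per trait; the target genes are the
union of their members.

**(e) Enrichment.** Selected genes with $\max_j |\ell_{ij}| \ge 2$
(quadrupled or quartered expression in at least one genotype, inclusive
threshold) are flagged as differentially expressed, and a one-sided Fisher
exact test checks whether DEGs are over-represented among selected genes
relative to the remaining filtered genes. A second, optional test does the
same for a user-supplied list of externally known treatment genes over the
same universe.

## Numerical and design choices

* **Quantiles** are the 75th/25th percentiles with linear interpolation
  (R's default type 7); the filter thresholds (1.5 ratio, 10 counts, 80%,
  0.25 IQR) are conventional defaults, all configurable.
* **LFC filter direction.** Descriptions of this filter are ambiguous
  between removing low-variance and high-variance response profiles. Both
  are implemented behind `lfc_filter_mode`; the default removes
  low-variance profiles, since the network is built from co-*variation* of
  responses and constant profiles carry no signal (and break the Pearson
  similarity). A zero-variance row is an error in `similarity_matrix()`.
* **Scale-free fit binning.** Connectivities are binned into 10 equal-width
  bins on the linear scale, the convention of the weighted co-expression
  literature's fit index. Binning log-transformed connectivities without a
  density correction biases the log–log slope by +1 and can invert the
  apparent trend, so it is not used.
* **Connectivity** of the weighted network is the soft connectivity
  $k_i = \sum_{j\ne i} a_{ij}$.
* **Cutoff scale.** The hard threshold (shipped default 0.2) applies to the
  soft-thresholded adjacency $a_{ij}$; `cutoff_scale = "similarity"`
  applies it to $s_{ij}$ instead (equivalently $\tau^\beta$ on the
  adjacency). When no override is given, the automatic rule returns the
  smallest grid cutoff minimizing network density among cutoffs that keep
  at least 5% of genes connected. The comparison is strict (`>`), so
  entries exactly at the cutoff are not edges.
* **Link communities.** Similarity is defined only for link pairs sharing
  exactly one node; disconnected link pairs never merge, so the dendrogram
  is a forest and communities never span graph components. Equal-similarity
  merges are processed simultaneously, making the partition independent of
  link enumeration order; at equal partition density the finer (higher
  similarity) cut wins. Communities whose induced subgraph has at most two
  nodes contribute zero to $D$ (the formula is undefined there). Note that
  evaluating the formula for one community of two disconnected edges gives
  $-1/3$; a sharper bound of $-2/3$ is sometimes quoted for this extremal
  case, but direct evaluation with $|E_c| = 2, |V_c| = 4$ yields
  $2 \cdot (2 - 4 + 1)/(3 \cdot 2) = -1/3$, and the implementation follows
  the formula.
* **Penalty rule.** The shipped default is the one-standard-error rule: the
  largest penalty within one SE of the minimum mean CV error. With tens to
  thousands of candidate modules and only tens of genotypes, the CV curve
  is flat near its minimum and the plain minimizer admits many spurious
  modules with near-zero coefficients, defeating the purpose of the
  selection stage (real studies of this design select a handful of modules
  out of thousands). `lasso.lambda_rule = "min"` restores the plain
  minimizer. On the Lagrangian objective above, a coordinate is zero iff
  $|x_j^\top r| \le \lambda/2$; the solver iterates to a KKT residual
  below $10^{-6}$, checked by `lasso_kkt_residual()`.
* **Seeds.** One pipeline seed fans out deterministically: trait $z$ uses
  `seed + z` for its CV fold assignment. Identical inputs, configuration
  and seed give byte-identical outputs.

## What the synthetic generator emulates

`simulate_study()` generates the full study design: planted overlapping
modules acting on the LFC scale (module activities over genotypes are
standard normal; member genes load with magnitude 0.8–1.2 and random sign;
each module gene joins a second module with probability 0.3), log-normal
baseline expression with per-genotype genetic variation (log2 SD 0.35 —
this spreads the expression filter's quantiles but cancels exactly in the
log ratio, which is the point of working on changes rather than levels),
negative-binomial counts (dispersion 0.005, typical of replicated inbred
lines under controlled conditions) under log-uniform per-sample scale
factors normalized to geometric mean one, and traits driven by two causal
modules each (effect magnitudes 1–1.5, trait noise SD 0.3, so the trait
signal-to-noise ratio stays above 3).

Background (non-module) genes are organized into many small co-response
groups (2–10 genes) whose coherence varies log-normally (median loading
0.3, sdlog 0.45). This mirrors the fine-grained modular structure of real
co-expression networks — thousands of small, partially coherent response
groups — and is what gives the weighted network the decaying connectivity
continuum that makes soft-threshold selection meaningful; with fully
independent background genes the scale-free fit is degenerate
(all-bin-noise) and the power selection is arbitrary. Gene-level LFC noise
is 0.1 SD, so the module signal-to-noise ratio (loading over noise) is
at least 3 even after count noise.

Defaults describe a reduced-scale study: 1,000 genes, 40 genotypes, 2
replicates, 3 traits, 8 planted modules of 8–15 genes. At this scale the
smallest qualifying soft power is typically 3–6 (at the case scale of real
studies, with an order of magnitude more genotypes and genes, it is
smaller); module recovery is assessed by best-match Jaccard and causal
attribution by the gene union of selected versus planted causal modules.

What the generator does *not* emulate: gene-length and GC effects,
genotype population structure, shared regulators between planted modules
(module activities are independent), dispersion heterogeneity across
genes, and trait measurement error structure beyond additive noise on the
log ratio. Passing recovery tests on these data therefore demonstrates the
pipeline's mechanics — normalization, filtering, network construction,
overlapping module detection, selection — not robustness to every
real-data pathology.

## Degenerate inputs and edge cases

* A gene with any zero count is excluded from the size-factor reference;
  if no gene is positive in all samples, normalization stops with advice.
* `filter_expression`/`filter_lfc` raise an error rather than return an
  empty matrix when nothing survives.
* A similarity matrix entry is clamped to $[0,1]$ against floating-point
  overshoot; the diagonal is fixed at 1.
* An empty thresholded network, or one with no module of minimum size, is
  an error at the network stage and an empty-selection result at the
  association stage, respectively.
* Degenerate Fisher margins (no selected genes, or no gene with the
  property) give $p = 1$ by convention.

## Known limitations

* Partition-density maximization favors small dense link communities;
  large planted modules are sometimes recovered as two or three fragments,
  which lowers gene-level recall of the selected sets even when the right
  modules are found. Because the LASSO keeps one of several nearly
  collinear fragment eigengenes, per-trait causal attribution measured at
  the gene level is systematically weaker than module detection itself;
  the recovery tests quantify both.
* Genes belonging to two modules have correlation at most about 0.7 with
  either module's profile; after soft thresholding at powers above 4 their
  bridging edges fall below the 0.2 cutoff, so detected overlap fades at
  high powers. This is a property of the method's operating point, not of
  the implementation.
* The eigengene sign convention (alignment with the mean standardized
  profile) is arbitrary for perfectly anti-symmetric modules; coefficients
  of such modules are sign-ambiguous, their selection is not.
* Problem sizes in the shipped tests (1,000 genes, 40 genotypes, 25
  replicate seeds) were chosen so the full validation suite represents the
  study design faithfully at desk scale.
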