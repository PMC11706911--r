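---
title: "Methods: co-occurrence networks of microbial C-cycling genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks of microbial C-cycling genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazynet)
```

## The analysis problem

Shotgun metagenomes of soil communities can be summarised as a table of
carbohydrate-active enzyme (CAZy) gene-family abundances per sample — the
community's carbon-cycling gene repertoire. Comparing how these gene
families co-occur across land uses asks a network question: which families
rise and fall together (or in opposition), how densely connected is that
co-occurrence structure, how is it organised into modules, and how fragile
is it to the loss of genes?

Sequencing counts are *compositional*: only relative abundances are
observable, and the closure to fractions induces spurious negative
correlation between otherwise independent components. `cazynet` therefore
estimates correlations with SparCC, which is built for compositions, and
then analyses the resulting thresholded, signed network.

The pipeline is per group: the abundance table is split by land use, each
group is filtered and analysed independently, and group-level summaries
are compared at the end.

## SparCC basis correlations

For genes $i, j$ with per-sample fractions $x_i, x_j$, the log-ratio
variance

$$t_{ij} = \mathrm{var}\, \log\frac{x_i}{x_j}$$

is invariant to the compositional closure. Writing $\omega_i$ for the
latent ("basis") variance of gene $i$ and $\rho_{ij}$ for the basis
correlation,

$$t_{ij} = \omega_i + \omega_j - 2 \rho_{ij} \sqrt{\omega_i \omega_j}.$$

Under the sparsity approximation (most $\rho_{ij} \approx 0$), summing
over $j$ gives a linear system for $\omega$, from which
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. Pairs whose estimated $|\rho|$ exceeds an exclusion
threshold (0.8, the algorithm's conventional default) are removed from the
variance system one pair per round — strongest first, at most 10 rounds —
and the system re-solved, so a few strong correlations do not inflate the
basis variances. Numerical choices:

* fractions use a single pseudocount of 1 (deterministic; a Dirichlet
  resampling average would add Monte-Carlo noise without changing the
  estimate materially at typical library sizes);
* $t$ entries are floored at 0 (they are variances; floating-point
  cancellation can produce tiny negatives for proportional genes);
* basis variances solved as non-positive are floored at $10^{-10}$ with a
  warning — the affected gene's correlations are unreliable but the
  remainder of the matrix is preserved;
* the estimator requires at least 4 genes and 4 samples; below that the
  basis system is underdetermined.

Significance comes from permutations: each permutation shuffles every
gene's values across samples independently, destroying all between-gene
association while preserving marginals, and the full SparCC estimate is
recomputed. Two-sided add-one p-values,
$p_{ij} = (1 + \#\{|\rho^{perm}_{ij}| \ge |\rho^{obs}_{ij}|\})/(1 + B)$,
avoid $p = 0$ at finite $B$. Benjamini–Hochberg adjustment runs over the
$G(G-1)/2$ unique pairs, separately within each land-use network (the
networks are built independently).

One practical consequence worth knowing: the smallest attainable q-value
is $m / (B (\text{number of top-ranked pairs}))$ in order of magnitude, so
with thousands of gene pairs and $B = 1000$ permutations, only datasets
with many genuinely strong correlations can clear an FDR of 0.05. This is
a property of permutation + FDR designs generally, not of this
implementation.

## Network construction and topology

An edge connects genes with $|\rho| > 0.6$ (strict) and $q < 0.05$
(strict); boundary values are excluded on both criteria. Edges keep the
signed correlation as weight; genes with no surviving edge are dropped, so
"network size" counts connected genes only. Topology metrics follow the
standard co-occurrence conventions:

* paths, diameter, clustering, modularity and roles use the unweighted,
  sign-stripped graph; the sign is retained for the percentage of negative
  links and for cohesion;
* average path length averages over connected ordered pairs only, and the
  diameter is the longest shortest path within components (thresholded
  networks are routinely disconnected);
* the clustering coefficient is the mean local value, with degree-1 nodes
  contributing 0;
* degree centralisation is $\sum_i (k_{max} - k_i)/((N-1)(N-2))$, reported
  as missing below 3 nodes;
* the degree distribution's power-law fit is an ordinary least-squares
  regression of $\log_{10}$ frequency on $\log_{10}$ degree over observed
  degrees, reporting slope, $R^2$ and the slope's p-value; with fewer than
  3 distinct degrees the fit is flagged unsupported rather than forced.

Modules come from Clauset–Newman–Moore fast-greedy agglomeration
(`igraph`). The package evaluates every cut of the agglomeration
dendrogram and keeps the one with maximal $Q$: the membership igraph
itself reports can sit one merge short of the best state on small graphs
(an edgeless 4-star otherwise lands at $Q < 0$ instead of the correct
single-module $Q = 0$). Module labels are renamed `M1`, `M2`, ... by each
module's smallest gene ID so runs are reproducible.

Node roles use the within-module degree z-score $z_i$ and participation
coefficient $P_i = 1 - \sum_s (k_{is}/k_i)^2$ with the conventional
thresholds $z = 2.5$ and $P = 0.62$: peripherals (low/low), connectors
(low $z$, high $P$), module hubs (high $z$, low $P$), network hubs
(high/high). The z-score uses the sample SD of within-module degrees in
the node's module, with $z_i = 0$ when the SD is 0 (including singleton
modules).

## Stability

Global efficiency is the mean inverse shortest-path length over ordered
pairs, with disconnected pairs contributing 0. Efficiency is normalised by
the **current** node count after deletions. This matches the removal
semantics of per-node vulnerability, $V_i = (Eff - Eff_{-i})/Eff$, and has
a documented counter-intuitive corollary: removing a peripheral node can
*raise* efficiency. On a 4-node star, deleting a leaf lifts $Eff$ from
$3/4$ to $5/6$, so the leaf's vulnerability is $-1/9$ — negative values
are expected and reported as such.

Robustness curves delete `round(f N)` nodes at
$f = 0, 0.1, \ldots, 0.5$. Targeted attack ranks nodes once by
intact-network degree (ties: descending absolute-weighted degree, then
gene ID) — the ranking is not recomputed adaptively. Random attack
averages 100 uniform deletion orders; the decline statistics are the
$R^2$ and p-value of OLS on the (mean) curve.

Cohesion is per sample: each gene's positive connectedness is the mean of
its positive incident edge weights (negative likewise), and a sample's
positive cohesion is the relative-abundance-weighted sum over network
genes; negative cohesion is reported as an absolute value and the
negative:positive ratio flags division by zero as missing. Connectedness
is computed from the retained network edges by default — the network is
the analysis object — with `connectedness_from = "correlation"` exposing
the full-matrix alternative. The null-model (taxon-shuffling) correction
of the original cohesion statistic is not applied. Group comparisons are
one-way ANOVA with Tukey HSD at the 5% level and a compact letter
display, run on per-node values for vulnerability and per-sample values
for cohesion.

## Module eigengenes and environment

A module's eigengene is the first principal component of its genes'
standardised profiles, scaled to unit variance and sign-fixed to correlate
positively with the module's mean standardised profile (removing the PC
sign ambiguity so heat maps reproduce). Profiles are `log1p`-transformed
by default: the counts are approximately log-normal, and extracting the
component on the log scale is what makes the eigengene linear in the
latent log-abundance factor; `transform = "none"` retains raw-scale
behaviour for pre-transformed tables. Modules with fewer than 2 usable
(non-constant) genes are skipped with a warning.

Eigengene–chemistry associations are Pearson correlations with two-sided
p-values over shared samples, BH-adjusted across the full module-by-
property grid per land use, starred at q < 0.05 / 0.01 / 0.001.
Zero-variance properties are reported missing and excluded from the
adjustment.

## The synthetic-data generator

No gene-abundance data are bundled; the generator supplies study-shaped
inputs with known ground truth so every stage has a parameter-recovery
test. Its model is a latent factor construction:

* each planted module $m$ has a standard-normal factor per sample; a
  member gene loads $\sqrt{\rho_m}$ on it (sign flipped for a configurable
  fraction of members, which is how negative associations are planted
  while keeping the covariance positive semi-definite by construction);
* hub genes are members whose loading is raised to $\sqrt{0.95}$, so they
  correlate more strongly with every module member than ordinary members
  do with each other — a core–periphery hub. Cross-module hubs are not
  planted: under unit gene variance, factor cross-loadings cannot push
  more than two between-module correlations past an 0.6 edge threshold,
  so such hubs could never materialise in the thresholded network;
* latent log-abundances (factor signal plus independent noise, plus a
  per-gene baseline) are exponentiated, closed to fractions, and counts
  drawn multinomially at lognormal library sizes — reproducing the
  compositional closure SparCC is designed to undo;
* soil-chemistry covariates are linear in the module factors
  (configurable loadings, default two properties per module at
  coefficient 0.9) plus independent noise, then affinely mapped to
  field-realistic ranges (pH around 5.8, Olsen P around 25 mg/l, and so
  on); affine maps leave every correlation untouched;
* gene IDs cycle over the six CAZy classes (GT, GH, PL, CE, AA, CBM).

Defaults are 5 groups x 15 samples, 120 gene families, four modules
(15/12/10/8 genes), within-module correlation 0.85, 25% negative
loadings, 3 hubs, library size 20000 with CV 0.25, chemistry noise SD
0.3. The strong default correlation is deliberate: at 15 samples per
group with BH over all 7140 gene pairs and 1000 permutations, a moderate
(0.7) planted signal sits below the FDR detectability floor described
above and yields empty networks — defensible statistically, but a
degenerate default for a generator whose purpose is end-to-end testing.

What the generator does **not** emulate: realistic CAZy rank-abundance
curves, overdispersion beyond multinomial sampling, sample-sample spatial
correlation, per-group differences in module structure (groups share the
planted loadings and differ only in their sampled factors), and
zero-inflation. Passing recovery tests therefore demonstrates
correctness of the estimators under a clean compositional factor model,
not performance on real soil metagenomes.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; the pipeline derives a
per-stage seed from one master seed, and two runs with the same
configuration produce byte-identical report bundles. The test suite and
acceptance script run their simulations at deliberately compact sizes —
tens of genes, 15–100 samples, 200–1000 permutations, brute-force
oracles on graphs of at most 12 nodes (shortest paths) and 8 nodes
(exhaustive modularity) — chosen so the whole suite completes in about a
minute while still exercising every code path at the study's scale of
network (10–80 nodes).

## Known limitations

* SparCC's sparsity assumption biases estimates when most pairs are truly
  correlated; the exclusion loop mitigates but does not remove this.
* Permutation p-values are granular at $1/(B+1)$; q-values inherit that
  granularity (see the FDR floor note above).
* The OLS power-law fit is a descriptive statistic, not a maximum-
  likelihood tail fit; it is reported with its $R^2$ exactly because the
  networks here are small enough that "scale-free" claims should stay
  modest.
* Targeted attack uses the intact-network degree ranking throughout
  rather than recomputing degrees adaptively after each deletion.
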