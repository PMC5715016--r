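---
title: "Models and methods behind challengeomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind challengeomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the procedure
left room for judgement.

## The crossover interaction screen

### Model

For each gene $g$, expression $y_{gis}$ (precision-weighted log2-cpm for
subject $i$, sample $s$) is modelled with linear mixed models fitted by
maximum likelihood:

$$\text{null:}\quad y = \mu + \text{Time} + \text{Challenge} + \text{Order}
  + b_{\text{subject}} + b_{\text{date}} + \varepsilon$$
$$\text{test:}\quad y = \mu + \text{Time} \times \text{Challenge} + \text{Order}
  + b_{\text{subject}} + b_{\text{date}} + \varepsilon$$

Time is an unordered 3-level factor (baseline, 2 h, 4 h) and Challenge a
2-level factor, so the interaction adds exactly $(3-1)(2-1) = 2$ fixed
parameters and the likelihood-ratio statistic is referred to $\chi^2_2$.
Three choices deserve comment:

* **ML, not REML.** The two models differ in fixed effects; REML
  likelihoods are not comparable across fixed-effect structures.
* **No boundary correction.** The random-effects structure (subject and
  collection-date intercepts) is identical in both models, so the LRT is a
  regular fixed-effects test and the plain chi-square reference applies.
  With 19 subjects the chi-square approximation is mildly anti-conservative
  (empirical type-I error slightly above nominal in our calibration runs);
  we accept this rather than introduce a small-sample correction the
  procedure does not specify.
* **Weights.** By default the voom precision weights enter the likelihood
  as per-observation weights, which is how a weighted mixed model is
  normally meant. A phrase like "weights as fixed effects" can also be read
  literally — the weight value as a covariate — and that reading is
  implemented behind `lmmSpec("covariate")` purely for comparability. It is
  statistically unusual and not the default. Estimates are invariant to
  rescaling all weights, so only relative precision matters.

Genes whose fits do not converge are reported flagged, excluded from the
Bonferroni multiplier $G$ (the count of successfully tested genes), and
never flagged significant. The extended response set uses raw $p < 0.005$;
the top set uses Bonferroni $p < 0.01$. The descriptive effect size
`deltaT4T0` is the unweighted difference of mean log2-cpm between the
4-hour and baseline allergen-arm samples — deliberately simple, because
mixed-model coefficients are harder to read.

For single-arm replication cohorts, `replicationScreen()` drops the
Challenge terms and tests the Time factor (again 2 df) against a null of
order plus random effects.

## Normalization

`normalizeChallenge()` reproduces the standard preprocessing contract:

* cpm conversion and filtering: keep genes with cpm strictly $> 0.1$ in at
  least $\lceil 0.10\, n \rceil$ samples. The ceiling resolves the
  ambiguity of "at least 10%" for non-integer sample counts; the boundary
  is strict, so a gene at exactly 0.1 cpm everywhere is removed.
* TMM composition factors (edgeR), rescaled to geometric mean 1.
* The precision-weight transform (limma::voom): offsets 0.5 (numerator) and
  1 (denominator) in the log2-cpm, a per-gene linear fit on the design
  `~ Time * Challenge + Order` (terms with single-level factors dropped
  automatically), a lowess trend (span 0.5, deterministic) of
  $\sqrt{\text{residual SD}}$ against mean log2-count, and weights equal to
  the inverse fourth power of the trend. Weights are clipped to
  $[10^{-6}, 10^{6}]$; if the trend is degenerate (all genes identical) the
  weights are flat by construction.
* MDS outlier flagging: classical MDS on Euclidean distances over the 500
  most variable genes; a sample is flagged when its distance from the
  coordinate-wise median exceeds 4 times the (scaled) MAD of those
  distances. The 4-MAD rule is our own — the flag rate on homogeneous
  Gaussian data is about 1% per sample — and both the multiplier and the
  decision to drop (rather than only flag) are configurable.

## Leukocyte deconvolution

`deconvolveSample()` follows the signature-based ν-SVR recipe: mixture and
signature are z-scored over their shared genes (the signature globally, so
relative cell-type contrasts are preserved), a linear ν-SVR is fitted at
ν ∈ {0.25, 0.5, 0.75}, the ν with the smallest reconstruction RMSE wins,
negative coefficients are clipped and the rest normalized to fractions.
Z-scoring makes the fractions invariant to positive rescaling of the
mixture. Inputs default to median-of-ratios-normalized counts (linear
scale); log2-cpm input is available behind a flag, as the literature is not
explicit about logging. No significance filter is applied to estimated
fractions.

Permutation p-values permute the mixture's gene labels and refit at the
*observed* best ν only, comparing reconstruction–mixture Pearson
correlations: $p = (1 + \#\{r^\ast \ge r\})/(B + 1)$. Refitting the full ν
grid per permutation would triple the cost without changing the statistic's
null behaviour appreciably; the selection step is therefore not permuted,
and this is the one deliberate shortcut in the module.

`cellFractionScreen()` applies the interaction screen's mixed-model LRT to
each cell type's fraction (no observation weights — fractions have no
count-derived precision), with BH FDR across cell types. Stratified
analyses (for instance by epinephrine administration) are pure subset
operations, as the model has no stratum terms.

## Coexpression modules

Collection-date effects are removed per gene by linear residualization
before correlation; subject effects are deliberately left in, because the
shared response across time points *is* coexpression signal. The unsigned
power adjacency $a_{ij} = |\mathrm{cor}(i,j)|^\beta$ uses $\beta = 6$ by
default; `softThresholdScan()` reports the scale-free fit $R^2$ (log–log
regression of the connectivity density over equal-width connectivity bins)
and picks the smallest $\beta$ reaching $R^2 \ge 0.8$, but the pipeline
pins $\beta = 6$ for comparability. A signed variant is available behind a
flag.

The topological overlap matrix is computed exactly as
$\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$, and modules come from average-linkage
clustering of $1 - \mathrm{TOM}$ with a dynamic-hybrid-style cut: a static
cut at height 0.99 defines branches, branches with at least 30 genes become
modules, and genes in smaller branches are attached to the module with the
highest mean topological overlap *only if* their mean dissimilarity to it
does not exceed the cut height — otherwise they stay unassigned (label 0).
That attachment condition is what keeps i.i.d. noise genes grey while
letting split-off fragments rejoin their module. Modules are relabelled by
decreasing size with lexicographic tie-breaks, and the whole procedure is
deterministic and invariant to gene input order (genes are canonically
sorted internally). The `deepSplit` argument is accepted for interface
stability but currently only validated. The exact tree-cut variant behind
any particular published module count is unknowable from a methods
description; module counts on real data are therefore not a quantity this
package promises to reproduce.

Enrichment of a module for a target gene set is plain contingency
arithmetic — fold $= (k/n)/(K/N)$ with the target intersected with the
universe first — and a one-sided Fisher exact test, BH-corrected across
modules. The universe is the gene set that entered module detection.

## Causal network with eQTL priors

The top 25% of genes by variance enter the network. Each gene is
standardized and discretized by k-means ($k = 3$, 10 seeded restarts) into
ordered states. Two collapse rules follow the "drop groups without enough
members" idea: clusters with fewer than 2 members are dropped (points
reassigned to the nearest surviving center), and clusters whose centers lie
within 0.5 standardized units are merged, because two centers that close
describe one expression regime. The merge rule is what maps a genuinely
bimodal gene to two states (high/low) — plain $k = 3$ k-means on bimodal
data splits one mode into two well-populated clusters, so a pure occupancy
rule cannot produce the documented two-state behaviour. Unimodal continuous
genes keep three states (centers roughly at $-1.1, 0, 1.1$ SD); surviving
states are relabelled 0..m−1 by center order so states are comparable
across genes.

Structure learning maximizes the BDeu score (equivalent sample size 1) plus
a log structure prior by greedy hill climbing over add/delete/reverse
moves, parent sets capped at 3, acyclicity enforced, best of 20 seeded
restarts (the first from the empty graph, the rest from random sparse
DAGs). The eQTL prior is *soft*: an edge $u \to v$ multiplies the prior by
`orientationOdds` (default 10) when $u$ is an eQTL-anchored gene and by its
inverse when $v$ is one — "can be considered a parent" is permissive, not a
hard constraint, and a soft prior lets strong data overrule a misannotated
anchor. The search/score combination substitutes for unpublished software
internals; it honours the described inputs (discretized states, eQTL
parents, three-state genes) but is not a re-implementation of any specific
tool. Partial priors computed from continuous data are described nowhere in
enough detail to implement and are omitted.

Two properties are worth knowing. First, BDeu on 3-state data has limited
power for edges whose dependence is largely explained through alternative
paths: in our planted-DAG experiments the learned graph can score *above*
the true DAG while missing such edges. Skeleton recall around 85–90% at 10
nodes and 500 samples is the realistic operating point, not a bug. Second,
a node with more true parents than the search cap (3) is unrecoverable by
construction, so recovery experiments plant DAGs with in-degree ≤ 3.

## Key driver analysis

`projectTargets()` implements the projection: targets present in the
network are expanded by all neighbours at path length one (ignoring edge
direction — a regulator sits upstream and would be missed by a directed
expansion), and the largest weakly connected component of the induced
subgraph is kept, with lexicographic tie-breaking.

`keyDriverAnalysis()` defines the background as the union of undirected
K-step neighbourhoods of the targets (K = 7), and for each background node
tests its directed k-step descendant set (k = 1..K) for target enrichment
with a one-sided Fisher test over the background universe (the candidate
excluded). The per-node p is the minimum over k without an inner
multiplicity adjustment — the scan over k is part of the statistic, and BH
across candidates handles multiplicity; a Bonferroni-over-k option exists
for the cautious. Whether the Fisher universe should be the background or
the whole network is genuinely underdetermined; background is the default
because that is the population from which candidates are drawn.

Path levels are the longest directed path from a node to any sink (sinks at
level 0), computed by dynamic programming over a topological order; cycles,
which can only arise in imported networks, are first broken by a greedily
approximated feedback arc set, with a warning. "Path level" has no single
established definition; longest-path-to-sink makes the top level the most
upstream regulators, which matches the way driver hierarchies are read, but
it is a documented choice, not a claim about any particular published
figure. Per-level driver enrichment and driver-set overlaps use the shared
2×2 machinery (sample odds ratio, Haldane 0.5 correction when a cell is
zero, two-sided Fisher p).

## The synthetic-data generator

`simulateChallengeDataset()` emulates the study conditions end to end: 19
subjects by default, each with 3 time points × 2 arms; negative-binomial
counts around per-gene means multiplied by
$2^{(\text{subject} + \text{date} + \text{shift} + \text{module} + \varepsilon)}$;
a planted interaction in a configurable fraction of genes (default 12.5%,
the rough share of response genes among tested genes), with the 4-hour
shift defaulting to 0.24 log2-cpm, the 2-hour shift to a sixth of that
(mirroring the observed 0.24 vs 0.04 means), and 65% of affected genes
up-regulated; challenge order randomized per subject and an epinephrine
flag drawn at the observed 11/19 rate.

Choices the conditions did not pin down, made once and documented here:

* **Per-gene random effects.** Subject and date intercepts are drawn per
  gene (SDs 0.5 and 0.1 log2 by default). A single global per-sample shift
  would be absorbed entirely by cpm normalization — making the subject
  variance unidentifiable downstream — and is also not what a per-gene
  mixed model describes.
* **Noise partition.** Biological overdispersion is carried by the
  per-observation log-normal term `sigmaResid` (default 0.5 log2);
  `nbDispersion` (default 0.01) covers only technical overdispersion beyond
  Poisson. Setting the NB dispersion to a conventional bulk-RNA-seq 0.1
  *in addition to* `sigmaResid` would double-count biological noise.
* **Abundance spread.** Baseline abundances are log-normal with SD 1.2
  log2 around 32 cpm. Real transcriptomes are broader, but at the
  hundred-gene scale used for testing a broader spread lets single genes
  dominate the library sum, injecting shared per-sample normalization noise
  that the genome-wide denominator of real data does not have.
* **Streams.** Every logical component (design, library sizes, gene
  effects, subject effects, factors, noise, counts) draws from its own
  stream derived from the master seed, so changing the gene count does not
  perturb the subject-level draws. Identical configurations give
  bit-identical output.

The generator does **not** emulate: batch effects beyond collection date,
missing samples (the real cohorts have them; the screen tolerates them as
missing-at-random but the generator always produces complete crossovers),
gene-length effects, read-level artefacts, or any single-cell structure.
`simulateMixtures()` produces exact signature convolutions with log-normal
noise — real bulk mixtures also contain cell types absent from the
signature, so recovery there is easier than reality. `simulateCausalLayer()`
uses linear-Gaussian structural equations with equal edge weights; real
regulatory effects are neither linear nor homogeneous. Passing tests
therefore demonstrate correctness of the machinery under the stated model,
not performance on any real cohort.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each statistical property is stably
observable: screens on 120–200 genes × 19 subjects (calibration and
power), deconvolution on 120-gene signatures with 5 cell types, module
recovery on two planted 50-gene blocks, structure learning on 10-node DAGs
at 500 samples pooled over six plants, and the full pipeline on ~100–150
gene studies. All stochastic steps take explicit seeds; the pipeline
derives per-stage seeds from a master seed by stage name, so disabling one
stage never shifts another's stream, and two runs with the same
configuration are byte-identical.

## Known limitations

* The chi-square LRT reference is slightly anti-conservative at 19
  subjects; users wanting strict type-I control at small n should verify by
  simulation at their design size (the generator makes this a few lines).
* Bonferroni uses the count of converged genes; with near-complete
  convergence this matches multiplying by the full gene count, but the two
  differ when many genes fail.
* TMM factors are not exactly invariant to depth rescaling (precision
  weights depend on depth); deviations are at the 1% level.
* The structure learner returns one DAG, not a posterior; edges should be
  read as a point estimate whose skeleton is far more reliable than any
  individual orientation, except where eQTL anchors pin direction.
* Deconvolution quality is bounded by signature quality; the package ships
  no signature matrix and treats it as user input (tests build clearly
  synthetic ones).
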