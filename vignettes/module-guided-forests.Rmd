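---
title: "Module-guided random forests: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-guided random forests: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrf)
```

## The problem

Predicting a quantitative trait (say, body weight in grams) from thousands of
heterogeneous genomic variables — categorical genetic-marker genotypes and
continuous transcript abundances — faces two coupled difficulties. First, the
curse of dimensionality: cohorts of an F2 intercross typically have one or
two hundred individuals against thousands of variables. Second, strong
correlation structure: markers are linked along chromosomes (linkage
disequilibrium), transcripts are co-expressed in modules, and eQTL effects
tie the two layers together. Conventional random forests handle
dimensionality well but split importance arbitrarily among correlated
variables, so biologically coherent groups of predictors "dilute" each other
in the rankings.

`mgrf` addresses both problems by letting the correlation structure guide
the forest:

1. **Mixed-type correlation network.** Every pair of variables gets an
   association score: Pearson correlation for two continuous variables,
   normalized mutual information (NMI) for two categorical variables, and
   NMI after a three-bin discretization for a mixed pair. A sparse network
   keeps an edge only when the association is strong in absolute value *and*
   locally top-ranked (see below).
2. **Modules by modularity maximization.** The network is cut into
   non-overlapping modules by maximizing Newman's weighted modularity, with
   the module count emerging automatically.
3. **Module-guided forest.** At every tree node, candidate split variables
   are drawn in two stages — first a set of modules, then exactly one
   representative variable per module — so candidates are always from
   pairwise-distinct modules and correlated variables never compete within
   one candidate set.
4. **Iterated importance weighting.** Forests are re-grown a few times; the
   module and variable importances learned by one forest weight the
   sampling of the next.
5. **Corrected importance and interaction tests.** The final forest yields
   impurity-decrease variable importance (VI), module importance (MI = sum
   of member VIs), a corrected variable importance (cVI) that pools VI over
   within-module network neighbours, and a hypergeometric test of pairwise
   variable interaction based on co-occurrence of split variables across
   trees.

## Association measures and the network

For a continuous variable $X$ the three-bin discretization uses
$\mu_X \pm \delta_X$ (sample mean, sample $n-1$ standard deviation) as cut
points; the middle bin is closed, so boundary values are `mid`, and a
constant variable is all `mid`. NMI is
$\mathrm{MI}(x,y)/\sqrt{H(x)H(y)}$ with natural-log entropies of empirical
frequencies, set to 0 when either entropy vanishes. The square-root
normalization is symmetric and bounds NMI in $[0,1]$.

An edge joins variables $i,j$ with score $s = |c_{ij}|$ iff

* $s > 0.5$ and one of the two is in the other's top-5 association list, or
* $s > 0.8$ and one is in the other's top-50 list.

Pearson scores enter in absolute value: for grouping and sampling weights,
negative co-expression is still dependence. Because Pearson and NMI live on
different scales, top-rank lists are computed separately within each pair of
variable sources (marker–marker, transcript–transcript, marker–transcript),
so no data type crowds out another. Rank ties break by variable id and edge
endpoints are stored in lexicographic order, making the network fully
deterministic. Constant variables get association 0 everywhere and end up
isolated.

All four tuning constants (`t1 = 0.5`, `r1 = 5`, `t2 = 0.8`, `r2 = 50`) are
exposed as arguments of `build_network()`; edge count is monotone in each
(more edges with lower thresholds or larger ranks), which the test suite
checks.

## Module detection

`detect_modules()` maximizes Newman's weighted modularity

$$Q = \sum_c \left[ \frac{w_{in}(c)}{W} - \left(\frac{s(c)}{2W}\right)^2 \right]$$

by recursive leading-eigenvector bipartition: for each connected component,
the leading eigenvector of the (generalized) modularity matrix proposes a
split, greedy node-moving sweeps refine it (each sweep provably never
decreases $Q$), and recursion stops when no split increases $Q$. The module
count is therefore automatic, matching the role the original analyses gave
their spectral clustering step. Design details chosen for determinism:

* dense symmetric eigendecomposition for groups up to 400 nodes, a shifted
  matrix-free power iteration (tolerance $10^{-12}$, cap 2000 iterations)
  above that;
* eigenvector sign fixed by making the largest-magnitude component
  positive; components with $|v_i| < 10^{-12}$ join the positive group;
* splits accepted only when the refined $\Delta Q$ exceeds $10^{-10}$;
* modules never span disconnected components and isolated nodes become
  singleton modules.

A fast agglomerative alternative (`method = "greedy"`, via
`igraph::cluster_fast_greedy`) is provided as a robustness fallback; the
partition interface is identical, so other optimizers can be swapped in.

## The forest

Trees are CART-style regression trees grown on bootstrap samples of size
$n$ drawn with replacement; out-of-bag (OOB) samples estimate
generalization error. Splits minimize squared loss. Continuous split points
are midpoints between consecutive distinct sorted values; categorical
splits order observed levels by mean response and scan level prefixes,
which is exact for squared loss and $O(L \log L)$. Ties break by (larger
reduction, smaller variable index, smaller threshold), and all randomness
flows through R's RNG, so a fixed seed reproduces forests split for split.
Categorical levels unseen at a node during training are routed to the right
child at prediction time.

**Two-stage candidate sampling.** At each node, `k_mod` candidate modules
are drawn, then one variable per module:

* module stage: stage-1 draws $N_1 = \max(\lceil M/3 \rceil, k_{mod})$
  modules without replacement with per-draw probability proportional to the
  remaining module weights, stage-2 keeps $k_{mod}$ of them uniformly;
* variable stage: within each chosen module, stage-1 draws
  $\lceil |m|/3 \rceil$ members weighted by variable importance, stage-2
  keeps exactly one uniformly.

The default $k_{mod} = \max(1, \lceil M/3 \rceil)$ mirrors the classic
`mtry = m/3` regression heuristic at the module level (several latent
factors are assumed to drive the trait); with that default the module-stage
pool equals $\lceil M/3 \rceil$. The $N_1$ maximum is taken so that the
degenerate configuration `k_mod = M` with singleton modules reduces exactly
to evaluating a permutation of all variables. The mixed
weighted-then-uniform scheme favours informative items without ever fixing
the candidate set. Weighted draws are implemented with exponential
(Efraimidis–Spirakis) keys, whose without-replacement order is distributed
identically to sequential proportional draws.

**Iterated weighting.** Iteration 1 samples uniformly. Iteration $t+1$
weights modules by the MI and variables by the raw VI of iteration $t$
(never by cVI: within a module, raw VI is an adequate relative ranking, and
correcting it would double-count the very correlations the correction
handles). Importances are re-estimated each round, not accumulated. Every
weight receives an epsilon floor of $10^{-6} \cdot \max(\text{weights}, 1)$
so zero-VI variables keep a nonzero selection probability and cannot be
permanently excluded by one unlucky round. Iteration stops when the $L_1$
distance between successive VI vectors, normalized to proportions, falls
below `vi_tol = 0.01` (i.e. less than 1% total absolute change — "percent
normalized" tolerances are stated on the proportion scale, where the
default is attainable within a handful of iterations), or after `max_iters`
forests.

**Importance measures.** VI is impurity-decrease importance: the summed SSE
reduction of all nodes splitting on a variable, divided by `ntrees` (the
regression analog of Gini importance; permutation importance was rejected
for its computation cost and its own correlation bias). MI of a module is
the sum of its members' VIs. The corrected importance is

$$\mathrm{cVI}(v_i) = \mathrm{VI}(v_i) + \sum_{j \ne i} c_{ij}\,\mathrm{VI}(v_j)$$

over variables $j$ that are both network neighbours of $v_i$ and in the
same module, with $c_{ij}$ the absolute association stored on the edge.
The self term has weight 1 and the sum is deliberately unnormalized: hub
variables of strong modules should rank high, which is the behaviour the
correction is meant to restore when conventional VI splits credit
arbitrarily among correlated variables. cVI is computed once, from the
final iteration's forest only.

## Interaction testing

A variable is "present" in a tree when it is the split variable of at least
one node (once per tree). For variables $u, v$ present in $n$ and $m$ of
$N$ trees, the number $k$ of trees containing both is hypergeometric under
independence, and

$$p = \sum_{j=k}^{\min(n,m)} \frac{C(n,j)\, C(N-n,\, m-j)}{C(N,m)}$$

is evaluated in log space. Conditional splitting makes interacting variables
co-occur more often than chance, so a small right tail flags candidate
epistatic or associated pairs; note that two variables forced into *every*
tree co-occur with probability one and correctly get $p = 1$. Pairs are
labelled marker–marker, transcript–transcript or marker–transcript from
source tags, ranked by raw $p$ (matching how the original top-100 lists
were built) with Benjamini–Hochberg $q$-values reported alongside; the
default presence floor `min_presence = 5` excludes degenerate never-chosen
variables and bounds the multiplicity burden. Stable rankings need a large
dedicated ensemble — 6000 trees in the original mouse-weight analyses —
grown at the converged weights, separate from the 1000-tree importance
forest.

## What the simulators emulate

`simulate_bxh_like()` emulates the structure of an F2 mouse intercross
"genetics of gene expression" study at desk scale: 150 samples, 19
autosomes of 10 markers with recombination fraction 0.1 between neighbours
(allele-dosage correlation 0.8 per interval), 60 expression modules of 10
genes with within-module correlation 0.7, every third module driven by an
eQTL explaining 40% of its latent-factor variance, and a body-weight-like
phenotype (intercept 35 g, noise 3.5 g) with three additive marker effects
($\beta = 2.5$), three additive transcript effects ($\beta = 2$) and two
pairwise interactions over centered variables. One trait marker doubles as
the eQTL of a trait gene module, so part of the genotype effect is
mediated by expression — the "expression bridges genotype and phenotype"
structure of eQTL studies. The phenotype effect sizes were calibrated once
against the real study's reported coefficient-of-determination pattern
(genotype-only weakest by a wide margin, expression-only strong, combined
best); under them the noiseless signal explains roughly 0.7 of phenotype
variance, a genotype-only forest reaches an out-of-bag $R^2$ of about
0.25, and an expression-only forest about 0.35. F2 genotypes come from two
independent gamete Markov chains per chromosome, so dosage frequencies are
1:2:1 and linkage decays as $(1-2r)$ per interval.

`make_group_benchmark()` reproduces the documented skeleton of the
structured importance benchmark: 110 relevant variables — a correlated
group $G_1$ of configurable size and a second group $G_2$ (both pairwise
$\rho = 0.9$, each carrying one latent signal), independent relevant
singletons for the remainder — plus 1000 pure-noise variables, with
additive response over the group factors and singletons. Default effect
sizes ($\beta_{group} = 3$, $\beta_{single} = 1$, $\sigma = 6.8$, $n =
400$) were chosen once for clear effect separation at an oracle $R^2$ of
about 0.7.

What the simulators do *not* emulate: real recombination maps and marker
spacing, dominance, batch and technical covariates, heavy-tailed expression
noise, and the sheer scale of real data (7441 genes, 1065 markers). Tests
passing on these generators therefore demonstrate the algorithmic
properties — bias correction, module recovery, calibration, integration
benefit — not field performance on any particular real dataset.

## Numerical and protocol choices

* Node splitting requires an SSE reduction above $10^{-10}$; nodes at or
  below `nodesize` samples (default 3, chosen for small cohorts) or with
  response range below $10^{-12}$ become leaves.
* The split search uses a presorted-scan for large nodes and gather-sort
  for small ones; both enumerate the same split set.
* OOB error excludes (with a warning) samples that were never out of bag.
* Cross-validation (`run_benchmark()`) keeps the same train/test split for
  every data-type arm in a fold (paired design) and, by default, rebuilds
  the network and modules inside each training fold so no test information
  leaks into module structure or sampling weights; `modules_precomputed =
  TRUE` restores the cheaper protocol that clusters once on all samples.
  One-tailed paired t-tests compare per-fold RMSE vectors between arms;
  when the fold differences have zero variance the p-value is 1 for a
  non-negative mean difference and the double floor otherwise.
* Forest ensembles: importance stabilizes slowly in ensemble size, so
  defaults are 1000 trees for importance work and 6000 for interaction
  ranking. The test suite and the acceptance script scale ensembles and
  sample counts down (stated in each test) to keep full runs in minutes;
  equivalence-mode comparisons between the module-guided and conventional
  samplers use 3000 trees because Spearman agreement of two independently
  grown forests' importance vectors is limited by Monte-Carlo noise at
  small ensembles; the bias-correction benchmark uses 150-tree,
  two-iteration fits on half-samples of the 400-sample benchmark; and the
  data-integration cross-validation uses 400-tree, three-iteration fits
  over 10 trials of 5-fold CV.

## Known limitations

* Categorical variables are limited to 64 levels by the bitmask split
  encoding (far above the 3 genotype classes of an F2 design).
* The modularity optimizer is a functional substitute for the published
  spectral clustering tool it emulates: it optimizes the same objective
  with the same automatic module count, but is not a line-for-line port,
  and it does not implement that tool's cluster-significance test.
* Only pairwise interactions are tested; higher-order interactions are out
  of scope.
* Missing data are rejected rather than imputed; `impute_missing()` must
  be called explicitly.
* The hypergeometric test conditions on presence counts and is calibrated
  under independent presence; variables with near-universal presence
  yield uninformative tests by construction.
* At desk scale the benefit of integrating genotypes with expression is
  directional but small: in repeated cross-validation the combined arm has
  the lowest mean error and beats genotype-only decisively, yet its margin
  over expression-only is within fold noise for most 150-sample
  realizations. Impurity-based split selection favours continuous
  variables (many candidate thresholds) over three-level markers when
  hundreds of genes compete, and at realistic eQTL strengths mixed-type
  associations stay below the edge threshold, so no mixed modules form to
  channel marker sampling. Larger cohorts or stronger marker
  architectures are needed before the integration gain clears paired
  significance tests.
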