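# mgrf — module-guided random forests for integrative trait prediction

`mgrf` predicts a quantitative trait (e.g. body weight of F2 intercross
mice, in grams) from heterogeneous genomic predictors — categorical
genetic-marker genotypes and continuous transcript abundances — and ranks
the predictors and their interactions in a way that respects their
correlation structure.

Small cohorts with thousands of correlated variables defeat both
penalized linear models (which force an encoding on genotype classes) and
plain random forests (which split importance arbitrarily among correlated
variables). `mgrf` instead:

1. builds a **mixed-type correlation network**: Pearson correlation
   between continuous pairs, normalized mutual information
   `NMI = MI / sqrt(Hx Hy)` between categorical pairs, and NMI after a
   three-bin discretization at `mu +/- sd` for mixed pairs; an edge needs
   `|c_ij| > 0.5` plus a top-5 rank, or `|c_ij| > 0.8` plus a top-50 rank,
   with ranks computed per data-type block;
2. cuts the network into **modules** by maximizing Newman's weighted
   modularity `Q = sum_c [ w_in(c)/W - (s_c/2W)^2 ]` with a recursive
   leading-eigenvector bipartition (automatic module count);
3. grows an **iterated regression forest** whose candidate split variables
   are drawn module-first (two-stage weighted sampling, one representative
   per module), re-weighted each iteration by the learned module (MI) and
   variable (VI) importances;
4. reports **corrected variable importance**
   `cVI(v_i) = VI(v_i) + sum_j c_ij VI(v_j)` over within-module network
   neighbours j — undoing the dilution of importance among correlated
   variables — and a **hypergeometric co-occurrence test**
   `p = sum_{j>=k} C(n,j) C(N-n, m-j) / C(N,m)` for pairwise interactions
   from the split variables of an `N`-tree ensemble.

## Worked example

Everything below runs in about half a minute on a synthetic desk-scale F2
study (150 mice, 190 linked markers on 19 chromosomes, 600 genes in 60
co-expression modules partially driven by eQTLs; the phenotype has marker,
transcript and interaction terms — see `?f2_sim_spec`).

```r
library(mgrf)

sim  <- simulate_bxh_like(f2_sim_spec(seed = 3))
A    <- pairwise_associations(sim$combined)
net  <- build_network(A)           # 0.5/top-5 or 0.8/top-50 edge criteria
part <- detect_modules(net)
part
#> module_partition: 204 modules over 790 nodes, Q = 0.9839

fit <- fit_mgrf(sim$combined, sim$phenotype, part, net,
                mgrf_control(ntrees = 200, max_iters = 3, seed = 7))
fit$trace
#>   iteration vi_change oob_rmse
#> 1         1        NA 5.382105
#> 2         2 0.5628983 5.142246
#> 3         3 0.3951108 5.060255
```

The out-of-bag RMSE (grams) drops as the importance-weighted sampling
concentrates on informative variables. The top corrected importances
recover the module mates of the causal genes (the phenotype loads on genes
of modules 1–3 and on three markers, one of which is also the eQTL of
module 2):

```r
round(head(sort(fit$importance$cvi_percent, decreasing = TRUE)), 2)
#> g_m02_04 g_m02_01 g_m02_02 g_m02_10 g_m02_05 g_m02_09
#>     2.75     2.47     2.32     2.24     2.12     2.01
```

`cvi_percent` is the share (%) of total corrected importance; whole
modules surface together because cVI pools importance over within-module
network neighbours. Interactions are then ranked from a dedicated larger
ensemble grown at the converged weights:

```r
big <- fit_forest(sim$combined, sim$phenotype, part,
                  mod_weights = fit$importance$mi,
                  var_weights = fit$importance$vi,
                  control = mgrf_control(ntrees = 2000))
head(test_all_pairs(big), 3)[, c("u", "v", "pair_type", "k", "p")]
#>          u        v             pair_type  k            p
#> 1 g_m07_04 g_m33_02 transcript-transcript  7 1.840899e-05
#> 2   c05m04 g_m21_09     marker-transcript 23 6.666418e-05
#> 3 g_m02_01 g_m26_06 transcript-transcript 14 8.727008e-05
```

and the three-way data-type comparison (genotype-only / expression-only /
combined) runs as a paired cross-validation benchmark:

```r
cv <- run_benchmark(sim$genotypes, sim$expression, sim$phenotype,
                    folds = 5, trials = 2, seed = 1)
cv$summary          # mean per-arm CV RMSE; combined is lowest
cv$t_tests          # one-tailed paired t-tests between arms
```

A thin command-line interface wraps the same functions
(`system.file("exec", "mgrf", package = "mgrf")` after installation, or
`exec/mgrf` in the source tree):

```sh
mgrf simulate --scenario bxh --seed 1 --out sim/
mgrf fit --data sim/genotypes.tsv --phenotype sim/phenotype.tsv --out fit/
```

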