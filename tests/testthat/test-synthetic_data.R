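test_that("F2 genotypes follow Mendelian and linkage expectations", {
  spec0 <- f2_sim_spec(n_samples = 400, chromosomes = c(5L, 5L),
                       recomb_fraction = 0, seed = 1)
  set.seed(spec0$seed)
  g0 <- simulate_f2_genotypes(spec0)
  # r = 0: all markers on a chromosome identical within each sample
  expect_true(all(g0$values[, 1:5] == g0$values[, 1]))
  expect_true(all(g0$values[, 6:10] == g0$values[, 6]))

  spec5 <- f2_sim_spec(n_samples = 5000, chromosomes = c(2L),
                       recomb_fraction = 0.5, seed = 2)
  set.seed(spec5$seed)
  g5 <- simulate_f2_genotypes(spec5)
  expect_lt(normalized_mi(g5$values[, 1], g5$values[, 2]), 0.05)
  freq <- tabulate(g5$values[, 1] + 1, 3) / 5000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.02))
})

test_that("expression realizes the requested module correlation structure", {
  spec <- f2_sim_spec(n_samples = 1000, chromosomes = c(4L, 4L),
                      n_modules = 6, genes_per_module = 5, rho = 0.9, seed = 3)
  set.seed(spec$seed)
  geno <- simulate_f2_genotypes(spec)
  expr <- simulate_expression(geno, spec)
  within <- c(); between <- c()
  R <- cor(expr$values)
  for (k in 1:6) {
    idx <- (k - 1) * 5 + 1:5
    within <- c(within, abs(R[idx, idx][upper.tri(diag(5))]))
    if (k < 6) between <- c(between, abs(R[idx, idx + 5]))
  }
  expect_gt(mean(within), 0.85)
  expect_lt(mean(within), 0.95)
  expect_lt(mean(between), 0.1)
})

test_that("eQTL effects link markers to module genes (and only then)", {
  base <- f2_sim_spec(n_samples = 1500, chromosomes = c(3L), n_modules = 2,
                      genes_per_module = 4, rho = 0.8, seed = 4)
  base$eqtl <- data.frame(marker = "c01m01", module = 1, effect = 0.5)
  set.seed(base$seed)
  geno <- simulate_f2_genotypes(base)
  expr <- simulate_expression(geno, base)
  r_driven <- abs(cor(geno$values[, "c01m01"], expr$values[, "g_m01_01"]))
  r_free <- abs(cor(geno$values[, "c01m01"], expr$values[, "g_m02_01"]))
  expect_gt(r_driven, 0.4)  # sqrt(0.5 * 0.8) ~ 0.63 expected
  expect_lt(r_free, 0.1)
})

test_that("phenotype terms behave as constructed", {
  spec <- f2_sim_spec(n_samples = 500, chromosomes = c(3L), n_modules = 2,
                      genes_per_module = 3, seed = 5, sigma = 0,
                      additive = data.frame(variable = "g_m01_01", beta = 2),
                      interactions = data.frame(var1 = character(),
                                                var2 = character(),
                                                gamma = numeric()))
  set.seed(spec$seed)
  geno <- simulate_f2_genotypes(spec)
  expr <- simulate_expression(geno, spec)
  ph <- simulate_phenotype(geno, expr, spec)
  expect_equal(abs(cor(ph$phenotype, expr$values[, "g_m01_01"])), 1,
               tolerance = 1e-12)

  # pure interaction: near-zero marginals, but the joint term explains y
  spec2 <- f2_sim_spec(n_samples = 2000, chromosomes = c(3L), n_modules = 2,
                       genes_per_module = 3, seed = 6, sigma = 0,
                       additive = data.frame(variable = character(),
                                             beta = numeric()),
                       interactions = data.frame(var1 = "c01m02",
                                                 var2 = "g_m02_01", gamma = 1))
  set.seed(spec2$seed)
  geno2 <- simulate_f2_genotypes(spec2)
  expr2 <- simulate_expression(geno2, spec2)
  ph2 <- simulate_phenotype(geno2, expr2, spec2)
  expect_lt(abs(cor(ph2$phenotype, geno2$values[, "c01m02"])), 0.08)
  expect_lt(abs(cor(ph2$phenotype, expr2$values[, "g_m02_01"])), 0.08)
  joint <- (geno2$values[, "c01m02"] - mean(geno2$values[, "c01m02"])) *
    (expr2$values[, "g_m02_01"] - mean(expr2$values[, "g_m02_01"]))
  expect_gt(abs(cor(ph2$phenotype, joint)), 0.99)

  spec_bad <- spec2
  spec_bad$additive <- data.frame(variable = "nope", beta = 1)
  expect_error(simulate_phenotype(geno2, expr2, spec_bad), "unknown variables")
})

test_that("group benchmark delivers its documented structure", {
  bench <- make_group_benchmark(g1_size = 10, n_samples = 500, seed = 7)
  expect_length(bench$truth$relevant, 110)
  expect_equal(bench$truth$g1, sprintf("G1_%02d", 1:10))
  R <- abs(cor(bench$dataset$values[, bench$truth$g1]))
  offdiag <- R[upper.tri(R)]
  expect_gt(mean(offdiag), 0.85)
  expect_lt(mean(offdiag), 0.95)
  # noise variables are pure noise: no correlation with the oracle signal
  noise_r <- abs(cor(bench$dataset$values[, sprintf("N%04d", 1:50)],
                     bench$truth$oracle))
  expect_lt(max(noise_r), 0.2)
  # oracle explains about 70% of phenotype variance
  expect_gt(r_squared(bench$truth$oracle, bench$phenotype), 0.55)
  expect_lt(r_squared(bench$truth$oracle, bench$phenotype), 0.85)
})

test_that("generators are deterministic and emit valid datasets", {
  s1 <- simulate_bxh_like(f2_sim_spec(n_samples = 40, chromosomes = rep(3L, 2),
                                      n_modules = 4, seed = 8))
  s2 <- simulate_bxh_like(f2_sim_spec(n_samples = 40, chromosomes = rep(3L, 2),
                                      n_modules = 4, seed = 8))
  expect_identical(s1$combined$values, s2$combined$values)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$truth$relevant, s2$truth$relevant)
  expect_s3_class(s1$combined, "omics_dataset")  # validation ran on build
  b1 <- make_group_benchmark(g1_size = 6, n_noise = 50, n_relevant = 20,
                             n_samples = 30, seed = 9)
  b2 <- make_group_benchmark(g1_size = 6, n_noise = 50, n_relevant = 20,
                             n_samples = 30, seed = 9)
  expect_identical(b1$dataset$values, b2$dataset$values)
})

test_that("planted-partition networks honour their block structure", {
  pp <- planted_partition_network(c(10, 10), p_in = 0.8, p_out = 0, seed = 10)
  expect_setequal(names(pp$labels), pp$network$nodes)
  memb <- pp$labels
  cross <- memb[pp$network$edges$source] != memb[pp$network$edges$target]
  expect_equal(sum(cross), 0L)
  # intra-block edge count within 3 sigma of Binomial(C(10,2)*2, 0.8)
  n_edges <- nrow(pp$network$edges)
  expected <- 0.8 * 2 * choose(10, 2)
  expect_lt(abs(n_edges - expected), 3 * sqrt(expected * 0.2) + 1)
})
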