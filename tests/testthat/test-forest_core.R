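# simple regression fixture: y depends on x01 only, plus noise variables
signal_dataset <- function(n = 200, m_noise = 5, seed = 1, noise_sd = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n * (m_noise + 1)), n, m_noise + 1,
              dimnames = list(sprintf("s%03d", 1:n),
                              sprintf("x%02d", 1:(m_noise + 1))))
  d <- omics_dataset(v, kind = "continuous")
  y <- setNames(v[, "x01"] + rnorm(n, sd = noise_sd), rownames(v))
  list(d = d, y = y)
}

test_that("weighted_subset_sample honours stage sizes and degenerate weights", {
  set.seed(1)
  items <- letters[1:4]
  expect_setequal(weighted_subset_sample(items, rep(1, 4), 4, 4), items)
  for (i in 1:25)
    expect_equal(weighted_subset_sample(items, c(0, 0, 0, 5), 1, 1), "d")
  # all-zero weights fall back to uniform
  expect_length(weighted_subset_sample(items, rep(0, 4), 2, 2), 2)
})

test_that("uniform two-stage sampling is unbiased (chi-square vs uniform)", {
  set.seed(2)
  draws <- replicate(40000, weighted_subset_sample(1:4, rep(1, 4), 2, 1))
  freq <- tabulate(draws, 4) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))
  chi <- sum((tabulate(draws, 4) - 10000)^2 / 10000)
  expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("two_stage_candidates respects module structure and weights", {
  net <- manual_network(sprintf("v%d", 1:6), NULL)
  singles <- manual_partition(net, setNames(sprintf("m%d", 1:6), net$nodes))
  set.seed(3)
  cand <- two_stage_candidates(singles, k_mod = 6)
  expect_setequal(cand, net$nodes)  # singleton modules, k_mod = M
  one_mod <- manual_partition(net, setNames(rep("m1", 6), net$nodes))
  expect_length(two_stage_candidates(one_mod, k_mod = 1), 1)

  # 3 modules, weights (100, 1, 1): module 1 dominates
  net9 <- manual_network(sprintf("w%d", 1:9), NULL)
  part3 <- manual_partition(net9, setNames(rep(c("A", "B", "C"), each = 3),
                                           net9$nodes))
  mw <- setNames(c(100, 1, 1), c("1", "2", "3"))
  set.seed(4)
  picks <- replicate(2000, two_stage_candidates(part3, mod_weights = mw, k_mod = 1))
  frac_m1 <- mean(picks %in% c("w1", "w2", "w3"))
  expect_gt(frac_m1, 0.5)
  expect_gt(frac_m1, 1 / 3 + 0.1)  # strictly above uniform
})

test_that("best_split enumerates thresholds and level partitions exactly", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(sprintf("s%d", 1:4), "x"))
  s <- best_split(X, c(0, 0, 10, 10))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$reduction, 100)

  # categorical levels (0,1,2) = (a,b,c) with means (0,10,0): {b} vs {a,c}
  v <- matrix(c(0, 0, 1, 1, 2, 2), 6, 1,
              dimnames = list(sprintf("s%d", 1:6), "g"))
  d <- omics_dataset(v, kind = "categorical")
  s2 <- best_split(d, c(0, 0, 10, 10, 0, 0))
  expect_true(s2$is_cat)
  expect_true(setequal(s2$left_levels, c(0, 2)) ||
              setequal(s2$left_levels, 1))  # {b} alone on either side
  # reduction oracle: perfect separation of (0,0,10,10,0,0)
  expect_equal(s2$reduction, sum((c(0, 0, 10, 10, 0, 0) - mean(c(0, 0, 10, 10, 0, 0)))^2))

  expect_null(best_split(X, rep(3, 4)))  # constant response
})

test_that("constant responses give single-leaf trees predicting the constant", {
  fx <- signal_dataset(n = 30)
  y <- setNames(rep(7, 30), names(fx$y))
  part <- singleton_partition(colnames(fx$d$values))
  set.seed(1)
  model <- fit_forest(fx$d, y, part, control = mgrf_control(ntrees = 20))
  expect_true(all(vapply(model$trees, function(t) nrow(t$nodes), 1L) == 1L))
  expect_equal(unname(predict(model, fx$d)), rep(7, 30))
  expect_equal(suppressWarnings(oob_error(model, fx$d, y)), 0)
})

test_that("a strong univariate signal is learned and dominates importance", {
  fx <- signal_dataset(n = 200, m_noise = 5)
  part <- singleton_partition(colnames(fx$d$values))
  set.seed(5)
  model <- fit_forest(fx$d, fx$y, part, control = mgrf_control(ntrees = 300))
  pred_oob_rmse <- oob_error(model, fx$d, fx$y)
  expect_gt(1 - pred_oob_rmse^2 / var(fx$y), 0.9)  # OOB R^2
  vi <- variable_importance(model)
  expect_gt(vi["x01"] / sum(vi), 0.5)
})

test_that("forests are bit-reproducible under a fixed seed", {
  fx <- signal_dataset(n = 60, m_noise = 4)
  part <- singleton_partition(colnames(fx$d$values))
  ctl <- mgrf_control(ntrees = 25)
  set.seed(99); m1 <- fit_forest(fx$d, fx$y, part, control = ctl)
  set.seed(99); m2 <- fit_forest(fx$d, fx$y, part, control = ctl)
  expect_identical(m1$vi_total, m2$vi_total)
  for (t in c(1, 13, 25))
    expect_identical(m1$trees[[t]]$nodes, m2$trees[[t]]$nodes)
})

test_that("importance conserves the total impurity decrease of the forest", {
  fx <- signal_dataset(n = 80, m_noise = 3, noise_sd = 0.5)
  part <- singleton_partition(colnames(fx$d$values))
  set.seed(6)
  model <- fit_forest(fx$d, fx$y, part, control = mgrf_control(ntrees = 40))
  total_red <- sum(vapply(model$trees, function(t) sum(t$nodes[, "red"]), 0))
  vi <- variable_importance(model)
  expect_equal(sum(vi) * model$ntrees, total_red, tolerance = 1e-9)
  # never-split variables have exactly zero importance
  split_ids <- unique(unlist(lapply(model$trees, function(t)
    names(vi)[t$split_vars])))
  expect_true(all(vi[setdiff(names(vi), split_ids)] == 0))
})

test_that("OOB machinery matches bootstrap expectations", {
  fx <- signal_dataset(n = 100, m_noise = 2, noise_sd = 1)
  part <- singleton_partition(colnames(fx$d$values))
  set.seed(7)
  model <- fit_forest(fx$d, fx$y, part, control = mgrf_control(ntrees = 200))
  oob_frac <- mean(vapply(model$trees, function(t) length(t$oob) / 100, 0))
  expect_lt(abs(oob_frac - (1 - 1 / 100)^100), 0.02)

  # informative vs pure-noise response: OOB error strictly larger for noise
  set.seed(8)
  y_noise <- setNames(sample(fx$y), names(fx$y))
  m_noise <- fit_forest(fx$d, y_noise, part, control = mgrf_control(ntrees = 200))
  expect_gt(oob_error(m_noise, fx$d, y_noise), oob_error(model, fx$d, fx$y))
})

test_that("overfit forests reach near-zero training error on clean signal", {
  fx <- signal_dataset(n = 120, m_noise = 2)
  part <- singleton_partition(colnames(fx$d$values))
  set.seed(9)
  model <- fit_forest(fx$d, fx$y, part,
                      control = mgrf_control(ntrees = 300, nodesize = 1))
  expect_lt(rmse(predict(model, fx$d), fx$y), 0.3 * sd(fx$y))
})

test_that("module importance sums member VIs and checks coverage", {
  vi <- c(a = 2, b = 4, c = 1)
  net <- manual_network(c("a", "b", "c"), NULL)
  part <- manual_partition(net, setNames(c("m1", "m1", "m2"), c("a", "b", "c")))
  mi <- module_importance(vi, part)
  expect_equal(unname(mi), c(6, 1))
  expect_equal(sum(mi), sum(vi))
  part_bad <- manual_partition(manual_network(c("a", "b"), NULL),
                               setNames(c("m1", "m1"), c("a", "b")))
  expect_error(module_importance(vi, part_bad), "not assigned")
})

test_that("cVI adds correlation-weighted within-module neighbour VIs", {
  net <- manual_network(c("a", "b", "c"),
                        data.frame(s = c("a", "b"), t = c("b", "c"),
                                   w = c(0.5, 0.9)))
  # a,b share a module; c is elsewhere, so the b-c edge must not contribute
  part <- manual_partition(net, setNames(c("m1", "m1", "m2"), c("a", "b", "c")))
  vi <- c(a = 2, b = 4, c = 10)
  cvi <- corrected_vi(vi, part, net)
  expect_equal(unname(cvi["a"]), 2 + 0.5 * 4)
  expect_equal(unname(cvi["b"]), 4 + 0.5 * 2)
  expect_equal(unname(cvi["c"]), 10)  # isolated within its module

  # duplicated-column pair: cVI nearly equalizes what VI splits arbitrarily
  set.seed(10)
  n <- 150
  x <- rnorm(n)
  v <- cbind(dup1 = x, dup2 = x + rnorm(n, sd = 1e-6), z = rnorm(n))
  rownames(v) <- sprintf("s%03d", 1:n)
  d <- omics_dataset(v, kind = "continuous")
  y <- setNames(x + rnorm(n, sd = 0.2), rownames(v))
  A <- pairwise_associations(d)
  netd <- build_network(A, r1 = 2, t1 = 0.5)
  partd <- detect_modules(netd)
  set.seed(11)
  model <- fit_forest(d, y, partd, control = mgrf_control(ntrees = 300))
  vi2 <- variable_importance(model)
  cvi2 <- corrected_vi(vi2, partd, netd)
  expect_lt(abs(cvi2["dup1"] - cvi2["dup2"]),
            abs(vi2["dup1"] - vi2["dup2"]) + 1e-12)
  # dilution: each duplicate carries less VI than the variable alone would
  set.seed(11)
  model_alone <- fit_forest(subset_dataset(d, variables = c("dup1", "z")), y,
                            singleton_partition(c("dup1", "z")),
                            control = mgrf_control(ntrees = 300))
  vi_alone <- variable_importance(model_alone)
  expect_lt(max(vi2[c("dup1", "dup2")]), vi_alone["dup1"])
})

test_that("iterated fitting converges and sharpens relevant variables", {
  set.seed(12)
  n <- 150
  v <- matrix(rnorm(n * 60), n, 60,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("x%02d", 1:60)))
  d <- omics_dataset(v, kind = "continuous")
  y <- setNames(v[, 1] + v[, 2] + 0.5 * v[, 3] + rnorm(n, sd = 0.7),
                rownames(v))
  part <- singleton_partition(colnames(v))
  net <- manual_network(colnames(v), NULL)
  fit <- fit_mgrf(d, y, part, net,
                  mgrf_control(ntrees = 150, max_iters = 4, seed = 13))
  expect_lte(fit$iterations, 4)
  expect_equal(sum(fit$importance$vi_percent), 100, tolerance = 1e-6)
  expect_equal(sum(fit$importance$mi_percent), 100, tolerance = 1e-6)
  expect_equal(sum(fit$importance$cvi_percent), 100, tolerance = 1e-6)
  expect_equal(sum(fit$importance$mi), sum(fit$importance$vi), tolerance = 1e-9)
  # weighting concentrates importance on the three relevant variables
  rel_share <- sum(fit$importance$vi_percent[c("x01", "x02", "x03")])
  fit1 <- fit_mgrf(d, y, part, net,
                   mgrf_control(ntrees = 150, max_iters = 1, seed = 13))
  rel_share1 <- sum(fit1$importance$vi_percent[c("x01", "x02", "x03")])
  expect_gt(rel_share, rel_share1)
  # re-running with the same seed reproduces everything
  fit_b <- fit_mgrf(d, y, part, net,
                    mgrf_control(ntrees = 150, max_iters = 4, seed = 13))
  expect_identical(fit$importance, fit_b$importance)
})

test_that("candidate modules at every node are pairwise distinct", {
  sim <- simulate_bxh_like(f2_sim_spec(n_samples = 60, chromosomes = rep(4L, 3),
                                       n_modules = 6, seed = 21))
  d <- sim$combined
  A <- pairwise_associations(d)
  net <- build_network(A)
  part <- detect_modules(net)
  set.seed(22)
  model <- fit_forest(d, sim$phenotype, part,
                      control = mgrf_control(ntrees = 15, trace_candidates = TRUE))
  for (tree in model$trees) {
    for (mods in tree$candidate_modules) {
      expect_equal(anyDuplicated(mods), 0L)
    }
  }
})

test_that("small-sample and misalignment guards trigger", {
  fx <- signal_dataset(n = 30)
  part <- singleton_partition(colnames(fx$d$values))
  expect_error(fit_forest(fx$d, unname(fx$y), part), "aligned")
  tiny <- subset_dataset(fx$d, samples = 1:4)
  expect_error(fit_forest(tiny, fx$y[1:4], part,
                          control = mgrf_control(nodesize = 3)), "at least")
  model <- fit_forest(fx$d, fx$y, part, control = mgrf_control(ntrees = 5))
  expect_error(predict(model, fx$d$values[, 1:3]), "lacks variables")
  expect_length(predict(model, fx$d$values[0, , drop = FALSE]), 0)
})
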