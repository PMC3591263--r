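#' K-fold cross-validation splits for repeated trials
#'
#' Per trial, samples are randomly partitioned into `folds` near-equal test
#' sets (sizes differ by at most 1). Deterministic given `seed`; trials use
#' successive draws of the same stream so each trial gets a different
#' partition.
#'
#' @param n_samples number of samples.
#' @param folds folds per trial (default 10).
#' @param trials repeated trials (default 10).
#' @param seed RNG seed.
#' @return list of `trials` lists, each holding `folds` integer index
#'   vectors (the test sets).
#' @export
kfold_splits <- function(n_samples, folds = 10, trials = 10, seed = 1L) {
  stopifnot(n_samples >= folds)
  set.seed(seed)
  lapply(seq_len(trials), function(tr) {
    perm <- sample.int(n_samples)
    sizes <- rep(n_samples %/% folds, folds)
    extra <- n_samples %% folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    unname(split(perm, rep(seq_len(folds), sizes)))
  })
}

#' Root-mean-square error
#' @param pred,truth equal-length numeric vectors.
#' @return RMSE.
#' @export
rmse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  sqrt(mean((pred - truth)^2))
}

#' Coefficient of determination about the truth mean
#' @param pred,truth equal-length numeric vectors (length >= 2).
#' @return `1 - SSE/SST`; `NA` with a warning if the truth is constant.
#' @export
r_squared <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) {
    warning("truth has zero variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((truth - pred)^2) / sst
}

#' One-tail paired t-test that errors `a` are smaller than errors `b`
#'
#' Tests H1: `mean(a - b) < 0` on paired difference vectors (e.g. per-fold
#' RMSEs of two methods on identical train/test splits). Zero-variance
#' differences use the documented convention p = 1 when the mean difference
#' is >= 0 and the double floor otherwise.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @return p-value.
#' @export
paired_one_tail_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    return(if (mean(d) >= 0) 1 else .Machine$double.xmin)
  }
  t.test(a, b, paired = TRUE, alternative = "less")$p.value
}

.cv_arm_data <- function(arm, geno, expr) {
  switch(arm,
         genotype = geno,
         expression = expr,
         combined = merge_datasets(geno, expr),
         stop("unknown arm: ", arm))
}

#' Paired cross-validation benchmark over data-type arms
#'
#' Reproduces the three-way comparison protocol: for each trial and fold,
#' the same train/test split is used for every arm (genotype-only,
#' expression-only, combined). Within each training fold the correlation
#' network and modules are rebuilt from training samples only (no
#' information leakage; set `modules_precomputed` to reuse partitions built
#' on all samples, a laxer but cheaper protocol), the iterated
#' module-guided forest is fitted, and test-fold RMSE recorded.
#'
#' @param geno marker [omics_dataset()].
#' @param expr transcript [omics_dataset()] over the same samples.
#' @param y aligned phenotype vector.
#' @param arms subset of `c("genotype", "expression", "combined")`.
#' @param folds,trials CV layout (default 10 x 10).
#' @param seed seed for fold construction and forest RNG.
#' @param control [mgrf_control()] for the per-fold fits (benchmark-scale
#'   defaults: 200 trees, 2 iterations).
#' @param modules_precomputed if `TRUE`, build network/modules once on all
#'   samples per arm instead of per training fold.
#' @param plain if `TRUE`, fit conventional (plain mtry) forests instead.
#' @return an `mgrf_cv` object: list with `rmse` (trials x folds x arms
#'   array), `summary` (per-arm mean/sd), `t_tests` (one-sided paired
#'   p-values, row arm smaller than column arm), `folds`, `seed`.
#' @export
run_benchmark <- function(geno, expr, y,
                          arms = c("genotype", "expression", "combined"),
                          folds = 10, trials = 10, seed = 1L,
                          control = mgrf_control(ntrees = 200, max_iters = 2),
                          modules_precomputed = FALSE, plain = FALSE) {
  stopifnot(length(arms) >= 1)
  y <- align_phenotype(geno, y)
  n <- nrow(geno$values)
  splits <- kfold_splits(n, folds = folds, trials = trials, seed = seed)
  res <- array(NA_real_, dim = c(trials, folds, length(arms)),
               dimnames = list(NULL, NULL, arms))

  arm_data <- lapply(setNames(arms, arms), .cv_arm_data, geno = geno, expr = expr)
  pre <- NULL
  if (modules_precomputed && !plain) {
    pre <- lapply(arm_data, function(d) {
      net <- build_network(pairwise_associations(d))
      list(net = net, part = detect_modules(net))
    })
  }

  for (tr in seq_len(trials)) {
    for (fd in seq_len(folds)) {
      test_idx <- splits[[tr]][[fd]]
      train_idx <- setdiff(seq_len(n), test_idx)
      for (a in seq_along(arms)) {
        d <- arm_data[[a]]
        d_tr <- subset_dataset(d, samples = train_idx)
        d_te <- subset_dataset(d, samples = test_idx)
        y_tr <- y[train_idx]
        set.seed((seed + tr * 1009L + fd * 101L) %% 2147483647L)
        if (plain) {
          model <- fit_forest(d_tr, y_tr, control = control, plain = TRUE)
        } else if (modules_precomputed) {
          model <- fit_mgrf(d_tr, y_tr, pre[[a]]$part, pre[[a]]$net,
                            control = control)$model
        } else {
          net <- build_network(pairwise_associations(d_tr))
          part <- detect_modules(net)
          model <- fit_mgrf(d_tr, y_tr, part, net, control = control)$model
        }
        res[tr, fd, a] <- rmse(predict(model, d_te), y[test_idx])
      }
    }
  }
  flat <- apply(res, 3, as.numeric)
  summary <- data.frame(arm = arms,
                        mean_rmse = colMeans(flat),
                        sd_rmse = apply(flat, 2, sd))
  tt <- matrix(NA_real_, length(arms), length(arms),
               dimnames = list(arms, arms))
  for (i in seq_along(arms)) for (j in seq_along(arms)) {
    if (i != j) tt[i, j] <- paired_one_tail_t(flat[, i], flat[, j])
  }
  structure(list(rmse = res, summary = summary, t_tests = tt,
                 folds = splits, seed = seed),
            class = "mgrf_cv")
}

#' @export
print.mgrf_cv <- function(x, ...) {
  cat("mgrf_cv:", dim(x$rmse)[1], "trials x", dim(x$rmse)[2], "folds\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
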