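#' Forest hyperparameters
#'
#' @param ntrees number of trees (default 1000; large ensembles stabilize
#'   importance estimates).
#' @param k_mod module-level mtry: number of candidate modules per node, or
#'   `"auto"` for `max(1, ceiling(n_modules / 3))` (multiple latent factors
#'   are assumed to contribute to the trait).
#' @param mtry candidate variables per node in conventional mode
#'   (`plain = TRUE` in [fit_forest()]), or `"auto"` for
#'   `max(1, ceiling(n_variables / 3))` — the standard regression choice.
#' @param nodesize minimum splittable node size (default 3, suited to the
#'   small cohorts typical of F2 crosses).
#' @param max_iters maximum forest-fitting iterations of [fit_mgrf()]
#'   (iteration 1 is unweighted; default 10).
#' @param vi_tol convergence tolerance: L1 distance between successive VI
#'   vectors normalized to proportions (default 0.01 = 1% total change).
#' @param seed optional integer seed applied by [fit_mgrf()].
#' @param trace_candidates record the candidate-module set of every node
#'   (audit/debug; memory-heavy for large forests).
#' @return a `mgrf_control` list.
#' @export
mgrf_control <- function(ntrees = 1000, k_mod = "auto", mtry = "auto",
                         nodesize = 3, max_iters = 10, vi_tol = 0.01,
                         seed = NULL, trace_candidates = FALSE) {
  stopifnot(ntrees >= 1, nodesize >= 1, max_iters >= 1, vi_tol >= 0)
  structure(list(ntrees = as.integer(ntrees), k_mod = k_mod, mtry = mtry,
                 nodesize = as.integer(nodesize),
                 max_iters = as.integer(max_iters), vi_tol = vi_tol,
                 seed = seed, trace_candidates = isTRUE(trace_candidates)),
            class = "mgrf_control")
}

#' Two-stage weighted subset sampling
#'
#' Stage 1 draws `n1` items without replacement, each successive draw with
#' probability proportional to the remaining weights (uniform when weights
#' are equal or all zero); stage 2 draws `n2` uniformly from the stage-1
#' survivors. This mixes weighted and uniform sampling so that informative
#' items are favoured without ever fixing the candidate set.
#'
#' @param items vector of items.
#' @param weights non-negative numeric weights, same length.
#' @param n1,n2 stage sizes, `n2 <= n1 <= length(items)`.
#' @return `n2` sampled items.
#' @export
weighted_subset_sample <- function(items, weights, n1, n2) {
  k <- length(items)
  stopifnot(length(weights) == k, all(weights >= 0), n2 <= n1, n1 <= k, n2 >= 1)
  w <- as.numeric(weights)
  avail <- seq_len(k)
  s1 <- integer(n1)
  for (d in seq_len(n1)) {
    pos <- if (sum(w[avail]) <= 0) sample.int(length(avail), 1)
           else sample.int(length(avail), 1, prob = w[avail])
    s1[d] <- avail[pos]
    avail <- avail[-pos]
  }
  items[s1[sample.int(n1, n2)]]
}

# epsilon floor so zero-importance items keep non-zero selection probability
.eps_weights <- function(w) {
  w + 1e-6 * max(max(w), 1)
}

#' Draw candidate split variables by module-guided two-stage sampling
#'
#' Samples `k_mod` distinct modules ([weighted_subset_sample()] with
#' `n1 = max(ceiling(n_modules/3), k_mod)`, `n2 = k_mod`, weighted by module
#' importance), then exactly one representative variable per chosen module
#' (`n1 = ceiling(module_size/3)`, `n2 = 1`, weighted by variable
#' importance). Returns `k_mod` variables from pairwise-distinct modules.
#'
#' @param part a `module_partition`.
#' @param mod_weights named module-importance weights (module id as name),
#'   or `NULL` for uniform.
#' @param var_weights named variable-importance weights, or `NULL` for
#'   uniform.
#' @param k_mod number of candidate modules (clamped to the stage-1 size).
#' @return character vector of candidate variable ids.
#' @export
two_stage_candidates <- function(part, mod_weights = NULL, var_weights = NULL,
                                 k_mod) {
  stopifnot(inherits(part, "module_partition"))
  members <- module_members(part)
  M <- length(members)
  stopifnot(k_mod >= 1)
  k2 <- min(k_mod, M)
  n1 <- max(ceiling(M / 3), k2)   # pool must be able to host all candidates
  mw <- if (is.null(mod_weights)) rep(1, M)
        else .eps_weights(as.numeric(mod_weights[names(members)]))
  chosen <- weighted_subset_sample(names(members), mw, n1, k2)
  vapply(chosen, function(mid) {
    mem <- members[[mid]]
    vw <- if (is.null(var_weights)) rep(1, length(mem))
          else .eps_weights(as.numeric(var_weights[mem]))
    weighted_subset_sample(mem, vw, ceiling(length(mem) / 3), 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Best squared-loss split over candidate variables
#'
#' Continuous candidates are scanned at midpoints between consecutive
#' sorted distinct values; categorical candidates order observed levels by
#' mean response and scan level-prefix partitions (exact for squared
#' loss). Returns the candidate and rule maximizing the SSE reduction,
#' with ties broken by (larger reduction, smaller variable index, smaller
#' threshold), or `NULL` when no candidate reduces the SSE.
#'
#' @param d an [omics_dataset()] (or numeric matrix of a node's samples).
#' @param y response vector for the same samples.
#' @param candidates variable ids (or column indices) to evaluate.
#' @return list with `var`, `is_cat`, `threshold` (continuous),
#'   `left_levels` (categorical codes routed left) and `reduction`, or
#'   `NULL`.
#' @export
best_split <- function(d, y, candidates = NULL) {
  if (inherits(d, "omics_dataset")) {
    X <- d$values
    nlev <- ifelse(d$variables$kind == "categorical", d$variables$n_levels, 0L)
  } else {
    X <- as.matrix(d)
    nlev <- rep(0L, ncol(X))
  }
  if (is.null(candidates)) candidates <- seq_len(ncol(X))
  if (is.character(candidates)) candidates <- match(candidates, colnames(X))
  res <- cpp_best_split(X, as.numeric(y), as.integer(nlev),
                        as.integer(candidates))
  if (res$var == 0) return(NULL)
  res$var <- colnames(X)[res$var] %||% res$var
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_k <- function(k, n_items) {
  if (identical(k, "auto")) max(1L, as.integer(ceiling(n_items / 3)))
  else as.integer(k)
}

#' Fit one module-guided (or conventional) regression forest
#'
#' Grows `ntrees` CART-style regression trees on bootstrap samples.
#' Candidate split variables at each node come from module-guided two-stage
#' sampling (or a plain uniform mtry draw when `plain = TRUE`). Continuous
#' splits use midpoints between sorted distinct values; categorical splits
#' order observed levels by mean response, which is exact for squared loss.
#' Categorical levels unseen at a node during training are routed to the
#' right child at prediction time.
#'
#' @param d an [omics_dataset()].
#' @param y phenotype vector aligned to `d` (see [align_phenotype()]).
#' @param part a `module_partition` covering `d`'s variables (not needed
#'   when `plain = TRUE`).
#' @param mod_weights,var_weights named non-negative weights (module ids /
#'   variable ids); `NULL` means uniform sampling. Learned weights get an
#'   epsilon floor so zero-importance variables stay reachable.
#' @param control a [mgrf_control()].
#' @param plain if `TRUE`, ignore modules and sample `mtry` candidates
#'   uniformly (conventional random forest mode).
#' @return an object of class `mgrf_forest`.
#' @export
fit_forest <- function(d, y, part = NULL, mod_weights = NULL,
                       var_weights = NULL, control = mgrf_control(),
                       plain = FALSE) {
  stopifnot(inherits(d, "omics_dataset"))
  X <- d$values
  n <- nrow(X); m <- ncol(X)
  if (!identical(names(y), rownames(X)))
    stop("phenotype not aligned to dataset; use align_phenotype()")
  if (n < 2 * control$nodesize)
    stop("need at least ", 2 * control$nodesize, " samples")
  nlev <- ifelse(d$variables$kind == "categorical", d$variables$n_levels, 0L)

  if (plain) {
    mtry <- .resolve_k(control$mtry, m)
    module_list <- list()
    k_mod <- 0L
    mw <- numeric(0); vw <- rep(1, m)
    weighted <- FALSE
  } else {
    if (is.null(part)) stop("module partition required (or set plain = TRUE)")
    members <- module_members(part)
    if (!all(colnames(X) %in% names(part$assignment)))
      stop("partition does not cover all dataset variables")
    module_list <- lapply(members, function(ids) match(ids, colnames(X)) - 1L)
    M <- length(members)
    k_mod <- max(1L, min(.resolve_k(control$k_mod, M), M))
    weighted <- !(is.null(mod_weights) && is.null(var_weights))
    mw <- if (is.null(mod_weights)) rep(1, M)
          else .eps_weights(as.numeric(mod_weights[names(members)]))
    vw <- if (is.null(var_weights)) rep(1, m)
          else .eps_weights(as.numeric(var_weights[colnames(X)]))
    if (anyNA(mw) || anyNA(vw)) stop("weights must cover all modules/variables")
    mtry <- 0L
  }

  res <- cpp_grow_forest(X, as.numeric(y), as.integer(nlev), module_list,
                         mw, vw, control$ntrees, k_mod, control$nodesize,
                         weighted, if (plain) mtry else 0L,
                         control$trace_candidates)
  structure(list(
    trees = res$trees,
    vi_total = setNames(res$vi_total, colnames(X)),
    variables = d$variables,
    nlev = nlev,
    ntrees = control$ntrees,
    nodesize = control$nodesize,
    k_mod = if (plain) NA_integer_ else k_mod,
    mtry = if (plain) mtry else NA_integer_,
    plain = plain,
    n_samples = n
  ), class = "mgrf_forest")
}

#' @export
print.mgrf_forest <- function(x, ...) {
  cat("mgrf_forest:", x$ntrees, "trees over", length(x$vi_total),
      "variables (", if (x$plain) paste("plain, mtry =", x$mtry)
      else paste("module-guided, k_mod =", x$k_mod), ")\n")
  invisible(x)
}

.model_matrix <- function(model, newdata) {
  X <- if (inherits(newdata, "omics_dataset")) newdata$values else as.matrix(newdata)
  want <- names(model$vi_total)
  missing <- setdiff(want, colnames(X))
  if (length(missing) > 0)
    stop("newdata lacks variables: ", paste(head(missing, 5), collapse = ", "))
  X[, want, drop = FALSE]
}

#' Predict from a fitted forest (mean over tree predictions)
#'
#' @param object an `mgrf_forest`.
#' @param newdata an [omics_dataset()] or numeric matrix containing the
#'   model's variables (categorical ones as integer codes).
#' @param ... unused.
#' @return numeric vector of per-sample predictions.
#' @export
predict.mgrf_forest <- function(object, newdata, ...) {
  X <- .model_matrix(object, newdata)
  if (nrow(X) == 0) return(numeric(0))
  setNames(as.numeric(cpp_predict_forest(object$trees, X)), rownames(X))
}

#' Out-of-bag RMSE of a fitted forest
#'
#' Each training sample is predicted by averaging only the trees whose
#' bootstrap excluded it. Samples never out-of-bag (vanishingly rare for
#' reasonable ensembles) are dropped with a warning.
#'
#' @param model an `mgrf_forest`.
#' @param d the training [omics_dataset()].
#' @param y the aligned training phenotype.
#' @return OOB root-mean-square error.
#' @export
oob_error <- function(model, d, y) {
  X <- .model_matrix(model, d)
  if (!identical(names(y), rownames(X))) stop("phenotype not aligned")
  res <- cpp_oob_predict(model$trees, X)
  keep <- res$n_oob > 0
  if (!all(keep))
    warning(sum(!keep), " sample(s) never out-of-bag; excluded from OOB error")
  rmse(res$pred[keep], as.numeric(y)[keep])
}

#' Impurity-decrease variable importance
#'
#' `VI(v)` is the summed squared-error reduction of all nodes splitting on
#' `v`, across all trees, divided by the number of trees (the regression
#' analog of Gini importance).
#'
#' @param model an `mgrf_forest`.
#' @return named non-negative numeric vector over all model variables.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "mgrf_forest"))
  model$vi_total / model$ntrees
}

#' Module importance: sum of member variable importances
#'
#' @param vi named VI vector (see [variable_importance()]).
#' @param part a `module_partition` covering the VI variables.
#' @return named numeric vector over module ids.
#' @export
module_importance <- function(vi, part) {
  stopifnot(inherits(part, "module_partition"))
  memb <- part$assignment[names(vi)]
  if (anyNA(memb))
    stop("variables not assigned to any module: ",
         paste(head(names(vi)[is.na(memb)], 5), collapse = ", "))
  out <- tapply(vi, memb, sum)
  full <- setNames(numeric(part$n_modules), as.character(seq_len(part$n_modules)))
  full[names(out)] <- out
  full
}

#' Corrected variable importance (cVI)
#'
#' Redistributes importance among correlated variables:
#' `cVI(v) = VI(v) + sum over network neighbours u of v within v's module
#' of c_vu * VI(u)`, with `c_vu` the absolute association carried by the
#' network edge. The sum is unnormalized, so well-connected hub variables
#' of strong modules rank high.
#'
#' @param vi named VI vector.
#' @param part a `module_partition`.
#' @param net the `corr_network` the partition was computed on.
#' @return named cVI vector over the VI variables.
#' @export
corrected_vi <- function(vi, part, net) {
  stopifnot(inherits(part, "module_partition"), inherits(net, "corr_network"))
  memb <- part$assignment
  cvi <- vi
  e <- net$edges
  if (nrow(e) > 0) {
    same <- memb[e$source] == memb[e$target] &
      e$source %in% names(vi) & e$target %in% names(vi)
    e <- e[same, , drop = FALSE]
    if (nrow(e) > 0) {
      add_s <- tapply(e$weight * vi[e$target], e$source, sum)
      add_t <- tapply(e$weight * vi[e$source], e$target, sum)
      cvi[names(add_s)] <- cvi[names(add_s)] + add_s
      cvi[names(add_t)] <- cvi[names(add_t)] + add_t
    }
  }
  cvi
}

.percent <- function(x) {
  s <- sum(x)
  if (s <= 0) return(x * 0)
  100 * x / s
}

#' Fit the full iterated module-guided random forest
#'
#' Iteration 1 grows a forest with uniform module/variable sampling; each
#' later iteration re-fits with module weights set to the previous module
#' importances (MI) and variable weights to the previous raw variable
#' importances (VI; never cVI). Importances are re-estimated each round,
#' not accumulated. Iteration stops when the L1 distance between successive
#' proportion-normalized VI vectors drops below `vi_tol`, or after
#' `max_iters` forests. cVI is computed once, from the final forest.
#'
#' @param d an [omics_dataset()].
#' @param y aligned phenotype vector.
#' @param part a `module_partition` over `d`'s variables.
#' @param net the `corr_network` behind `part` (used for cVI).
#' @param control a [mgrf_control()].
#' @return an object of class `mgrf_fit`: list with `model` (final
#'   `mgrf_forest`), `importance` (list `vi`, `mi`, `cvi` plus
#'   `*_percent`), `trace` (per-iteration data.frame) and `iterations`.
#' @export
fit_mgrf <- function(d, y, part, net, control = mgrf_control()) {
  if (!is.null(control$seed)) set.seed(control$seed)
  vi_prev <- NULL
  mod_w <- NULL; var_w <- NULL
  trace <- data.frame(iteration = integer(), vi_change = numeric(),
                      oob_rmse = numeric())
  model <- NULL; vi <- NULL; mi <- NULL
  for (it in seq_len(control$max_iters)) {
    model <- fit_forest(d, y, part, mod_weights = mod_w, var_weights = var_w,
                        control = control)
    vi <- variable_importance(model)
    mi <- module_importance(vi, part)
    change <- if (is.null(vi_prev)) NA_real_ else {
      p1 <- if (sum(vi_prev) > 0) vi_prev / sum(vi_prev) else vi_prev
      p2 <- if (sum(vi) > 0) vi / sum(vi) else vi
      sum(abs(p1 - p2))
    }
    trace <- rbind(trace, data.frame(
      iteration = it, vi_change = change,
      oob_rmse = suppressWarnings(oob_error(model, d, y))))
    if (!is.na(change) && change < control$vi_tol) break
    vi_prev <- vi
    mod_w <- mi; var_w <- vi
  }
  cvi <- corrected_vi(vi, part, net)
  structure(list(
    model = model,
    importance = list(vi = vi, mi = mi, cvi = cvi,
                      vi_percent = .percent(vi), mi_percent = .percent(mi),
                      cvi_percent = .percent(cvi)),
    trace = trace,
    iterations = nrow(trace)
  ), class = "mgrf_fit")
}

#' @export
print.mgrf_fit <- function(x, ...) {
  cat("mgrf_fit:", x$iterations, "iteration(s); final OOB RMSE =",
      signif(tail(x$trace$oob_rmse, 1), 4), "\n")
  top <- sort(x$importance$cvi_percent, decreasing = TRUE)
  cat("top cVI (%):",
      paste(names(top)[1:min(5, length(top))],
            signif(top[1:min(5, length(top))], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Write an importance report TSV
#'
#' Columns: `variable_id`, `module_id`, `VI`, `cVI`, `cVI_percent`, sorted
#' by decreasing cVI.
#'
#' @param fit an `mgrf_fit`.
#' @param part the `module_partition` used in the fit.
#' @param path output path.
#' @export
write_importance <- function(fit, part, path) {
  imp <- fit$importance
  df <- data.frame(variable_id = names(imp$vi),
                   module_id = as.integer(part$assignment[names(imp$vi)]),
                   VI = as.numeric(imp$vi),
                   cVI = as.numeric(imp$cvi),
                   cVI_percent = as.numeric(imp$cvi_percent))
  df <- df[order(-df$cVI), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
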