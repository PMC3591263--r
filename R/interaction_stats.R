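#' Per-tree presence sets of split variables
#'
#' A variable is present in a tree iff it is the split variable of at least
#' one internal node of that tree (counted once per tree).
#'
#' @param model an `mgrf_forest`.
#' @return named list mapping variable id to an integer vector of tree
#'   indices; variables never split on are absent.
#' @export
tree_presence <- function(model) {
  stopifnot(inherits(model, "mgrf_forest"))
  ids <- names(model$vi_total)
  pairs <- lapply(seq_along(model$trees), function(t) {
    sv <- model$trees[[t]]$split_vars
    if (length(sv) == 0) return(NULL)
    cbind(sv, t)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(setNames(list(), character(0)))
  out <- split(pairs[, 2], pairs[, 1])
  setNames(out, ids[as.integer(names(out))])
}

#' Right-tail hypergeometric probability
#'
#' Probability that two variables present in `n` and `m` of `N` trees
#' co-occur in at least `k` trees under independence:
#' `p = sum_{j=k}^{min(n,m)} C(n,j) C(N-n, m-j) / C(N,m)`, evaluated in
#' log-space for numerical stability.
#'
#' @param N ensemble size.
#' @param n,m per-variable presence counts.
#' @param k observed co-occurrence count.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_right_tail <- function(N, n, m, k) {
  stopifnot(N >= 0, n >= 0, m >= 0, n <= N, m <= N)
  if (k < max(0, n + m - N) || k > min(n, m))
    stop("k = ", k, " outside feasible range [", max(0, n + m - N), ", ",
         min(n, m), "]")
  if (k == 0) return(1)
  j <- k:min(n, m)
  lp <- lchoose(n, j) + lchoose(N - n, m - j) - lchoose(N, m)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Co-occurrence interaction test over explicit presence sets
#'
#' Core of [test_all_pairs()], exposed so presence sets from any source
#' (e.g. null simulations) can be tested. All pairs of variables present in
#' at least `min_presence` trees are tested with the right-tail
#' hypergeometric test; q-values are BH-adjusted within the tested family;
#' rows are sorted by ascending p.
#'
#' @param presence named list of tree-index vectors (see [tree_presence()]).
#' @param ntrees ensemble size `N`.
#' @param min_presence minimum per-variable presence count (default 5).
#' @param pair_types optional named character vector mapping variable id to
#'   a source tag used to label pairs (e.g. `marker`/`transcript`).
#' @param types optional character vector of pair-type labels to keep.
#' @return data.frame with columns `u`, `v`, `pair_type`, `n`, `m`, `k`,
#'   `N`, `p`, `q`.
#' @export
test_pairs_presence <- function(presence, ntrees, min_presence = 5,
                                pair_types = NULL, types = NULL) {
  counts <- lengths(presence)
  keep <- names(presence)[counts >= min_presence]
  empty <- data.frame(u = character(), v = character(), pair_type = character(),
                      n = integer(), m = integer(), k = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (length(keep) < 2) return(empty)
  keep <- sort(keep)
  # incidence matrix: co-occurrence counts come from one cross-product
  inc <- matrix(0, length(keep), ntrees, dimnames = list(keep, NULL))
  for (id in keep) inc[id, presence[[id]]] <- 1
  K <- tcrossprod(inc)
  idx <- combn(keep, 2)
  u <- idx[1, ]; v <- idx[2, ]
  n <- counts[u]; m <- counts[v]
  k <- K[cbind(u, v)]
  p <- mapply(hypergeom_right_tail, ntrees, n, m, k, USE.NAMES = FALSE)
  pt <- if (is.null(pair_types)) rep("other-other", length(u))
        else mapply(.pair_type, pair_types[u], pair_types[v], USE.NAMES = FALSE)
  out <- data.frame(u = u, v = v, pair_type = pt,
                    n = as.integer(n), m = as.integer(m), k = as.integer(k),
                    N = as.integer(ntrees), p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  if (!is.null(types)) out <- out[out$pair_type %in% types, , drop = FALSE]
  out <- out[order(out$p, out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test all variable pairs of a forest for interaction
#'
#' Counts, for each pair of variables, the trees in which each appears as a
#' split variable (`n`, `m`) and the trees containing both (`k`); under
#' independence `k` is hypergeometric, so a small right-tail p flags pairs
#' co-selected more often than chance — the signature of an interaction
#' exploited by conditional splits. Stable rankings need a large ensemble
#' (6000 trees were used for the mouse-weight analyses); grow a dedicated
#' forest at the converged weights for this test rather than reusing the
#' smaller importance forest.
#'
#' @param model an `mgrf_forest` (typically with a large `ntrees`).
#' @param min_presence minimum per-variable presence count (default 5).
#' @param types optional filter of pair-type labels, e.g.
#'   `"marker-transcript"`.
#' @return ranked data.frame as in [test_pairs_presence()].
#' @export
test_all_pairs <- function(model, min_presence = 5, types = NULL) {
  stopifnot(inherits(model, "mgrf_forest"))
  presence <- tree_presence(model)
  src <- setNames(model$variables$source, model$variables$id)
  test_pairs_presence(presence, length(model$trees),
                      min_presence = min_presence, pair_types = src,
                      types = types)
}

#' Write an interaction table as TSV (sorted by p)
#' @param interactions data.frame from [test_all_pairs()].
#' @param path output path.
#' @param top optionally keep only the `top` most significant rows.
#' @export
write_interactions <- function(interactions, path, top = NULL) {
  if (!is.null(top)) interactions <- head(interactions, top)
  write.table(interactions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
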