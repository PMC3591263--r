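#' Pearson correlation between two continuous variables
#'
#' Thin, validated wrapper used for continuous-continuous association.
#' Constant inputs have no defined correlation and yield 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: association undefined, returning 0")
    return(0)
  }
  cor(x, y)
}

#' Discretize a continuous variable into three bins
#'
#' Bins are `low` (x < mu - delta), `mid` (mu - delta <= x <= mu + delta,
#' boundaries inclusive) and `high` (x > mu + delta), with `mu` the mean and
#' `delta` the sample (n-1) standard deviation. A constant vector is all
#' `mid`.
#'
#' @param x numeric vector, length >= 3.
#' @param codes if `TRUE` return integer codes 0/1/2 instead of labels.
#' @return factor with levels `low`, `mid`, `high`, or integer codes.
#' @export
discretize_three_bins <- function(x, codes = FALSE) {
  stopifnot(length(x) >= 3)
  mu <- mean(x)
  delta <- sd(x)
  code <- integer(length(x)) + 1L
  code[x < mu - delta] <- 0L
  code[x > mu + delta] <- 2L
  if (codes) return(code)
  factor(c("low", "mid", "high")[code + 1L], levels = c("low", "mid", "high"))
}

#' Normalized mutual information between two categorical variables
#'
#' `MI(x, y) / sqrt(H(x) H(y))` with natural-log entropies of the empirical
#' joint distribution; 0 by convention when either marginal entropy is 0.
#'
#' @param x,y vectors of equal length interpretable as factors.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(x, y) {
  stopifnot(length(x) == length(y))
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx <= 0 || hy <= 0) return(0)
  e <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / e[nz]))
  min(1, max(0, mi / sqrt(hx * hy)))
}

#' Association between a continuous and a categorical variable
#'
#' The continuous variable is discretized into three bins
#' ([discretize_three_bins()]) and compared with the categorical one by
#' normalized mutual information.
#'
#' @param x continuous vector.
#' @param g categorical vector (codes or factor) of the same length.
#' @return NMI in `[0, 1]`.
#' @export
mixed_association <- function(x, g) {
  stopifnot(length(x) == length(g))
  normalized_mi(discretize_three_bins(x), g)
}

#' All pairwise associations of a mixed-type dataset
#'
#' Continuous-continuous pairs use Pearson correlation; categorical pairs use
#' normalized mutual information; mixed pairs discretize the continuous
#' variable into three bins first. Constant variables get association 0 to
#' everything.
#'
#' @param d an [omics_dataset()] with >= 2 variables.
#' @return an `association_matrix`: list with the symmetric `values` matrix
#'   and the `variables` metadata (used for per-source-block edge ranking).
#' @export
pairwise_associations <- function(d) {
  stopifnot(inherits(d, "omics_dataset"), ncol(d$values) >= 2)
  vars <- d$variables
  m <- nrow(vars)
  S <- matrix(0, m, m, dimnames = list(vars$id, vars$id))

  is_cont <- vars$kind == "continuous"
  const <- apply(d$values, 2, function(x) max(x) == min(x))

  # continuous block: Pearson
  ic <- which(is_cont & !const)
  if (length(ic) >= 2) S[ic, ic] <- cor(d$values[, ic, drop = FALSE])

  # integer codes for NMI: categorical as-is, continuous via three bins
  code_of <- function(j) {
    if (is_cont[j]) discretize_three_bins(d$values[, j], codes = TRUE)
    else as.integer(d$values[, j])
  }
  icat <- which(!is_cont & !const)
  if (length(icat) >= 1) {
    C <- vapply(icat, code_of, integer(nrow(d$values)))
    nl <- vars$n_levels[icat]
    if (length(icat) >= 2)
      S[icat, icat] <- cpp_nmi_block(C, C, nl, nl, TRUE)
    imix <- which(is_cont & !const)
    if (length(imix) >= 1) {
      X <- vapply(imix, code_of, integer(nrow(d$values)))
      nx <- rep(3L, length(imix))
      S[imix, icat] <- cpp_nmi_block(X, C, nx, nl, FALSE)
      S[icat, imix] <- t(S[imix, icat, drop = FALSE])
    }
  }
  diag(S) <- ifelse(const, 0, 1)
  structure(list(values = S, variables = vars), class = "association_matrix")
}

#' Pair-type label for a pair of source tags
#' @keywords internal
.pair_type <- function(s1, s2) {
  paste(sort(c(s1, s2)), collapse = "-")
}

#' Build the sparse correlation network from an association matrix
#'
#' An edge joins variables i and j (absolute association `s`) iff
#' (1) `s > t1` and one of the two is among the other's top `r1` most
#' associated variables, or (2) `s > t2` and one is among the other's top
#' `r2`. Top-rank lists are computed separately within each pair of source
#' blocks (marker-marker, transcript-transcript, marker-transcript), so the
#' rank criterion is independent of the association scale of each data-type
#' pair. Rank ties break by variable id. Edge weight is `s`.
#'
#' @param A an `association_matrix`.
#' @param r1,t1 rank and threshold of the strict local criterion (defaults 5
#'   and 0.5).
#' @param r2,t2 rank and threshold of the relaxed global criterion (defaults
#'   50 and 0.8).
#' @return a `corr_network`: list with `nodes`, `variables` and an `edges`
#'   data.frame (`source`, `target`, `weight`, `pair_type`).
#' @export
build_network <- function(A, r1 = 5, t1 = 0.5, r2 = 50, t2 = 0.8) {
  stopifnot(inherits(A, "association_matrix"))
  vars <- A$variables
  S <- abs(A$values)
  sources <- unique(vars$source)
  edges <- list()

  for (a in seq_along(sources)) {
    for (b in a:length(sources)) {
      iu <- which(vars$source == sources[a])
      iv <- which(vars$source == sources[b])
      same <- a == b
      B <- S[iu, iv, drop = FALSE]
      if (same) diag(B) <- -Inf   # never rank or link a node to itself
      rr <- .row_ranks(B, vars$id[iv])          # rank of j within i's list
      rc <- t(.row_ranks(t(B), vars$id[iu]))    # rank of i within j's list
      keep <- (B > t1 & (rr <= r1 | rc <= r1)) |
              (B > t2 & (rr <= r2 | rc <= r2))
      if (same) keep[lower.tri(keep, diag = TRUE)] <- FALSE
      w <- which(keep, arr.ind = TRUE)
      if (nrow(w) > 0) {
        u <- vars$id[iu][w[, 1]]
        v <- vars$id[iv][w[, 2]]
        swap <- u > v            # canonical endpoint order: source < target
        edges[[length(edges) + 1L]] <- data.frame(
          source = ifelse(swap, v, u),
          target = ifelse(swap, u, v),
          weight = B[w],
          pair_type = .pair_type(sources[a], sources[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               weight = numeric(), pair_type = character(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = vars$id, variables = vars, edges = edges),
            class = "corr_network")
}

# Per-row descending ranks with ties broken by column id; -Inf entries get
# rank > ncol so they never qualify.
.row_ranks <- function(B, col_ids) {
  cpp_row_ranks(B, order(col_ids))
}

#' @export
print.corr_network <- function(x, ...) {
  cat("corr_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Sparse weighted adjacency matrix of a correlation network
#'
#' @param net a `corr_network`.
#' @return symmetric `dgCMatrix` over `net$nodes`.
#' @export
network_adjacency <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  n <- length(net$nodes)
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = c(net$edges$weight, net$edges$weight),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Write a network as a weighted edge-list TSV
#' @param net a `corr_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
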