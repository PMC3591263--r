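#' Newman weighted modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (s(c)/(2W))^2 ]` where `W` is the total edge
#' weight (each edge counted once), `w_in(c)` the weight of edges inside
#' module `c` and `s(c)` the summed strength of its nodes. An empty network
#' has Q = 0.
#'
#' @param net a `corr_network`.
#' @param part a `module_partition`, or a named membership vector over
#'   `net$nodes`.
#' @return modularity Q.
#' @export
modularity_q <- function(net, part) {
  stopifnot(inherits(net, "corr_network"))
  memb <- if (inherits(part, "module_partition")) part$assignment else part
  if (!all(net$nodes %in% names(memb)))
    stop("partition does not cover all network nodes")
  memb <- memb[net$nodes]
  e <- net$edges
  W <- sum(e$weight)
  if (W <= 0) return(0)
  ms <- memb[e$source]; mt <- memb[e$target]
  w_in <- tapply(e$weight[ms == mt], ms[ms == mt], sum)
  strength <- tapply(c(e$weight, e$weight), memb[c(e$source, e$target)], sum)
  q <- sum(w_in) / W - sum((strength / (2 * W))^2)
  as.numeric(q)
}

.make_partition <- function(nodes, memb_raw, net) {
  # relabel to dense 1..K in order of first appearance along `nodes`
  memb_raw <- memb_raw[nodes]
  ids <- unique(memb_raw)
  memb <- setNames(match(memb_raw, ids), nodes)
  structure(list(
    assignment = memb,
    n_modules = length(ids),
    modularity = modularity_q(net, memb)
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", x$n_modules, "modules over",
      length(x$assignment), "nodes, Q =", signif(x$modularity, 4), "\n")
  invisible(x)
}

#' Member lists of a module partition
#' @param part a `module_partition`.
#' @return list of character vectors, one per module id.
#' @export
module_members <- function(part) {
  stopifnot(inherits(part, "module_partition"))
  split(names(part$assignment), part$assignment)
}

#' Detect network modules by modularity maximization
#'
#' The default `spectral` method recursively bipartitions each connected
#' component using the leading eigenvector of the (generalized) weighted
#' modularity matrix; each accepted split is refined by greedy node-moving
#' sweeps that never decrease Q, and recursion stops when no split increases
#' Q — the module count emerges automatically. The `greedy` method is a
#' fast agglomerative fallback ([igraph::cluster_fast_greedy()]). Isolated
#' nodes always form singleton modules; modules never span disconnected
#' components.
#'
#' @param net a `corr_network`.
#' @param method `"spectral"` (default) or `"greedy"`.
#' @return a `module_partition` with elements `assignment` (named dense
#'   integer vector), `n_modules` and `modularity`.
#' @export
detect_modules <- function(net, method = c("spectral", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "corr_network"), length(net$nodes) > 0)
  A <- network_adjacency(net)
  n <- length(net$nodes)

  if (method == "greedy") {
    if (nrow(net$edges) == 0) {
      memb_raw <- setNames(seq_len(n), net$nodes)
    } else {
      g <- igraph::graph_from_data_frame(net$edges[, c("source", "target", "weight")],
                                         directed = FALSE,
                                         vertices = data.frame(name = net$nodes))
      cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
      memb_raw <- setNames(igraph::membership(cl), net$nodes)
    }
    return(.make_partition(net$nodes, memb_raw, net))
  }

  k <- Matrix::rowSums(A)            # node strengths
  W <- sum(k) / 2
  memb_raw <- setNames(integer(n), net$nodes)

  # connected components (never split across them)
  comp <- .components(net)
  next_id <- 0L
  for (cidx in split(seq_len(n), comp)) {
    groups <- .split_recursive(A, k, W, cidx)
    for (g in groups) {
      next_id <- next_id + 1L
      memb_raw[g] <- next_id
    }
  }
  .make_partition(net$nodes, memb_raw, net)
}

# connected components of the network, as integer labels over net$nodes
.components <- function(net) {
  n <- length(net$nodes)
  if (nrow(net$edges) == 0) return(seq_len(n))
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  unname(igraph::components(g)$membership[net$nodes])
}

# Recursive spectral bipartition of node set `idx` (indices into A).
# Returns a list of index vectors (final modules).
.split_recursive <- function(A, k, W, idx) {
  if (length(idx) < 2 || W <= 0) return(list(idx))
  side <- .leading_split(A, k, W, idx)
  if (is.null(side)) return(list(idx))
  side <- .refine_split(A, k, W, idx, side)
  g1 <- idx[side]; g2 <- idx[!side]
  if (length(g1) == 0 || length(g2) == 0) return(list(idx))
  if (.delta_q_split(A, k, W, g1, g2) <= 1e-10) return(list(idx))
  c(.split_recursive(A, k, W, g1), .split_recursive(A, k, W, g2))
}

# Q gain of cutting group (g1 u g2) into g1 | g2, rest of partition fixed.
.delta_q_split <- function(A, k, W, g1, g2) {
  win <- function(g) sum(A[g, g, drop = FALSE]) / 2
  sg <- function(g) sum(k[g])
  (win(g1) + win(g2) - win(c(g1, g2))) / W -
    ((sg(g1) / (2 * W))^2 + (sg(g2) / (2 * W))^2 - (sg(c(g1, g2)) / (2 * W))^2)
}

# Leading eigenvector of the generalized modularity matrix restricted to
# idx; returns logical side vector (TRUE = positive group), or NULL when the
# leading eigenvalue is non-positive (indivisible group). Deterministic:
# dense symmetric eigen for moderate groups, shifted power iteration above.
.leading_split <- function(A, k, W, idx, dense_limit = 400L) {
  ng <- length(idx)
  kg <- k[idx]
  if (ng <= dense_limit) {
    B <- as.matrix(A[idx, idx, drop = FALSE]) - outer(kg, kg) / (2 * W)
    diag(B) <- diag(B) - rowSums(B)
    ev <- eigen(B, symmetric = TRUE)
    lambda <- ev$values[1]
    v <- ev$vectors[, 1]
  } else {
    Ag <- A[idx, idx, drop = FALSE]
    d <- Matrix::rowSums(Ag) - kg * sum(kg) / (2 * W)  # row sums of B_g
    shift <- max(Matrix::rowSums(abs(Ag)) + abs(kg) * sum(abs(kg)) / (2 * W) + abs(d))
    Bx <- function(x) {
      as.numeric(Ag %*% x) - kg * sum(kg * x) / (2 * W) - d * x
    }
    x <- sin(seq_len(ng))
    x <- x / sqrt(sum(x^2))
    lambda <- 0
    for (it in seq_len(2000L)) {
      y <- Bx(x) + shift * x
      ny <- sqrt(sum(y^2))
      if (ny == 0) break
      y <- y / ny
      if (sum(abs(y - x)) < 1e-12) { x <- y; break }
      x <- y
    }
    v <- x
    lambda <- sum(v * Bx(v))
  }
  if (lambda <= 1e-9) return(NULL)
  # deterministic sign: largest-magnitude component positive
  if (v[which.max(abs(v))] < 0) v <- -v
  side <- v > 0 | abs(v) < 1e-12   # ties to the positive group
  if (all(side) || !any(side)) return(NULL)
  side
}

# Greedy node-moving sweeps on a bipartition of idx; never decreases Q.
.refine_split <- function(A, k, W, idx, side, max_sweeps = 100L) {
  ng <- length(idx)
  Ag <- as.matrix(A[idx, idx, drop = FALSE])
  kg <- k[idx]
  s1 <- sum(kg[side]); s2 <- sum(kg[!side])
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(ng)) {
      in1 <- side[i]
      a_own <- sum(Ag[i, side == in1]) - Ag[i, i]
      a_oth <- sum(Ag[i, side != in1])
      s_own <- if (in1) s1 else s2
      s_oth <- if (in1) s2 else s1
      if ((in1 && sum(side) == 1) || (!in1 && sum(!side) == 1)) next
      dq <- (a_oth - a_own) / W -
        (((s_own - kg[i])^2 + (s_oth + kg[i])^2 - s_own^2 - s_oth^2) / (4 * W^2))
      if (dq > 1e-12) {
        side[i] <- !in1
        if (in1) { s1 <- s1 - kg[i]; s2 <- s2 + kg[i] }
        else     { s2 <- s2 - kg[i]; s1 <- s1 + kg[i] }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  side
}

#' Write a module partition as TSV (`variable_id`, `module_id`)
#' @param part a `module_partition`.
#' @param path output path.
#' @export
write_modules <- function(part, path) {
  df <- data.frame(variable_id = names(part$assignment),
                   module_id = as.integer(part$assignment))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Singleton partition (one module per variable)
#'
#' Useful for running the forest in conventional-RF equivalence mode, where
#' module guidance degenerates to plain mtry sampling.
#'
#' @param ids variable ids.
#' @param net optional `corr_network` used to score modularity (defaults to
#'   an edgeless network over `ids`).
#' @return a `module_partition`.
#' @export
singleton_partition <- function(ids, net = NULL) {
  if (is.null(net)) {
    net <- structure(list(
      nodes = ids,
      variables = data.frame(id = ids, stringsAsFactors = FALSE),
      edges = data.frame(source = character(), target = character(),
                         weight = numeric(), pair_type = character())),
      class = "corr_network")
  }
  .make_partition(ids, setNames(seq_along(ids), ids), net)
}
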