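# small in-code fixtures shared across test files

tiny_continuous <- function(n = 6, m = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("x%02d", 1:m)))
  omics_dataset(v, kind = "continuous", source = "other")
}

tiny_markers <- function(n = 6, m = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("p%02d", 1:m)))
  omics_dataset(v, kind = "categorical", source = "marker")
}

# hand-built correlation network over explicit edges
manual_network <- function(ids, edges, source = "other") {
  ed <- if (is.null(edges) || nrow(edges) == 0) {
    data.frame(source = character(), target = character(), weight = numeric(),
               pair_type = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(source = as.character(edges[[1]]), target = as.character(edges[[2]]),
               weight = as.numeric(edges[[3]]), pair_type = "other-other",
               stringsAsFactors = FALSE)
  }
  structure(list(
    nodes = ids,
    variables = data.frame(id = ids, kind = "continuous", source = source,
                           n_levels = NA_integer_, chromosome = NA_character_,
                           position_mb = NA_real_, stringsAsFactors = FALSE),
    edges = ed), class = "corr_network")
}

manual_partition <- function(net, memb) {
  ids <- unique(memb)
  assignment <- stats::setNames(match(memb, ids), names(memb))
  structure(list(assignment = assignment, n_modules = length(ids),
                 modularity = modularity_q(net, assignment)),
            class = "module_partition")
}

# symmetric association matrix from a plain matrix
manual_assoc <- function(S, source = "other") {
  ids <- colnames(S)
  structure(list(
    values = S,
    variables = data.frame(id = ids, kind = "continuous", source = source,
                           n_levels = NA_integer_, chromosome = NA_character_,
                           position_mb = NA_real_, stringsAsFactors = FALSE)),
    class = "association_matrix")
}

# independent re-check of the two edge criteria, written as a direct
# transcription (per source-block ranks, OR over directions)
recheck_edge <- function(S, sources, i, j, r1 = 5, t1 = 0.5, r2 = 50, t2 = 0.8) {
  s <- abs(S[i, j])
  ids <- colnames(S)
  peers_i <- setdiff(which(sources == sources[j]), i)  # i ranks within j's block
  peers_j <- setdiff(which(sources == sources[i]), j)
  rank_of <- function(center, peers, target) {
    vals <- abs(S[center, peers])
    ord <- peers[order(-vals, ids[peers])]
    match(target, ord)
  }
  ri <- rank_of(i, peers_i, j)
  rj <- rank_of(j, peers_j, i)
  (s > t1 && (ri <= r1 || rj <= r1)) || (s > t2 && (ri <= r2 || rj <= r2))
}
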