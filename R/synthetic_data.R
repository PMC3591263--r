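#' Specification of a synthetic F2 genotype/expression/phenotype study
#'
#' Describes a scaled-down emulation of an F2 intercross "genetics of gene
#' expression" study: chromosome-linked markers with linkage disequilibrium,
#' expression organized into correlated modules partly driven by eQTL
#' markers, and a phenotype depending on a small subset of markers and genes
#' plus pairwise interactions plus Gaussian noise.
#'
#' Defaults are a desk-scale analog of a mouse F2 cross: 150 samples, 19
#' autosomes with 10 markers each at recombination fraction 0.1, 60
#' expression modules of 10 genes with within-module correlation 0.7, a
#' third of modules driven by an eQTL (40% of module-factor variance), and
#' a body-weight-like phenotype (grams) with additive marker and transcript
#' effects and two pairwise interactions.
#'
#' @param n_samples number of F2 individuals.
#' @param chromosomes integer vector: markers per chromosome.
#' @param recomb_fraction recombination fraction between adjacent markers
#'   (`[0, 0.5]`; 0.5 = free recombination).
#' @param n_modules,genes_per_module expression module layout.
#' @param rho target within-module gene-gene Pearson correlation (`[0, 1)`).
#' @param eqtl data.frame(`marker`, `module`, `effect`) where `effect` is
#'   the fraction of module-factor variance explained by the marker, or
#'   `NULL` for the default layout (every third module, effect 0.4).
#' @param additive data.frame(`variable`, `beta`) of additive phenotype
#'   terms (variables are centered), or `NULL` for defaults.
#' @param interactions data.frame(`var1`, `var2`, `gamma`) of product
#'   terms over centered variables, or `NULL` for defaults.
#' @param sigma phenotype noise standard deviation (grams).
#' @param intercept phenotype mean (grams).
#' @param seed integer seed making all generators reproducible.
#' @return a `f2_sim_spec` list.
#' @export
f2_sim_spec <- function(n_samples = 150,
                        chromosomes = rep(10L, 19),
                        recomb_fraction = 0.1,
                        n_modules = 60, genes_per_module = 10,
                        rho = 0.7,
                        eqtl = NULL,
                        additive = NULL,
                        interactions = NULL,
                        sigma = 3.5,
                        intercept = 35,
                        seed = 1L) {
  stopifnot(recomb_fraction >= 0, recomb_fraction <= 0.5,
            rho >= 0, rho < 1, sigma >= 0)
  marker_ids <- unlist(lapply(seq_along(chromosomes), function(c) {
    sprintf("c%02dm%02d", c, seq_len(chromosomes[c]))
  }))
  gene_ids <- unlist(lapply(seq_len(n_modules), function(k) {
    sprintf("g_m%02d_%02d", k, seq_len(genes_per_module))
  }))
  if (is.null(eqtl)) {
    mods <- seq(1, n_modules, by = 3)
    eqtl <- data.frame(
      marker = marker_ids[(seq_along(mods) * 7L) %% length(marker_ids) + 1L],
      module = mods, effect = 0.4, stringsAsFactors = FALSE)
    # one trait marker also drives a trait gene module: genotype effects
    # partially mediated by expression, as in eQTL studies
    if (n_modules >= 2 && length(chromosomes) >= 2) {
      bridge <- sprintf("c%02dm%02d", min(5L, length(chromosomes)),
                        pmin(5L, chromosomes[min(5L, length(chromosomes))]))
      eqtl <- rbind(eqtl[eqtl$module != 2, ],
                    data.frame(marker = bridge, module = 2, effect = 0.4))
    }
  }
  # default phenotype terms scale down with the layout: markers from spread
  # chromosomes, genes from the first modules, one marker x gene and one
  # gene x gene interaction
  C <- length(chromosomes)
  mk <- function(ci) sprintf("c%02dm%02d", ci, pmin(5L, chromosomes[ci]))
  if (is.null(additive)) {
    chr <- unique(pmin(c(1L, 5L, 9L), C))
    gm <- unique(pmin(1:3, n_modules))
    additive <- data.frame(
      variable = c(mk(chr), sprintf("g_m%02d_01", gm)),
      beta = c(rep(2.5, length(chr)), rep(2, length(gm))),
      stringsAsFactors = FALSE)
  }
  if (is.null(interactions)) {
    interactions <- data.frame(
      var1 = c(mk(min(3L, C)), sprintf("g_m%02d_01", min(5L, n_modules))),
      var2 = sprintf("g_m%02d_01", c(min(4L, n_modules), min(6L, n_modules))),
      gamma = c(2, 2), stringsAsFactors = FALSE)
    interactions <- interactions[interactions$var1 != interactions$var2, ,
                                 drop = FALSE]
  }
  structure(list(n_samples = as.integer(n_samples),
                 chromosomes = as.integer(chromosomes),
                 recomb_fraction = recomb_fraction,
                 n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 rho = rho, eqtl = eqtl, additive = additive,
                 interactions = interactions, sigma = sigma,
                 intercept = intercept, seed = as.integer(seed),
                 marker_ids = marker_ids, gene_ids = gene_ids),
            class = "f2_sim_spec")
}

.sample_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Simulate F2 intercross genotypes
#'
#' Each individual inherits two gametes per chromosome, each simulated as a
#' Markov chain along the marker order with crossover probability
#' `recomb_fraction` between adjacent markers; the genotype code is the
#' allele dosage 0/1/2 (expected 1:2:1 in an F2).
#'
#' @param spec a [f2_sim_spec()].
#' @return an [omics_dataset()] of categorical markers (source `marker`),
#'   with chromosome/position metadata (adjacent markers 1 map unit apart).
#' @export
simulate_f2_genotypes <- function(spec) {
  stopifnot(inherits(spec, "f2_sim_spec"))
  n <- spec$n_samples
  r <- spec$recomb_fraction
  gamete_chain <- function(len) {
    a <- integer(len)
    a[1] <- runif(1) < 0.5
    if (len > 1) {
      flips <- runif(len - 1) < r
      for (j in 2:len) a[j] <- if (flips[j - 1]) 1L - a[j - 1] else a[j - 1]
    }
    a
  }
  cols <- list()
  chrom <- character(0); pos <- numeric(0)
  for (c in seq_along(spec$chromosomes)) {
    len <- spec$chromosomes[c]
    G <- matrix(0L, n, len)
    for (i in seq_len(n)) G[i, ] <- gamete_chain(len) + gamete_chain(len)
    cols[[c]] <- G
    chrom <- c(chrom, rep(sprintf("chr%d", c), len))
    pos <- c(pos, seq_len(len))
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(.sample_ids(n), spec$marker_ids)
  omics_dataset(values, kind = "categorical", source = "marker",
                chromosome = chrom, position_mb = pos)
}

#' Simulate module-structured expression with eQTL drivers
#'
#' Each module has a latent factor with unit variance; for eQTL-driven
#' modules a fraction `effect` of that variance comes from the standardized
#' genotype code of the linked marker. Each gene is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise`, so the within-module
#' gene-gene correlation is `rho` in expectation and between-module
#' correlation is 0.
#'
#' @param genotypes marker [omics_dataset()] from [simulate_f2_genotypes()].
#' @param spec the [f2_sim_spec()].
#' @return an [omics_dataset()] of continuous transcripts (source
#'   `transcript`).
#' @export
simulate_expression <- function(genotypes, spec) {
  stopifnot(inherits(genotypes, "omics_dataset"), inherits(spec, "f2_sim_spec"))
  n <- nrow(genotypes$values)
  cols <- matrix(0, n, spec$n_modules * spec$genes_per_module)
  for (k in seq_len(spec$n_modules)) {
    f <- rnorm(n)
    hit <- spec$eqtl[spec$eqtl$module == k, , drop = FALSE]
    if (nrow(hit) == 1 && hit$effect > 0) {
      g <- genotypes$values[, hit$marker]
      z <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g * 0
      f <- sqrt(hit$effect) * z + sqrt(1 - hit$effect) * f
    }
    for (j in seq_len(spec$genes_per_module)) {
      cols[, (k - 1) * spec$genes_per_module + j] <-
        sqrt(spec$rho) * f + sqrt(1 - spec$rho) * rnorm(n)
    }
  }
  dimnames(cols) <- list(rownames(genotypes$values), spec$gene_ids)
  omics_dataset(cols, kind = "continuous", source = "transcript")
}

#' Simulate the phenotype from genotype and expression data
#'
#' `y = intercept + sum beta * x + sum gamma * x1 * x2 + N(0, sigma^2)`,
#' with every term variable centered at its sample mean (so pure
#' interaction terms have near-zero marginal correlation with y).
#'
#' @param genotypes,expression the simulated datasets.
#' @param spec the [f2_sim_spec()].
#' @return list with `phenotype` (named numeric vector, grams) and `truth`
#'   (list: `relevant` variable ids, `additive`, `interactions`, `sigma`,
#'   `oracle` — the noiseless signal).
#' @export
simulate_phenotype <- function(genotypes, expression, spec) {
  all_vals <- cbind(genotypes$values, expression$values)
  need <- unique(c(spec$additive$variable, spec$interactions$var1,
                   spec$interactions$var2))
  missing <- setdiff(need, colnames(all_vals))
  if (length(missing) > 0)
    stop("phenotype terms reference unknown variables: ",
         paste(missing, collapse = ", "))
  n <- nrow(all_vals)
  centered <- function(id) {
    x <- all_vals[, id]
    x - mean(x)
  }
  signal <- numeric(n)
  for (i in seq_len(nrow(spec$additive)))
    signal <- signal + spec$additive$beta[i] * centered(spec$additive$variable[i])
  for (i in seq_len(nrow(spec$interactions)))
    signal <- signal + spec$interactions$gamma[i] *
      centered(spec$interactions$var1[i]) * centered(spec$interactions$var2[i])
  y <- spec$intercept + signal + rnorm(n, sd = spec$sigma)
  names(y) <- rownames(all_vals)
  list(phenotype = y,
       truth = list(relevant = need, additive = spec$additive,
                    interactions = spec$interactions, sigma = spec$sigma,
                    oracle = spec$intercept + signal))
}

#' Simulate a complete desk-scale F2 study
#'
#' Convenience wrapper: seeds the RNG from the spec and returns genotypes,
#' expression, phenotype and ground truth.
#'
#' @param spec a [f2_sim_spec()] (default: the standard desk-scale layout).
#' @return list `genotypes`, `expression`, `combined`, `phenotype`,
#'   `truth`, `spec`.
#' @export
simulate_bxh_like <- function(spec = f2_sim_spec()) {
  set.seed(spec$seed)
  geno <- simulate_f2_genotypes(spec)
  expr <- simulate_expression(geno, spec)
  ph <- simulate_phenotype(geno, expr, spec)
  list(genotypes = geno, expression = expr,
       combined = merge_datasets(geno, expr),
       phenotype = ph$phenotype, truth = ph$truth, spec = spec)
}

#' Correlated-group importance benchmark
#'
#' Builds the structured importance benchmark: a correlated group `G1` of
#' `g1_size` signal-bearing variables (pairwise correlation `rho`), a second
#' correlated group `G2`, and independent relevant singletons to a total of
#' `n_relevant` relevant variables, plus `n_noise` pure-noise variables.
#' The response is additive over the two group latent factors and the
#' singletons, plus Gaussian noise. Variables are ordered relevant-first,
#' so the first `n_relevant` columns are relevant by construction.
#'
#' @param g1_size cardinality of `G1` (>= 2).
#' @param g2_size cardinality of `G2`.
#' @param n_relevant total relevant variables (default 110).
#' @param n_noise pure-noise variables (default 1000).
#' @param n_samples samples (default 400).
#' @param rho within-group correlation (default 0.9).
#' @param beta_group,beta_single effect sizes of group factors and
#'   singletons.
#' @param sigma noise sd; the default gives an oracle R^2 of about 0.7
#'   under the default effect sizes.
#' @param seed RNG seed.
#' @return list `dataset` ([omics_dataset()]), `truth` (list with
#'   `relevant`, `g1`, `g2`, `oracle`).
#' @export
make_group_benchmark <- function(g1_size = 10, g2_size = 10,
                                 n_relevant = 110, n_noise = 1000,
                                 n_samples = 400, rho = 0.9,
                                 beta_group = 3, beta_single = 1,
                                 sigma = 6.8, seed = 1L) {
  stopifnot(g1_size >= 2, g2_size >= 2, n_relevant >= g1_size + g2_size,
            rho >= 0, rho < 1, sigma >= 0)
  set.seed(seed)
  n <- n_samples
  n_single <- n_relevant - g1_size - g2_size
  f1 <- rnorm(n); f2 <- rnorm(n)
  grp <- function(f, q) {
    vapply(seq_len(q), function(j) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n),
           numeric(n))
  }
  G1 <- grp(f1, g1_size)
  G2 <- grp(f2, g2_size)
  S <- matrix(rnorm(n * n_single), n, n_single)
  Z <- matrix(rnorm(n * n_noise), n, n_noise)
  values <- cbind(G1, G2, S, Z)
  ids <- c(sprintf("G1_%02d", seq_len(g1_size)),
           sprintf("G2_%02d", seq_len(g2_size)),
           sprintf("R%03d", seq_len(n_single)),
           sprintf("N%04d", seq_len(n_noise)))
  dimnames(values) <- list(.sample_ids(n), ids)
  signal <- beta_group * f1 + beta_group * f2 +
    as.numeric(S %*% rep(beta_single, n_single))
  y <- signal + rnorm(n, sd = sigma)
  names(y) <- rownames(values)
  d <- omics_dataset(values, kind = "continuous", source = "other")
  list(dataset = d, phenotype = y,
       truth = list(relevant = ids[seq_len(n_relevant)],
                    g1 = ids[seq_len(g1_size)],
                    g2 = ids[g1_size + seq_len(g2_size)],
                    oracle = signal))
}

#' Planted-partition (stochastic block model) network
#'
#' Unit-weight edges drawn independently: probability `p_in` within a
#' block, `p_out` between blocks. Used as a ground-truthed fixture for
#' module detection.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities, `p_in > p_out`.
#' @param seed RNG seed.
#' @return list `network` (a `corr_network`) and `labels` (named integer
#'   vector of planted block ids).
#' @export
planted_partition_network <- function(block_sizes, p_in, p_out, seed = 1L) {
  stopifnot(p_in > p_out, p_in <= 1, p_out >= 0)
  set.seed(seed)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  keep <- runif(ncol(pairs)) < prob
  edges <- data.frame(source = ids[pairs[1, keep]],
                      target = ids[pairs[2, keep]],
                      weight = 1, pair_type = "other-other",
                      stringsAsFactors = FALSE)
  net <- structure(list(
    nodes = ids,
    variables = data.frame(id = ids, kind = "continuous", source = "other",
                           n_levels = NA_integer_,
                           chromosome = NA_character_,
                           position_mb = NA_real_, stringsAsFactors = FALSE),
    edges = edges), class = "corr_network")
  list(network = net, labels = setNames(labels, ids))
}
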