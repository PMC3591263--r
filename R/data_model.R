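#' Construct an omics dataset
#'
#' An `omics_dataset` bundles a samples-by-variables numeric matrix with
#' per-variable metadata. Categorical variables (genetic markers) are stored
#' as integer codes `0 .. n_levels - 1`; continuous variables (transcript
#' abundances) as reals. Missing values are rejected: the forest and the
#' association measures assume complete data (see [impute_missing()] for an
#' explicit utility).
#'
#' @param values numeric matrix, samples x variables, with unique non-empty
#'   rownames (sample ids) and colnames (variable ids).
#' @param kind character vector, one of `"categorical"` or `"continuous"` per
#'   column, a single value to recycle, or `"auto"` to infer: integer-valued
#'   columns with at most `max_levels` distinct values are categorical.
#' @param source character vector over `{"marker", "transcript", "other"}`,
#'   recycled. Sources define the blocks within which network edge ranks are
#'   computed.
#' @param chromosome,position_mb optional per-variable genomic location;
#'   `position_mb` may only be given where `chromosome` is.
#' @param max_levels categorical auto-detection threshold (default 10; an F2
#'   intercross has 3 genotype classes).
#' @return an object of class `omics_dataset`: list with elements `values`
#'   (the matrix) and `variables` (data.frame with columns `id`, `kind`,
#'   `source`, `n_levels`, `chromosome`, `position_mb`).
#' @export
omics_dataset <- function(values, kind = "auto", source = "other",
                          chromosome = NULL, position_mb = NULL,
                          max_levels = 10L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("values must have rownames (sample ids) and colnames (variable ids)")
  m <- ncol(values)
  ids <- colnames(values)
  if (anyDuplicated(ids))
    stop("duplicate variable ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  .check_no_missing(values)

  if (identical(kind, "auto")) {
    kind <- vapply(seq_len(m), function(j) {
      x <- values[, j]
      if (all(x == round(x)) && length(unique(x)) <= max_levels)
        "categorical" else "continuous"
    }, character(1))
  } else {
    kind <- rep_len(kind, m)
  }
  if (!all(kind %in% c("categorical", "continuous")))
    stop("kind must be 'categorical' or 'continuous'")
  source <- rep_len(source, m)
  if (!all(source %in% c("marker", "transcript", "other")))
    stop("source must be 'marker', 'transcript' or 'other'")

  n_levels <- rep(NA_integer_, m)
  for (j in which(kind == "categorical")) {
    x <- values[, j]
    if (any(x != round(x)) || any(x < 0))
      stop("categorical variable '", ids[j], "' must hold non-negative integer codes")
    n_levels[j] <- max(2L, as.integer(max(x)) + 1L)
  }

  chromosome <- if (is.null(chromosome)) rep(NA_character_, m) else rep_len(as.character(chromosome), m)
  position_mb <- if (is.null(position_mb)) rep(NA_real_, m) else rep_len(as.numeric(position_mb), m)
  if (any(!is.na(position_mb) & is.na(chromosome)))
    stop("position_mb given without chromosome")

  structure(list(
    values = values,
    variables = data.frame(id = ids, kind = kind, source = source,
                           n_levels = n_levels, chromosome = chromosome,
                           position_mb = position_mb,
                           stringsAsFactors = FALSE)
  ), class = "omics_dataset")
}

.check_no_missing <- function(values) {
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("missing/non-finite cell at sample '", rownames(values)[bad[1, 1]],
         "', variable '", colnames(values)[bad[1, 2]], "'")
  }
  invisible(TRUE)
}

#' @export
print.omics_dataset <- function(x, ...) {
  tab <- table(x$variables$kind)
  cat("omics_dataset:", nrow(x$values), "samples x", ncol(x$values), "variables (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' Subset an omics dataset by samples and/or variables
#'
#' @param x an `omics_dataset`.
#' @param samples,variables index vectors (ids, logical or positions); `NULL`
#'   keeps everything.
#' @return an `omics_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, variables = NULL) {
  stopifnot(inherits(x, "omics_dataset"))
  v <- x$values
  vars <- x$variables
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(variables)) {
    if (is.character(variables)) variables <- match(variables, vars$id)
    v <- v[, variables, drop = FALSE]
    vars <- vars[variables, , drop = FALSE]
  }
  structure(list(values = v, variables = vars), class = "omics_dataset")
}

#' Read a samples-by-variables TSV into an omics dataset
#'
#' Expects a header row (`sample_id` then variable ids) and one row per
#' sample; body cells must be numeric and complete. Variable kinds are
#' inferred unless overridden by `kind_map` or a sidecar metadata table
#' (columns `id`, `kind`, `source`, and optionally `chromosome`,
#' `position_mb`).
#'
#' @param path TSV file path.
#' @param kind_map `"auto"`, a single kind, or a named character vector of
#'   kinds keyed by variable id.
#' @param source default source tag for all columns (overridden by metadata).
#' @param meta optional path of a variable metadata TSV.
#' @param max_levels see [omics_dataset()].
#' @return an `omics_dataset`.
#' @export
read_dataset <- function(path, kind_map = "auto", source = "other",
                         meta = NULL, max_levels = 10L) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a sample-id column plus at least one variable")
  sample_ids <- raw[[1]]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  body <- raw[, -1, drop = FALSE]
  ids <- colnames(body)
  if (anyDuplicated(ids)) stop("duplicate variable ids in ", path)
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, ids))
  bad <- which(is.na(num) | (as.matrix(body) == ""), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or empty cell at sample '", sample_ids[bad[1, 1]],
         "', variable '", ids[bad[1, 2]], "' in ", path)
  rownames(num) <- sample_ids

  kind <- kind_map
  chrom <- pos <- NULL
  if (!is.null(meta)) {
    md <- read.delim(meta, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    i <- match(ids, md$id)
    if (anyNA(i)) stop("metadata missing variables: ",
                       paste(head(ids[is.na(i)], 5), collapse = ", "))
    kind <- md$kind[i]
    if (!is.null(md$source)) source <- md$source[i]
    if (!is.null(md$chromosome)) chrom <- md$chromosome[i]
    if (!is.null(md$position_mb)) pos <- md$position_mb[i]
  } else if (!identical(kind_map, "auto") && !is.null(names(kind_map))) {
    kind <- ifelse(ids %in% names(kind_map), kind_map[ids], "continuous")
  }
  omics_dataset(num, kind = kind, source = source, chromosome = chrom,
                position_mb = pos, max_levels = max_levels)
}

#' Write an omics dataset as TSV (inverse of [read_dataset()])
#'
#' @param x an `omics_dataset`.
#' @param path output TSV path.
#' @param meta optional path for the variable metadata sidecar.
#' @export
write_dataset <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "omics_dataset"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    write.table(x$variables, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge two omics datasets over the same samples
#'
#' Columns of `b` are appended to `a` after reordering `b` to `a`'s sample
#' order; kinds and source tags are preserved. Sample id sets must coincide.
#'
#' @param a,b `omics_dataset` objects with identical sample sets.
#' @return combined `omics_dataset`.
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "omics_dataset"), inherits(b, "omics_dataset"))
  sa <- rownames(a$values); sb <- rownames(b$values)
  if (!setequal(sa, sb)) {
    stop("sample sets differ; only in a: {",
         paste(setdiff(sa, sb), collapse = ", "), "}; only in b: {",
         paste(setdiff(sb, sa), collapse = ", "), "}")
  }
  dup <- intersect(a$variables$id, b$variables$id)
  if (length(dup) > 0)
    stop("variable ids present in both datasets: ", paste(head(dup, 5), collapse = ", "))
  vb <- b$values[sa, , drop = FALSE]
  structure(list(
    values = cbind(a$values, vb),
    variables = rbind(a$variables, b$variables)
  ), class = "omics_dataset")
}

#' Read a phenotype TSV (columns `sample_id`, `value`)
#'
#' @param path TSV path.
#' @return named numeric vector (names are sample ids).
#' @export
read_phenotype <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  y <- as.numeric(df[[2]])
  if (anyNA(y)) stop("non-numeric phenotype value in ", path)
  if (anyDuplicated(df[[1]])) stop("duplicate sample ids in ", path)
  setNames(y, df[[1]])
}

#' Align a phenotype vector to a dataset's sample order
#'
#' @param d an `omics_dataset`.
#' @param y named numeric vector whose names cover `d`'s samples.
#' @return `y` subset and reordered to `d`'s sample order.
#' @export
align_phenotype <- function(d, y) {
  stopifnot(inherits(d, "omics_dataset"))
  s <- rownames(d$values)
  missing <- setdiff(s, names(y))
  if (length(missing) > 0)
    stop("phenotype missing samples: ", paste(head(missing, 5), collapse = ", "))
  y[s]
}

#' Impute missing cells of a numeric matrix (explicit utility)
#'
#' Column means for continuous columns, column modes for categorical ones.
#' Never applied implicitly: [omics_dataset()] rejects missing data.
#'
#' @param values numeric matrix possibly containing `NA`.
#' @param kind per-column kind vector as in [omics_dataset()].
#' @return completed matrix.
#' @export
impute_missing <- function(values, kind) {
  kind <- rep_len(kind, ncol(values))
  for (j in seq_len(ncol(values))) {
    na <- is.na(values[, j])
    if (!any(na)) next
    obs <- values[!na, j]
    if (length(obs) == 0) stop("column ", j, " entirely missing")
    fill <- if (kind[j] == "categorical") {
      as.numeric(names(which.max(table(obs))))
    } else mean(obs)
    values[na, j] <- fill
  }
  values
}
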