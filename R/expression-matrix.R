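#' Construct an expression matrix container
#'
#' The central data container: a genes x samples real matrix of normalized
#' expression values, with unique gene and sample identifiers and a per-gene
#' flag marking regulator (driver) genes, e.g. transcription factors. All
#' discovery and evaluation functions in the package consume this container.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Must carry
#'   unique, non-empty rownames (gene ids) and colnames (sample ids) and
#'   contain only finite values.
#' @param regulator_flags Logical vector of length `nrow(values)` (optionally
#'   named by gene id) marking which genes may serve as regulators. Defaults
#'   to all `FALSE`; use [set_regulators()] to flag by id.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `regulator_flags`.
#' @seealso [read_expression()], [normalize_genes()], [set_regulators()]
#' @export
expression_matrix <- function(values, regulator_flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    camodi_stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    camodi_stop("'values' must have gene ids as rownames and sample ids as colnames")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    camodi_stop("duplicated gene id(s): %s", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    camodi_stop("duplicated sample id(s): %s", paste(unique(dup_s), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    camodi_stop("non-finite value at gene '%s', sample '%s'",
                gene_ids[bad[1]], sample_ids[bad[2]])
  }
  if (is.null(regulator_flags)) regulator_flags <- rep(FALSE, nrow(values))
  if (length(regulator_flags) != nrow(values))
    camodi_stop("'regulator_flags' must have one entry per gene")
  regulator_flags <- as.logical(regulator_flags)
  names(regulator_flags) <- gene_ids
  structure(list(values = values, regulator_flags = regulator_flags),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d regulators flagged)\n",
              nrow(x$values), ncol(x$values), sum(x$regulator_flags)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
regulator_ids <- function(x) names(x$regulator_flags)[x$regulator_flags]

n_genes <- function(x) nrow(x$values)
n_samples <- function(x) ncol(x$values)

#' Flag regulator genes by identifier
#'
#' Ids absent from the matrix are reported and ignored with a warning, so a
#' generic transcription-factor list can be applied to any expression matrix.
#'
#' @param x An `ExpressionMatrix`.
#' @param ids Character vector of gene ids to flag as regulators.
#' @return `x` with `regulator_flags` set for `ids`.
#' @export
set_regulators <- function(x, ids) {
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, gene_ids(x))
  if (length(missing))
    camodi_warn("%d regulator id(s) not in the matrix were ignored: %s",
                length(missing), paste(utils::head(missing, 5), collapse = ", "))
  flags <- rep(FALSE, n_genes(x))
  names(flags) <- gene_ids(x)
  flags[intersect(ids, gene_ids(x))] <- TRUE
  x$regulator_flags <- flags
  x
}

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header row `gene_id<TAB>sample1<TAB>...`, then one gene
#' per row. Duplicate identifiers and non-numeric cells are format errors
#' that name the offending entry.
#'
#' @param path Path to a TSV file.
#' @return An `ExpressionMatrix` (no regulators flagged).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) camodi_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) camodi_stop("expression file '%s' needs a gene id column plus samples", path)
  gids <- df[[1]]
  sids <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(sids),
                 dimnames = list(gids, sids))
  for (j in seq_along(sids)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad))
      camodi_stop("non-numeric cell '%s' at gene '%s', sample '%s'",
                  col[bad[1]], gids[bad[1]], sids[j])
    vals[, j] <- num
  }
  expression_matrix(vals)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(x)), collapse = "\t"), con)
  body <- vapply(seq_len(n_genes(x)), function(i) {
    paste(c(gene_ids(x)[i], fmt_num(x$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a regulator list (one gene id per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of ids.
#' @export
read_regulators <- function(path) {
  if (!file.exists(path)) camodi_stop("file not found: %s", path)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Z-normalize each gene across samples
#'
#' Scales every gene row to mean zero and unit standard deviation (the
#' `m - 1` denominator sample convention). When `scope_samples` is given,
#' the mean and standard deviation are estimated on those samples only but
#' applied to all samples — this supports a train-only normalization variant
#' of the protocol; the default uses all samples.
#'
#' @param x An `ExpressionMatrix`.
#' @param scope_samples Optional character vector of sample ids on which to
#'   estimate the per-gene mean and standard deviation.
#' @return A normalized `ExpressionMatrix`.
#' @export
normalize_genes <- function(x, scope_samples = NULL) {
  v <- x$values
  sub <- if (is.null(scope_samples)) v else v[, scope_samples, drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    camodi_stop("constant gene(s) cannot be normalized: %s",
                paste(utils::head(gene_ids(x)[zero], 5), collapse = ", "))
  x$values <- (v - mu) / sdv
  x
}

#' Build random 70/30 train-test sample splits
#'
#' One "bootstrap" in this protocol is a random partition of the samples
#' into 70% training and 30% testing (not a with-replacement resample).
#' Split `i` is seeded with `base_seed + i`, so the full list is reproducible
#' and splits are mutually independent.
#'
#' @param x An `ExpressionMatrix` (only its sample ids are used).
#' @param n_bootstraps Number of splits to generate.
#' @param base_seed Integer seed offset.
#' @param train_fraction Fraction of samples used for training (default 0.7);
#'   `|train| = round(train_fraction * m)`.
#' @return A list of `BootstrapSplit` objects with elements
#'   `train_sample_ids`, `test_sample_ids`, `seed`, `index`.
#' @export
make_splits <- function(x, n_bootstraps, base_seed, train_fraction = 0.7) {
  m <- n_samples(x)
  if (m < 4) camodi_stop("need at least 4 samples to split, got %d", m)
  if (n_bootstraps < 1) camodi_stop("'n_bootstraps' must be >= 1")
  if (n_bootstraps < 2)
    camodi_warn("consistency evaluation needs at least 2 bootstraps")
  sids <- sample_ids(x)
  n_train <- round(train_fraction * m)
  lapply(seq_len(n_bootstraps), function(i) {
    seed_i <- base_seed + i
    idx <- with_seed(seed_i, sample.int(m, n_train))
    structure(list(train_sample_ids = sids[sort(idx)],
                   test_sample_ids = sids[-sort(idx)],
                   seed = seed_i, index = i),
              class = "BootstrapSplit")
  })
}

#' Select the most variable genes on the training samples
#'
#' Keeps the `max(1, floor(fraction * n_total))` genes with the largest
#' variance computed over the split's training samples only (the test side
#' never informs the filter). Ties at the cutoff are broken by input order.
#'
#' @param x An `ExpressionMatrix`.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @param split A `BootstrapSplit` whose training samples define the variance.
#' @return Character vector of retained gene ids, in matrix order.
#' @export
variance_filter <- function(x, fraction, split) {
  if (!(fraction > 0 && fraction <= 1)) camodi_stop("'fraction' must be in (0, 1]")
  train <- split$train_sample_ids
  if (length(train) == 0) camodi_stop("training sample set is empty")
  v <- apply(x$values[, train, drop = FALSE], 1, stats::var)
  keep_n <- max(1L, floor(fraction * n_genes(x)))
  # order() is stable: among tied variances the gene earlier in the matrix wins
  top <- order(v, decreasing = TRUE)[seq_len(keep_n)]
  gene_ids(x)[sort(top)]
}

#' Restrict an expression matrix to a sample subset
#'
#' @param x An `ExpressionMatrix`.
#' @param ids Sample ids to keep (order preserved as given).
#' @return An `ExpressionMatrix` over the selected samples.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing))
    camodi_stop("unknown sample id(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  expression_matrix(x$values[, ids, drop = FALSE], x$regulator_flags)
}

#' Restrict an expression matrix to a gene subset
#'
#' @param x An `ExpressionMatrix`.
#' @param ids Gene ids to keep (order preserved as given).
#' @return An `ExpressionMatrix` over the selected genes.
#' @export
subset_genes <- function(x, ids) {
  missing <- setdiff(ids, gene_ids(x))
  if (length(missing))
    camodi_stop("unknown gene id(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  expression_matrix(x$values[ids, , drop = FALSE], x$regulator_flags[ids])
}
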