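#' Construct a module
#'
#' A module `M = {G, R}` couples a set of member genes `G` with a set of
#' regulators `R` and one shared coefficient vector: every gene in `G` is
#' approximated by the same weighted sum of the regulators' expression.
#'
#' @param module_id Identifier.
#' @param genes Character vector of member gene ids (non-empty, unique).
#' @param coefficients Named numeric vector of regulator coefficients; the
#'   regulator set `R` is the names with non-zero coefficient (zeros are
#'   dropped).
#' @param cv_r2 Mean held-out R-squared from gene-fold cross-validation.
#' @param r2_train,r2_test R-squared of the module on training / test samples.
#' @param adj_r2_test Adjusted R-squared on test samples.
#' @return An object of class `Module`.
#' @export
new_module <- function(module_id, genes, coefficients,
                       cv_r2 = NA_real_, r2_train = NA_real_,
                       r2_test = NA_real_, adj_r2_test = NA_real_) {
  genes <- as.character(genes)
  if (length(genes) == 0) camodi_stop("module '%s' has no genes", module_id)
  if (anyDuplicated(genes)) camodi_stop("module '%s' has duplicated genes", module_id)
  if (is.null(names(coefficients)) && length(coefficients) > 0)
    camodi_stop("'coefficients' must be named by regulator id")
  coefficients <- coefficients[coefficients != 0]
  structure(list(module_id = as.character(module_id), genes = genes,
                 regulators = names(coefficients),
                 coefficients = coefficients,
                 cv_r2 = cv_r2, r2_train = r2_train,
                 r2_test = r2_test, adj_r2_test = adj_r2_test),
            class = "Module")
}

#' @export
print.Module <- function(x, ...) {
  cat(sprintf("Module %s: %d genes, %d regulators (cv_r2 = %.3f, adj_r2_test = %.3f)\n",
              x$module_id, length(x$genes), length(x$regulators),
              x$cv_r2, x$adj_r2_test))
  invisible(x)
}

#' Predict module-gene expression from regulator expression
#'
#' The module model is a single shared linear predictor: for sample k,
#' `s_hat(k) = sum_j alpha_j s_j(k)` over the module's regulators, and this
#' one value predicts every member gene.
#'
#' @param module A `Module`.
#' @param samples Either an `ExpressionMatrix` or a numeric matrix with
#'   regulator rows (rownames = regulator ids) over the samples to predict.
#' @return Numeric vector, one predicted value per sample.
#' @export
predict_module <- function(module, samples) {
  mat <- if (inherits(samples, "ExpressionMatrix")) samples$values else samples
  if (length(module$regulators) == 0)
    return(stats::setNames(numeric(ncol(mat)), colnames(mat)))
  missing <- setdiff(module$regulators, rownames(mat))
  if (length(missing))
    camodi_stop("regulator(s) missing from sample data: %s",
                paste(missing, collapse = ", "))
  drop(module$coefficients %*% mat[module$regulators, , drop = FALSE])
}

# Module R-squared of a prediction shared across a block of genes.
# S: genes x samples observed block; pred: one predicted value per sample.
# Numerator: residual energy of the shared prediction over all genes and
# samples. Denominator: total energy of the block around each gene's own
# mean (for z-normalized data this is essentially the block's total energy).
# A perfect shared fit scores 1; values below 0 are reported as computed.
module_block_r2 <- function(S, pred) {
  num <- sum((sweep(S, 2, pred))^2)
  den <- sum((S - rowMeans(S))^2)
  if (den == 0) camodi_stop("degenerate module: member genes have zero variance")
  1 - num / den
}

#' Score a module with R-squared and adjusted R-squared
#'
#' R-squared measures how small the residual energy the shared regulator
#' prediction leaves is, relative to the module genes' total energy:
#' `R2 = 1 - sum_k sum_{i in G} (s_hat(k) - s_i(k))^2 /
#'         sum_k sum_{i in G} (s_i(k) - mean_k s_i(k))^2`,
#' the denominator deviating each gene from its own mean over the scored
#' samples (for z-normalized data, simply the total energy). The adjustment
#' penalizes regulator count relative to the sample count:
#' `adj = R2 - (1 - R2) * |R| / (m - |R| - 1)`. Values are reported as
#' computed (no flooring at zero).
#'
#' @param module A `Module`.
#' @param x An `ExpressionMatrix` containing the module's genes and regulators.
#' @param sample_ids Samples over which to score (e.g. train or test side).
#' @return List with elements `r2` and `adj_r2`.
#' @export
score_module <- function(module, x, sample_ids) {
  xs <- subset_samples(x, sample_ids)
  m <- length(sample_ids)
  nr <- length(module$regulators)
  if (m <= nr + 1)
    camodi_stop("adjusted R-squared undefined: m = %d samples with %d regulators", m, nr)
  missing <- setdiff(module$genes, gene_ids(xs))
  if (length(missing))
    camodi_stop("module gene(s) missing from matrix: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  S <- xs$values[module$genes, , drop = FALSE]
  pred <- predict_module(module, xs)
  r2 <- module_block_r2(S, pred)
  adj <- r2 - (1 - r2) * nr / (m - nr - 1)
  list(r2 = r2, adj_r2 = adj)
}

#' Sparsify a cluster centroid over the regulator basis
#'
#' Same elastic-net path contract as [sparsify_gene()], applied to a cluster
#' centroid (mean expression of the cluster's genes) with the centroid-side
#' sparsity cap `c2`.
#'
#' @param centroid Numeric centroid expression over the training samples.
#' @param regulators Regulator expression matrix (rows = regulators with
#'   rownames, columns = the same samples).
#' @param c2 Maximum number of regulators for the centroid.
#' @param l2_penalty Fixed ridge penalty (>= 0).
#' @param refit Refit active sets by least squares (default `FALSE`).
#' @return List with `reps` (`c2` x n_regulators candidate coefficient
#'   matrix) and `fit_r2` (training R-squared of each candidate).
#' @export
fit_centroid <- function(centroid, regulators, c2, l2_penalty = 0, refit = FALSE) {
  if (!is.matrix(regulators) || is.null(rownames(regulators)))
    camodi_stop("'regulators' must be a matrix with regulator ids as rownames")
  path <- enet_sparse_path(t(regulators), centroid, pmax = c2, l2 = l2_penalty,
                           refit = refit)
  list(reps = path$reps, fit_r2 = path$fit_r2)
}

#' Select centroid sparsity by cross-validation over the cluster's genes
#'
#' The folds partition the cluster's GENES (not the samples). For each fold,
#' the centroid of the training-fold genes is sparsified into candidates of
#' sparsity 1..`c2`; each candidate's shared prediction is scored with the
#' module R-squared over the held-out genes. Candidates are evaluated with
#' their active sets refit by least squares, so the comparison across
#' sparsity levels is not confounded by the path's p-dependent shrinkage
#' (penalized coefficients are shrunk more at the breakpoint of a sparser
#' model, which would bias selection toward dense models). The sparsity with
#' the highest mean held-out R-squared wins (ties break toward the sparser
#' model), and the returned coefficients are taken from the full-cluster
#' centroid path at that sparsity (penalized by default; `refit = TRUE`
#' refits them).
#'
#' @param cluster_genes Numeric matrix of member-gene expression (rows =
#'   genes with rownames, columns = training samples).
#' @param regulators Regulator expression matrix over the same samples.
#' @param c2 Maximum centroid sparsity.
#' @param l2_penalty Fixed ridge penalty.
#' @param n_folds Number of gene folds (default 10; reduced with a warning to
#'   leave-one-out when the cluster is smaller).
#' @param seed Integer seed for the fold shuffle.
#' @param refit Passed to [fit_centroid()].
#' @return List with `p` (chosen sparsity), `coefficients` (named, non-zero
#'   entries only), `cv_r2` (mean held-out R-squared at `p`) and `cv_curve`
#'   (mean held-out R-squared per candidate sparsity).
#' @export
select_sparsity_cv <- function(cluster_genes, regulators, c2, l2_penalty = 0,
                               n_folds = 10, seed = 1, refit = FALSE) {
  ng <- nrow(cluster_genes)
  if (is.null(ng) || ng < 2)
    camodi_stop("cross-validation needs a cluster of at least 2 genes")
  if (n_folds > ng) {
    camodi_warn("reducing %d folds to leave-one-out over %d genes", n_folds, ng)
    n_folds <- ng
  }
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = ng)))
  X <- t(regulators)
  heldout <- matrix(NA_real_, n_folds, c2)
  for (f in seq_len(n_folds)) {
    train_rows <- cluster_genes[folds != f, , drop = FALSE]
    test_rows <- cluster_genes[folds == f, , drop = FALSE]
    centroid <- colMeans(train_rows)
    # refit = TRUE here regardless of the reporting convention: see Details
    cand <- fit_centroid(centroid, regulators, c2 = c2,
                         l2_penalty = l2_penalty, refit = TRUE)
    for (p in seq_len(c2)) {
      pred <- drop(X %*% cand$reps[p, ])
      heldout[f, p] <- module_block_r2(test_rows, pred)
    }
  }
  curve <- colMeans(heldout)
  p_star <- which.max(curve)  # first maximum = smallest p on ties
  full <- fit_centroid(colMeans(cluster_genes), regulators, c2 = c2,
                       l2_penalty = l2_penalty, refit = refit)
  coefs <- full$reps[p_star, ]
  list(p = p_star, coefficients = coefs[coefs != 0],
       cv_r2 = curve[p_star], cv_curve = curve)
}
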