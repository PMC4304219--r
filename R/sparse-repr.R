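# Elastic-net machinery for p-sparse representations.
#
# The model solved is  min ||y - X b||^2 + l2 ||b||^2 + l1 ||b||_1  with the
# ridge penalty l2 held fixed while l1 sweeps from large to small. This is
# realised as a lasso path on the ridge-augmented design [X; sqrt(l2) I],
# which yields the "naive" elastic-net coefficients. The p-sparse vector is
# the path solution at the smallest l1 with exactly p active coefficients,
# i.e. the end of the p-active segment (the LARS-style breakpoint just before
# the (p+1)-th regulator enters). No intercept is fit: all data is
# z-normalized upstream.

enet_sparse_path <- function(X, y, pmax, l2 = 0, refit = FALSE) {
  p_avail <- ncol(X)
  if (pmax < 1) camodi_stop("'pmax' must be >= 1")
  if (pmax >= p_avail)
    camodi_stop("max sparsity %d must be below the number of available regulators (%d)",
                pmax, p_avail)
  if (l2 < 0) camodi_stop("'l2' must be non-negative")
  if (stats::sd(y) == 0) camodi_stop("response has zero variance")

  if (l2 > 0) {
    Xa <- rbind(X, diag(sqrt(l2), p_avail))
    ya <- c(y, numeric(p_avail))
  } else {
    Xa <- X
    ya <- y
  }
  fit <- glmnet::glmnet(Xa, ya, family = "gaussian", alpha = 1,
                        intercept = FALSE, standardize = FALSE,
                        nlambda = 200, lambda.min.ratio = 1e-4,
                        dfmax = pmax + 1L)
  beta <- as.matrix(fit$beta)
  df <- fit$df
  lambda <- fit$lambda

  probe <- function(lam) {
    # refit at a specific l1 strength (short descending sequence keeps
    # glmnet's warm starts happy); returns the coefficient vector at `lam`
    f <- glmnet::glmnet(Xa, ya, family = "gaussian", alpha = 1,
                        intercept = FALSE, standardize = FALSE,
                        lambda = c(lambda[1], lam))
    as.matrix(f$beta)[, 2]
  }

  reps <- matrix(0, pmax, p_avail, dimnames = list(NULL, colnames(X)))
  reached <- logical(pmax)
  for (p in seq_len(pmax)) {
    idx <- which(df == p)
    if (length(idx)) {
      reps[p, ] <- beta[, max(idx)]  # smallest lambda on the p-active segment
      reached[p] <- TRUE
    } else if (any(df > p)) {
      # the discretized path jumped over sparsity p: bisect lambda between
      # the bracketing grid points to land on a p-active solution
      lo <- lambda[min(which(df > p))]          # denser side (smaller lambda)
      hi_idx <- which(df < p)
      hi <- if (length(hi_idx)) lambda[max(hi_idx)] else lambda[1]
      for (it in seq_len(30)) {
        mid <- sqrt(lo * hi)
        b <- probe(mid)
        nz <- sum(b != 0)
        if (nz == p) {
          reps[p, ] <- b
          reached[p] <- TRUE
          break
        } else if (nz > p) lo <- mid else hi <- mid
      }
    }
  }
  # saturated (or unrecoverable) levels inherit the densest level reached
  last <- 0L
  for (p in seq_len(pmax)) {
    if (reached[p]) last <- p
    else if (last > 0L) reps[p, ] <- reps[last, ]
  }
  if (refit) {
    for (p in seq_len(pmax)) {
      act <- which(reps[p, ] != 0)
      if (length(act))
        reps[p, act] <- stats::lsfit(X[, act, drop = FALSE], y,
                                     intercept = FALSE)$coefficients
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  fit_r2 <- apply(reps, 1, function(b) 1 - sum((y - drop(X %*% b))^2) / ss_tot)
  list(reps = reps, fit_r2 = unname(fit_r2), reached = reached)
}

#' Sparsify one gene over the regulator basis
#'
#' Expresses a gene's (training-sample) expression as p-sparse linear
#' combinations of regulator expressions for p = 1..`c1`, via the elastic-net
#' regularization path with a fixed ridge penalty. The p-th representation
#' uses at most p regulators; if the path saturates before reaching p active
#' coefficients, the densest representation reached is carried forward.
#'
#' @param gene Numeric expression vector of the gene over the training
#'   samples (z-normalized).
#' @param regulators Numeric matrix of regulator expression, rows =
#'   regulators (with rownames), columns = the same training samples.
#' @param c1 Maximum number of regulators per representation; must be below
#'   the number of available regulators.
#' @param l2_penalty Fixed ridge penalty of the elastic net (>= 0).
#' @param gene_id Identifier attached to the result.
#' @param refit If `TRUE`, re-estimate the active coefficients by
#'   unpenalized least squares on each active set (default `FALSE`: the
#'   penalized path coefficients are reported).
#' @return A `SparseRepresentation`: list with `gene_id`, `reps` (a
#'   `c1` x n_regulators coefficient matrix, row p holding the p-sparse
#'   vector) and `fit_r2` (training R-squared per sparsity level).
#' @export
sparsify_gene <- function(gene, regulators, c1, l2_penalty = 0,
                          gene_id = "gene", refit = FALSE) {
  if (!is.matrix(regulators) || is.null(rownames(regulators)))
    camodi_stop("'regulators' must be a matrix with regulator ids as rownames")
  if (length(gene) != ncol(regulators))
    camodi_stop("gene vector and regulator matrix disagree on sample count")
  path <- enet_sparse_path(t(regulators), gene, pmax = c1, l2 = l2_penalty,
                           refit = refit)
  structure(list(gene_id = gene_id, reps = path$reps, fit_r2 = path$fit_r2),
            class = "SparseRepresentation")
}

#' Sparsify a set of genes over the regulator basis
#'
#' Applies [sparsify_gene()] to every requested gene of a (training-sample)
#' expression matrix. A gene that is itself a flagged regulator is excluded
#' from its own basis (its self-coefficient is fixed at zero), so the trivial
#' self-fit is impossible. Genes are independent; the result does not depend
#' on evaluation order.
#'
#' @param x An `ExpressionMatrix` restricted to the training samples.
#' @param ids Gene ids to sparsify (default: all genes).
#' @param c1 Maximum regulators per representation.
#' @param l2_penalty Fixed ridge penalty (>= 0).
#' @param refit Passed to [sparsify_gene()].
#' @return Named list of `SparseRepresentation`, one per gene; every `reps`
#'   matrix has the full regulator basis as columns.
#' @export
sparsify_all <- function(x, ids = gene_ids(x), c1, l2_penalty = 0,
                         refit = FALSE) {
  missing <- setdiff(ids, gene_ids(x))
  if (length(missing))
    camodi_stop("unknown gene id(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  regs <- regulator_ids(x)
  if (length(regs) == 0) camodi_stop("no regulators flagged in the matrix")
  reg_mat <- x$values[regs, , drop = FALSE]
  out <- lapply(ids, function(g) {
    basis <- if (g %in% regs) setdiff(regs, g) else regs
    rep_g <- tryCatch(
      sparsify_gene(x$values[g, ], reg_mat[basis, , drop = FALSE],
                    c1 = c1, l2_penalty = l2_penalty, gene_id = g,
                    refit = refit),
      error = function(e) camodi_stop("gene '%s': %s", g, conditionMessage(e)))
    if (length(basis) < length(regs)) {
      # re-embed into the full basis with a structural zero at the gene itself
      full <- matrix(0, nrow(rep_g$reps), length(regs),
                     dimnames = list(NULL, regs))
      full[, basis] <- rep_g$reps
      rep_g$reps <- full
    }
    rep_g
  })
  names(out) <- ids
  out
}

#' Stack p-sparse coefficient vectors into a genes x regulators matrix
#'
#' @param reps Named list of `SparseRepresentation` (from [sparsify_all()]).
#' @param p Sparsity level to extract.
#' @return Numeric matrix, one row per gene, columns = regulator basis.
#' @export
sparse_matrix_at <- function(reps, p) {
  stopifnot(length(reps) > 0)
  basis <- colnames(reps[[1]]$reps)
  out <- t(vapply(reps, function(r) {
    if (p > nrow(r$reps)) camodi_stop("sparsity %d exceeds the fitted path", p)
    r$reps[p, basis]
  }, numeric(length(basis))))
  rownames(out) <- names(reps)
  colnames(out) <- basis
  out
}
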