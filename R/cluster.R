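# K-means on sparse coefficient vectors (Lloyd iterations, k-means++ seeding).
#
# Implemented in-package rather than via stats::kmeans so that (i) seeding is
# k-means++ and fully determined by the supplied seed, (ii) a cluster that
# empties mid-iteration is re-seeded at the point farthest from its assigned
# centroid (keeping K stable), and (iii) the objective history is available
# for invariant checks.

squared_dist <- function(X, C) {
  # n x k matrix of squared Euclidean distances
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- squared_dist(X, X[centers[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, squared_dist(X, X[centers[j + 1], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

lloyd_kmeans <- function(X, k, max_iter = 300, tol = 1e-6) {
  n <- nrow(X)
  C <- kmeanspp_init(X, k)
  labels <- rep(0L, n)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- squared_dist(X, C)
    new_labels <- max.col(-D, ties.method = "first")
    objective <- c(objective, sum(D[cbind(seq_len(n), new_labels)]))
    moved <- 0
    for (c in seq_len(k)) {
      members <- which(new_labels == c)
      if (length(members) == 0) {
        # re-seed an emptied cluster at the point farthest from its centroid
        dist_own <- D[cbind(seq_len(n), new_labels)]
        far <- which.max(dist_own)
        C[c, ] <- X[far, ]
        new_labels[far] <- c
        moved <- Inf
      } else {
        newc <- colMeans(X[members, , drop = FALSE])
        moved <- max(moved, max(abs(newc - C[c, ])))
        C[c, ] <- newc
      }
    }
    converged <- identical(new_labels, labels) || moved < tol
    labels <- new_labels
    if (converged) break
  }
  list(labels = labels, centers = C, objective = objective)
}

#' Cluster genes by their sparse coefficient representations
#'
#' Standard K-means (Euclidean distance, Lloyd iterations with k-means++
#' seeding) applied to the S1-sparse coefficient vectors of the genes: two
#' genes cluster together when the same few regulators, with similar weights,
#' describe them. Deterministic given `seed`. If fewer distinct vectors than
#' `k` exist, fewer clusters are returned with a warning.
#'
#' @param reps Either a genes x regulators numeric matrix of coefficient
#'   vectors (rownames = gene ids; see [sparse_matrix_at()]) or a named list
#'   of equal-length numeric vectors.
#' @param k Number of clusters requested.
#' @param seed Integer seed controlling initialization.
#' @param max_iter,tol Lloyd iteration controls.
#' @return A `ClusterAssignment`: list with `labels` (named integer vector,
#'   gene -> cluster in 1..k_effective), `centroids_sparse` (k_effective x
#'   regulators matrix of mean member coefficient vectors),
#'   `centroids_expression` (`NULL` until [attach_expression_centroids()]),
#'   and `objective` (within-cluster sum of squares per Lloyd pass).
#' @export
cluster_sparse <- function(reps, k, seed, max_iter = 300, tol = 1e-6) {
  if (is.list(reps) && !is.matrix(reps))
    reps <- do.call(rbind, reps)
  if (is.null(rownames(reps))) camodi_stop("'reps' must carry gene ids as rownames")
  if (k < 1) camodi_stop("'k' must be >= 1")
  n <- nrow(reps)
  if (k > n) camodi_stop("'k' (%d) exceeds the number of genes (%d)", k, n)
  n_distinct <- nrow(unique(reps))
  k_eff <- k
  if (n_distinct < k) {
    camodi_warn("only %d distinct representations; returning %d clusters instead of %d",
                n_distinct, n_distinct, k)
    k_eff <- n_distinct
  }
  km <- with_seed(seed, lloyd_kmeans(reps, k_eff, max_iter = max_iter, tol = tol))
  labels <- km$labels
  # drop any residual empty labels and renumber compactly
  used <- sort(unique(labels))
  relabel <- match(labels, used)
  centroids <- t(vapply(seq_along(used), function(j) {
    colMeans(reps[relabel == j, , drop = FALSE])
  }, numeric(ncol(reps))))
  colnames(centroids) <- colnames(reps)
  names(relabel) <- rownames(reps)
  structure(list(labels = relabel, centroids_sparse = centroids,
                 centroids_expression = NULL, objective = km$objective),
            class = "ClusterAssignment")
}

#' Compute expression-space centroids of a clustering
#'
#' Fills `centroids_expression`: for each cluster, the arithmetic mean of the
#' member genes' original normalized expression over the training samples
#' (not their sparse representations).
#'
#' @param assign A `ClusterAssignment` from [cluster_sparse()].
#' @param x The training `ExpressionMatrix` containing every labeled gene.
#' @return `assign` with `centroids_expression` set (clusters x samples).
#' @export
attach_expression_centroids <- function(assign, x) {
  gene_set <- names(assign$labels)
  missing <- setdiff(gene_set, gene_ids(x))
  if (length(missing))
    camodi_stop("labeled gene(s) missing from matrix: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  ks <- sort(unique(assign$labels))
  cent <- t(vapply(ks, function(c) {
    members <- gene_set[assign$labels == c]
    colMeans(x$values[members, , drop = FALSE])
  }, numeric(n_samples(x))))
  rownames(cent) <- ks
  colnames(cent) <- sample_ids(x)
  assign$centroids_expression <- cent
  assign
}
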