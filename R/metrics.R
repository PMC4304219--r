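#' Jaccard index of two identifier sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`. Two empty sets are defined as
#' identical, `J = 1`.
#'
#' @param a,b Character vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Average Jaccard similarity of two modules
#'
#' The mean of the gene-set and regulator-set Jaccard indices:
#' `(J(G1, G2) + J(R1, R2)) / 2`.
#'
#' @param m1,m2 `Module` objects.
#' @return A number in `[0, 1]`.
#' @export
avg_module_jaccard <- function(m1, m2) {
  (jaccard(m1$genes, m2$genes) + jaccard(m1$regulators, m2$regulators)) / 2
}

modules_of <- function(r) {
  if (inherits(r, "BootstrapResult")) r$modules else r
}

#' Consistency of module discovery across bootstraps
#'
#' Measures stability against the random train/test split. For each pair of
#' bootstraps, every module of the first is matched to its best
#' [avg_module_jaccard()] partner in the second and vice versa, giving
#' `N_a + N_b` matched similarities whose mean is the pair score; the
#' consistency `S` is the mean pair score over all unordered bootstrap
#' pairs. Best-match ties resolve to the earliest module.
#'
#' @param results List of `BootstrapResult` objects (or bare lists of
#'   `Module`s), length >= 2, each with at least one module.
#' @return A number in `[0, 1]`.
#' @export
consistency <- function(results) {
  B <- length(results)
  if (B < 2) camodi_stop("consistency needs at least 2 bootstraps")
  mods <- lapply(results, modules_of)
  empty <- which(vapply(mods, length, integer(1)) == 0)
  if (length(empty))
    camodi_stop("bootstrap %d has no modules", empty[1])
  pair_scores <- c()
  for (a in seq_len(B - 1)) {
    for (b in seq(a + 1, B)) {
      J <- matrix(0, length(mods[[a]]), length(mods[[b]]))
      for (i in seq_along(mods[[a]]))
        for (j in seq_along(mods[[b]]))
          J[i, j] <- avg_module_jaccard(mods[[a]][[i]], mods[[b]][[j]])
      pair_scores <- c(pair_scores,
                       mean(c(apply(J, 1, max), apply(J, 2, max))))
    }
  }
  mean(pair_scores)
}

#' Homogeneity of a module set
#'
#' Within each module, every gene gets the mean Pearson correlation of its
#' expression with each other member gene; the module's homogeneity is the
#' mean of these per-gene values (equivalently the mean off-diagonal entry
#' of the member correlation matrix), and `H` averages over modules.
#' Singleton modules are excluded with a warning.
#'
#' @param modules List of `Module`s.
#' @param x An `ExpressionMatrix` containing the member genes.
#' @param sample_ids Samples over which correlations are computed
#'   (typically the held-out test samples).
#' @return The homogeneity `H`.
#' @export
homogeneity <- function(modules, x, sample_ids) {
  xs <- subset_samples(x, sample_ids)
  vals <- vapply(modules, function(m) {
    if (length(m$genes) < 2) return(NA_real_)
    C <- stats::cor(t(xs$values[m$genes, , drop = FALSE]))
    per_gene <- (rowSums(C) - 1) / (nrow(C) - 1)
    mean(per_gene)
  }, numeric(1))
  if (anyNA(vals)) {
    camodi_warn("%d singleton module(s) excluded from homogeneity", sum(is.na(vals)))
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) camodi_stop("no module with >= 2 genes")
  mean(vals)
}

#' Apply the reporting filter to a scored module set
#'
#' The evaluation convention: drop modules with fewer than `size_min` or more
#' than `size_max` genes, sort the rest by test-set adjusted R-squared
#' (descending), and keep the shortest prefix whose union of member genes
#' covers at least `coverage` of the gene universe. By default the universe
#' is the union of genes appearing in the size-filtered modules; set
#' `universe` explicitly to use all analyzed genes instead.
#'
#' @param modules List of scored `Module`s (`adj_r2_test` present).
#' @param size_min,size_max Gene-count bounds (defaults 5 and 1000).
#' @param coverage Required coverage fraction (default 0.8).
#' @param universe Optional character vector overriding the coverage
#'   denominator.
#' @return The retained list of `Module`s (possibly empty).
#' @export
reporting_filter <- function(modules, size_min = 5, size_max = 1000,
                             coverage = 0.8, universe = NULL) {
  sizes <- vapply(modules, function(m) length(m$genes), integer(1))
  keep <- modules[sizes >= size_min & sizes <= size_max]
  if (length(keep) == 0) return(list())
  scores <- vapply(keep, function(m) m$adj_r2_test, numeric(1))
  if (anyNA(scores)) camodi_stop("reporting_filter needs adj_r2_test on every module")
  keep <- keep[order(scores, decreasing = TRUE)]
  if (is.null(universe))
    universe <- unique(unlist(lapply(keep, function(m) m$genes)))
  target <- coverage * length(universe)
  covered <- character(0)
  for (i in seq_along(keep)) {
    covered <- union(covered, intersect(keep[[i]]$genes, universe))
    if (length(covered) >= target) return(keep[seq_len(i)])
  }
  keep
}

#' Summarize a set of bootstrap results
#'
#' @param results List of `BootstrapResult`s.
#' @param x The `ExpressionMatrix` the bootstraps ran on (for homogeneity).
#' @param apply_reporting_filter Apply [reporting_filter()] per bootstrap
#'   before averaging (default `TRUE`, the evaluation convention).
#' @return A one-row `data.frame` with the bootstrap count, mean test-set
#'   adjusted R-squared, consistency `S`, homogeneity `H`, mean module count
#'   and mean regulators per module.
#' @export
evaluate_bootstraps <- function(results, x, apply_reporting_filter = TRUE) {
  sets <- lapply(results, function(r) {
    mods <- modules_of(r)
    if (apply_reporting_filter) mods <- reporting_filter(mods)
    mods
  })
  adj <- unlist(lapply(sets, function(ms)
    vapply(ms, function(m) m$adj_r2_test, numeric(1))))
  nreg <- unlist(lapply(sets, function(ms)
    vapply(ms, function(m) length(m$regulators), integer(1))))
  H <- mean(vapply(seq_along(sets), function(i) {
    homogeneity(sets[[i]], x, results[[i]]$split$test_sample_ids)
  }, numeric(1)))
  S <- if (length(sets) >= 2) consistency(sets) else NA_real_
  data.frame(n_bootstraps = length(sets),
             mean_adj_r2_test = mean(adj),
             consistency = S,
             homogeneity = H,
             mean_module_count = mean(vapply(sets, length, integer(1))),
             mean_regulators_per_module = mean(nreg))
}
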