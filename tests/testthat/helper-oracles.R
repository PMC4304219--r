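# Independent brute-force implementations of the evaluation formulas,
# written with naive loops and kept deliberately separate from the package
# code paths they check.

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  inter <- 0
  for (el in a) if (el %in% b) inter <- inter + 1
  inter / (length(a) + length(b) - inter)
}

oracle_avg_module_jaccard <- function(m1, m2) {
  (oracle_jaccard(m1$genes, m2$genes) +
     oracle_jaccard(m1$regulators, m2$regulators)) / 2
}

oracle_consistency <- function(sets) {
  pair_scores <- c()
  B <- length(sets)
  for (a in 1:(B - 1)) {
    for (b in (a + 1):B) {
      vals <- c()
      for (m1 in sets[[a]]) {
        best <- -1
        for (m2 in sets[[b]]) best <- max(best, oracle_avg_module_jaccard(m1, m2))
        vals <- c(vals, best)
      }
      for (m2 in sets[[b]]) {
        best <- -1
        for (m1 in sets[[a]]) best <- max(best, oracle_avg_module_jaccard(m1, m2))
        vals <- c(vals, best)
      }
      pair_scores <- c(pair_scores, sum(vals) / length(vals))
    }
  }
  sum(pair_scores) / length(pair_scores)
}

# mean, over member genes, of that gene's mean Pearson correlation with
# every other member gene; S is the genes x samples block
oracle_module_homogeneity <- function(S) {
  n <- nrow(S)
  per_gene <- numeric(n)
  for (i in 1:n) {
    rhos <- c()
    for (j in setdiff(1:n, i)) rhos <- c(rhos, stats::cor(S[i, ], S[j, ]))
    per_gene[i] <- mean(rhos)
  }
  mean(per_gene)
}

oracle_homogeneity <- function(modules, x, sample_ids) {
  vals <- c()
  for (m in modules) {
    if (length(m$genes) < 2) next
    vals <- c(vals, oracle_module_homogeneity(
      x$values[m$genes, sample_ids, drop = FALSE]))
  }
  mean(vals)
}

# module R-squared: residual energy of the shared prediction over the total
# energy of the member genes around their own means
oracle_module_r2 <- function(S, pred) {
  num <- 0; den <- 0
  for (i in 1:nrow(S)) {
    mu_i <- sum(S[i, ]) / ncol(S)
    for (k in 1:ncol(S)) {
      num <- num + (pred[k] - S[i, k])^2
      den <- den + (S[i, k] - mu_i)^2
    }
  }
  1 - num / den
}

oracle_score_module <- function(module, x, sample_ids) {
  S <- x$values[module$genes, sample_ids, drop = FALSE]
  pred <- numeric(length(sample_ids))
  for (k in seq_along(sample_ids)) {
    v <- 0
    for (r in module$regulators)
      v <- v + module$coefficients[[r]] * x$values[r, sample_ids[k]]
    pred[k] <- v
  }
  r2 <- oracle_module_r2(S, pred)
  nr <- length(module$regulators)
  list(r2 = r2, adj_r2 = r2 - (1 - r2) * nr / (length(sample_ids) - nr - 1))
}

# exhaustive reporting-filter prefix: try every prefix length of the
# size-filtered, score-sorted list and return the first that covers
oracle_reporting_filter <- function(modules, size_min = 5, size_max = 1000,
                                    coverage = 0.8) {
  keep <- Filter(function(m) length(m$genes) >= size_min &&
                   length(m$genes) <= size_max, modules)
  if (length(keep) == 0) return(list())
  scores <- sapply(keep, function(m) m$adj_r2_test)
  keep <- keep[order(scores, decreasing = TRUE)]
  universe <- unique(unlist(lapply(keep, function(m) m$genes)))
  for (L in seq_along(keep)) {
    cov <- unique(unlist(lapply(keep[1:L], function(m) m$genes)))
    if (length(cov) >= coverage * length(universe)) return(keep[1:L])
  }
  keep
}

oracle_best_single_regulator <- function(gene, reg_mat) {
  # exhaustive single-regulator least squares: picks max squared correlation
  best <- NA_character_; best_ss <- Inf
  for (r in rownames(reg_mat)) {
    b <- sum(reg_mat[r, ] * gene) / sum(reg_mat[r, ]^2)
    ss <- sum((gene - b * reg_mat[r, ])^2)
    if (ss < best_ss) { best_ss <- ss; best <- r }
  }
  best
}
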