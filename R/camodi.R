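#' Build a discovery configuration
#'
#' The tunable parameters of the module discovery iteration, with
#' implementation defaults sized for a variance-filtered matrix of a few
#' thousand genes. The parameters that matter most: `c1`/`c2` cap the number
#' of regulators per gene representation / per centroid; `s1_init` is the
#' initial sparsity fed to K-means, incremented by `s1_step` each iteration
#' (and capped at `c1`); `k` is the K-means cluster count; `p_keep` is the
#' percentage of clusters always retained per iteration; `r_thresh`,
#' `n_min`, `n_max` define the alternative retention rule (cross-validated
#' R-squared above the threshold and size within bounds); `l2_gene` and
#' `l2_centroid` are the fixed ridge penalties of the two elastic-net stages.
#'
#' @param c1 Max regulators per gene representation (default 10).
#' @param c2 Max regulators per centroid (default 10).
#' @param s1_init Initial sparsity (default 1).
#' @param s1_step Sparsity increment per iteration (default 2).
#' @param k K-means cluster count at full gene pool (default 100).
#' @param p_keep Percentage of clusters retained per iteration (default 10).
#' @param r_thresh Cross-validated R-squared threshold (default 0.6).
#' @param n_min,n_max Cluster size bounds for threshold retention
#'   (defaults 5 and 1000).
#' @param l2_gene,l2_centroid Ridge penalties (defaults 0.01).
#' @param n_folds Gene folds for centroid cross-validation (default 10).
#' @param max_iterations Iteration cap (default 10).
#' @param base_seed Seed from which all randomness derives (default 1).
#' @param k_scaling `"scaled"` (default) shrinks K with the remaining gene
#'   pool, `K_t = max(2, round(k * n_remaining / n_initial))`; `"fixed"`
#'   keeps `k` constant.
#' @param var_fraction Variance-filter fraction used by [run_bootstraps()]
#'   (default 0.15).
#' @param normalize_scope `"all"` (default) z-normalizes genes on all samples
#'   before splitting; `"train"` estimates the normalization on the training
#'   samples only.
#' @param refit Refit active-set coefficients by least squares
#'   (default `FALSE`).
#' @return A validated `CamodiConfig` list.
#' @export
camodi_config <- function(c1 = 10, c2 = 10, s1_init = 1, s1_step = 2,
                          k = 100, p_keep = 10, r_thresh = 0.6,
                          n_min = 5, n_max = 1000,
                          l2_gene = 0.01, l2_centroid = 0.01,
                          n_folds = 10, max_iterations = 10, base_seed = 1,
                          k_scaling = c("scaled", "fixed"),
                          var_fraction = 0.15,
                          normalize_scope = c("all", "train"),
                          refit = FALSE) {
  cfg <- list(c1 = as.integer(c1), c2 = as.integer(c2),
              s1_init = as.integer(s1_init), s1_step = as.integer(s1_step),
              k = as.integer(k), p_keep = as.numeric(p_keep),
              r_thresh = as.numeric(r_thresh),
              n_min = as.integer(n_min), n_max = as.integer(n_max),
              l2_gene = as.numeric(l2_gene),
              l2_centroid = as.numeric(l2_centroid),
              n_folds = as.integer(n_folds),
              max_iterations = as.integer(max_iterations),
              base_seed = as.integer(base_seed),
              k_scaling = match.arg(as.character(k_scaling)[1],
                                    c("scaled", "fixed")),
              var_fraction = as.numeric(var_fraction),
              normalize_scope = match.arg(as.character(normalize_scope)[1],
                                          c("all", "train")),
              refit = isTRUE(as.logical(refit)))
  if (cfg$s1_init < 1 || cfg$s1_init > cfg$c1)
    camodi_stop("'s1_init' must satisfy 1 <= s1_init <= c1")
  if (!(cfg$p_keep > 0 && cfg$p_keep <= 100))
    camodi_stop("'p_keep' must be in (0, 100]")
  if (cfg$n_min < 2) camodi_stop("'n_min' must be >= 2")
  if (cfg$n_max <= cfg$n_min) camodi_stop("'n_max' must exceed 'n_min'")
  if (cfg$l2_gene < 0 || cfg$l2_centroid < 0)
    camodi_stop("ridge penalties must be non-negative")
  structure(cfg, class = "CamodiConfig")
}

#' Run the module discovery iteration on training data
#'
#' One iteration: (a) sparsify the remaining genes over the regulator basis
#' at the current sparsity `S1`; (b) K-means on the S1-sparse coefficient
#' vectors; (c) sparsify each cluster centroid with sparsity selected by
#' cross-validation over the cluster's genes and rank clusters by that
#' cross-validated R-squared; (d) retain the union of the top
#' `ceiling(p_keep% x candidates)` clusters and all clusters with
#' `cv_r2 > r_thresh` and size in `[n_min, n_max]`. Retained clusters become
#' final modules; the other genes carry to the next iteration with `S1`
#' incremented by `s1_step` (capped at `c1`). Iteration stops when the
#' sparsity budget `c1` is exhausted, fewer than `n_min` genes remain, or
#' `max_iterations` is hit; leftovers are reported unassigned.
#'
#' @param x_train An `ExpressionMatrix` restricted to training samples, with
#'   regulators flagged.
#' @param config A [camodi_config()].
#' @param ids Gene ids to explain (default: all genes in `x_train`,
#'   regulators included — a regulator gene never uses itself in its basis).
#' @param verbose Log one line per iteration.
#' @return A `camodi_fit`: list with `modules` (list of scored `Module`s,
#'   `r2_train` filled), `unassigned` (character vector) and `iterations`
#'   (per-iteration data.frame: sparsity, clusters formed/candidates/
#'   retained, genes remaining after the iteration).
#' @export
run_camodi <- function(x_train, config, ids = gene_ids(x_train),
                       verbose = FALSE) {
  stopifnot(inherits(config, "CamodiConfig"))
  regs <- regulator_ids(x_train)
  if (length(regs) == 0) camodi_stop("no regulators flagged in the matrix")
  pool <- ids
  n_initial <- length(pool)
  modules <- list()
  log_rows <- list()
  t <- 0L
  repeat {
    t <- t + 1L
    if (t > config$max_iterations || length(pool) < config$n_min) break
    raw_s1 <- config$s1_init + (t - 1L) * config$s1_step
    # a regulator gene loses itself from its basis, hence the extra headroom
    basis_floor <- length(regs) - 1L - as.integer(any(pool %in% regs))
    s1 <- max(1L, min(raw_s1, config$c1, basis_floor))

    reps <- sparsify_all(x_train, pool, c1 = s1, l2_penalty = config$l2_gene,
                         refit = config$refit)
    M <- sparse_matrix_at(reps, s1)

    k_t <- if (config$k_scaling == "scaled") {
      max(2L, as.integer(round(config$k * length(pool) / n_initial)))
    } else config$k
    k_t <- min(k_t, length(pool))
    seed_t <- config$base_seed + 1000L * t
    assign <- suppressWarnings(cluster_sparse(M, k_t, seed = seed_t))

    cluster_ids <- sort(unique(assign$labels))
    members <- lapply(cluster_ids, function(c) names(assign$labels)[assign$labels == c])
    sizes <- lengths(members)
    candidates <- which(sizes >= 2)
    n_formed <- length(cluster_ids)

    sel <- vector("list", n_formed)
    cv_r2 <- rep(-Inf, n_formed)
    for (ci in candidates) {
      genes_c <- members[[ci]]
      # exclude member regulators from the centroid basis (no self-fit)
      basis <- setdiff(regs, genes_c)
      if (length(basis) < 2) basis <- regs
      c2_eff <- min(config$c2, length(basis) - 1L)
      sel[[ci]] <- select_sparsity_cv(
        x_train$values[genes_c, , drop = FALSE],
        x_train$values[basis, , drop = FALSE],
        c2 = c2_eff, l2_penalty = config$l2_centroid,
        n_folds = min(config$n_folds, length(genes_c)),
        seed = seed_t + ci, refit = config$refit)
      cv_r2[ci] <- sel[[ci]]$cv_r2
    }

    retained <- integer(0)
    if (length(candidates)) {
      n_top <- ceiling(config$p_keep / 100 * length(candidates))
      ranked <- candidates[order(cv_r2[candidates], decreasing = TRUE)]
      top <- ranked[seq_len(min(n_top, length(ranked)))]
      thr <- candidates[cv_r2[candidates] > config$r_thresh &
                          sizes[candidates] >= config$n_min &
                          sizes[candidates] <= config$n_max]
      retained <- sort(union(top, thr))
    }

    for (ci in retained) {
      mod <- new_module(sprintf("it%d_c%d", t, ci), members[[ci]],
                        sel[[ci]]$coefficients, cv_r2 = sel[[ci]]$cv_r2)
      sc <- score_module(mod, x_train, sample_ids(x_train))
      mod$r2_train <- sc$r2
      modules[[length(modules) + 1L]] <- mod
    }
    pool <- unlist(members[setdiff(seq_len(n_formed), retained)],
                   use.names = FALSE) %||% character(0)

    log_rows[[t]] <- data.frame(iteration = t, s1 = s1,
                                clusters_formed = n_formed,
                                clusters_candidate = length(candidates),
                                clusters_retained = length(retained),
                                genes_remaining = length(pool))
    if (verbose)
      message(sprintf("iteration %d: S1=%d, %d clusters (%d candidates), %d retained, %d genes remaining",
                      t, s1, n_formed, length(candidates), length(retained),
                      length(pool)))
    if (n_formed == 0) {
      camodi_warn("no clusters formed; terminating")
      break
    }
    if (raw_s1 >= config$c1) break  # sparsity budget exhausted
  }
  structure(list(modules = modules, unassigned = pool,
                 iterations = do.call(rbind, log_rows)),
            class = "camodi_fit")
}

#' @export
print.camodi_fit <- function(x, ...) {
  cat(sprintf("camodi_fit: %d modules over %d iterations, %d genes unassigned\n",
              length(x$modules), NROW(x$iterations), length(x$unassigned)))
  invisible(x)
}

#' Run the full bootstrap protocol
#'
#' Per bootstrap: z-normalize genes (on all samples by default, the
#' protocol's convention; set `normalize_scope = "train"` in the config to
#' avoid the implied leakage), draw a 70/30 train-test split, variance-filter
#' genes on the training side, run [run_camodi()] on the training samples,
#' then score every discovered module on both sample sides. Fully
#' deterministic given `config$base_seed`.
#'
#' @param x An `ExpressionMatrix` with regulators flagged.
#' @param config A [camodi_config()].
#' @param n_bootstraps Number of 70/30 splits.
#' @param verbose Passed to [run_camodi()].
#' @return List of `BootstrapResult`s: each holds `split`, `modules` (scored
#'   on train and test), `unassigned`, `iterations` and a `summary` row
#'   (mean test adjusted R-squared, mean regulators per module, module count).
#' @export
run_bootstraps <- function(x, config, n_bootstraps, verbose = FALSE) {
  stopifnot(inherits(config, "CamodiConfig"))
  if (n_bootstraps < 1) camodi_stop("'n_bootstraps' must be >= 1")
  if (config$normalize_scope == "all") x_norm <- normalize_genes(x)
  splits <- suppressWarnings(make_splits(x, n_bootstraps, config$base_seed))
  lapply(splits, function(split) {
    xb <- if (config$normalize_scope == "train")
      normalize_genes(x, split$train_sample_ids) else x_norm
    keep <- variance_filter(xb, config$var_fraction, split)
    cfg_b <- config
    cfg_b$base_seed <- config$base_seed + 100003L * split$index
    x_train <- subset_samples(xb, split$train_sample_ids)
    fit <- run_camodi(x_train, cfg_b, ids = keep, verbose = verbose)
    test_ids <- split$test_sample_ids
    fit$modules <- lapply(fit$modules, function(m) {
      sc <- score_module(m, xb, test_ids)
      m$r2_test <- sc$r2
      m$adj_r2_test <- sc$adj_r2
      m
    })
    adj <- vapply(fit$modules, function(m) m$adj_r2_test, numeric(1))
    nreg <- vapply(fit$modules, function(m) length(m$regulators), numeric(1))
    structure(list(split = split, modules = fit$modules,
                   unassigned = fit$unassigned, iterations = fit$iterations,
                   summary = data.frame(
                     index = split$index,
                     n_modules = length(fit$modules),
                     mean_adj_r2_test = if (length(adj)) mean(adj) else NA_real_,
                     mean_n_regulators = if (length(nreg)) mean(nreg) else NA_real_)),
              class = "BootstrapResult")
  })
}

tuning_objective <- function(x, config, n_bootstraps) {
  res <- run_bootstraps(x, config, n_bootstraps)
  adj <- unlist(lapply(res, function(r)
    vapply(r$modules, function(m) m$adj_r2_test, numeric(1))))
  if (length(adj) == 0) return(-Inf)
  mean(adj)
}

#' Greedy coordinate-ascent parameter tuning
#'
#' From `start`, repeatedly evaluates single-parameter changes drawn from
#' `grid` and adopts the change with the largest increase in the mean
#' test-set adjusted R-squared over the bootstraps' retained modules;
#' stops when no change improves the objective by more than `tol`.
#'
#' @param x An `ExpressionMatrix` with regulators flagged.
#' @param start A [camodi_config()] starting point.
#' @param grid Named list: parameter name -> candidate values.
#' @param n_bootstraps Bootstraps per objective evaluation.
#' @param tol Minimum adoption improvement (default 0.005).
#' @param verbose Log adopted moves.
#' @return The tuned `CamodiConfig`.
#' @export
tune_parameters <- function(x, start, grid, n_bootstraps = 2, tol = 0.005,
                            verbose = FALSE) {
  stopifnot(inherits(start, "CamodiConfig"))
  grid <- grid[lengths(grid) > 0]
  if (length(grid) == 0) {
    camodi_warn("empty tuning grid; returning the starting configuration")
    return(start)
  }
  current <- start
  current_obj <- tuning_objective(x, current, n_bootstraps)
  repeat {
    best_obj <- current_obj
    best_cfg <- NULL
    best_move <- NULL
    for (par in names(grid)) {
      for (val in grid[[par]]) {
        if (identical(val, current[[par]])) next
        args <- unclass(current)
        args[[par]] <- val
        cand <- do.call(camodi_config, args)
        obj <- tuning_objective(x, cand, n_bootstraps)
        if (obj > best_obj) {
          best_obj <- obj
          best_cfg <- cand
          best_move <- sprintf("%s=%s", par, val)
        }
      }
    }
    if (is.null(best_cfg) || best_obj - current_obj <= tol) break
    if (verbose) message(sprintf("adopting %s (objective %.4f -> %.4f)",
                                 best_move, current_obj, best_obj))
    current <- best_cfg
    current_obj <- best_obj
  }
  current
}
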