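# Driver tests run at deliberately reduced scale (small planted worlds,
# few bootstraps) to keep the suite fast; the acceptance tests exercise the
# spec-scale design.

exact_copy_world <- function(seed = 1) {
  # every target gene equals one of three regulators exactly
  set.seed(seed)
  m <- 60
  reg_ids <- paste0("R", 1:5)
  reg <- matrix(rnorm(5 * m), 5, m, dimnames = list(reg_ids, NULL))
  planted <- rep(c("R1", "R2", "R3"), each = 8)
  genes <- reg[planted, , drop = FALSE]
  rownames(genes) <- sprintf("G%02d", seq_along(planted))
  v <- rbind(reg, genes)
  colnames(v) <- sprintf("S%02d", seq_len(m))
  x <- set_regulators(normalize_genes(expression_matrix(v)), reg_ids)
  list(x = x, planted = stats::setNames(planted, rownames(genes)))
}

test_that("noiseless copy-world is fully assigned in the first iteration", {
  w <- exact_copy_world(3)
  cfg <- camodi_config(c1 = 3, c2 = 3, k = 3, n_min = 5, n_max = 100,
                       var_fraction = 1, base_seed = 7)
  fit <- run_camodi(w$x, cfg, ids = names(w$planted))
  expect_length(fit$unassigned, 0)
  expect_equal(fit$iterations$iteration[1], 1)
  expect_gte(length(fit$modules), 3)
  for (m in fit$modules) expect_gt(m$cv_r2, 0.999)
  # each module's genes share one planted regulator, which the module found
  for (m in fit$modules) {
    truth_regs <- unique(w$planted[m$genes])
    expect_length(truth_regs, 1)
    expect_true(truth_regs %in% m$regulators)
  }
})

test_that("max_iterations = 1 returns exactly the first-iteration retention", {
  sim <- generate_planted(planted_design(n_modules = 4, n_background_genes = 30,
                                         n_regulators = 20, m_samples = 100,
                                         seed = 9))
  cfg1 <- camodi_config(c1 = 4, c2 = 4, k = 6, var_fraction = 1, base_seed = 5,
                        max_iterations = 1)
  cfg_full <- camodi_config(c1 = 4, c2 = 4, k = 6, var_fraction = 1,
                            base_seed = 5)
  ids <- setdiff(gene_ids(sim$x), regulator_ids(sim$x))
  f1 <- run_camodi(sim$x, cfg1, ids = ids)
  ffull <- run_camodi(sim$x, cfg_full, ids = ids)
  expect_equal(nrow(f1$iterations), 1)
  expect_equal(length(f1$modules), f1$iterations$clusters_retained[1])
  first_full <- ffull$modules[startsWith(
    vapply(ffull$modules, `[[`, character(1), "module_id"), "it1_")]
  expect_equal(vapply(f1$modules, `[[`, character(1), "module_id"),
               vapply(first_full, `[[`, character(1), "module_id"))
  expect_setequal(c(unlist(lapply(f1$modules, `[[`, "genes")), f1$unassigned),
                  ids)
})

test_that("modules partition the assigned genes and protocol invariants hold", {
  sim <- generate_planted(planted_design(n_modules = 5, n_background_genes = 40,
                                         n_regulators = 25, m_samples = 120,
                                         seed = 21))
  cfg <- camodi_config(c1 = 5, c2 = 5, k = 8, var_fraction = 1, base_seed = 11)
  fit <- run_camodi(sim$x, cfg)
  assigned <- unlist(lapply(fit$modules, `[[`, "genes"))
  expect_equal(anyDuplicated(assigned), 0L)
  expect_length(intersect(assigned, fit$unassigned), 0)
  it <- fit$iterations
  expect_true(all(it$clusters_retained >=
                    ceiling(cfg$p_keep / 100 * it$clusters_candidate)))
  expect_equal(it$s1, pmin(cfg$s1_init + (it$iteration - 1) * cfg$s1_step,
                           cfg$c1))
})

test_that("simple one-regulator modules are retained no later than complex ones", {
  set.seed(77)
  m <- 150
  reg_ids <- sprintf("R%02d", 1:20)
  reg <- matrix(rnorm(20 * m), 20, m, dimnames = list(reg_ids, NULL))
  blocks <- list(); planted_iter <- c()
  gid <- 0
  truth <- list()
  for (j in 1:10) {
    nr <- if (j <= 5) 1 else 4
    regs_j <- sample(reg_ids, nr)
    coefs <- runif(nr, 0.7, 1.2) * sample(c(-1, 1), nr, TRUE)
    signal <- drop(coefs %*% reg[regs_j, , drop = FALSE])
    gids <- sprintf("G%03d", gid + 1:10); gid <- gid + 10
    blocks[[j]] <- matrix(rep(signal, each = 10), 10, m) +
      matrix(rnorm(10 * m, sd = 0.2), 10, m)
    rownames(blocks[[j]]) <- gids
    truth[[j]] <- list(genes = gids, complex = j > 5)
  }
  v <- rbind(reg, do.call(rbind, blocks))
  colnames(v) <- sprintf("S%03d", 1:m)
  x <- set_regulators(normalize_genes(expression_matrix(v)), reg_ids)
  cfg <- camodi_config(c1 = 6, c2 = 6, k = 10, var_fraction = 1, base_seed = 3)
  fit <- run_camodi(x, cfg, ids = setdiff(gene_ids(x), reg_ids))
  iter_of <- function(genes) {
    js <- vapply(fit$modules, function(mo) jaccard(genes, mo$genes), numeric(1))
    id <- fit$modules[[which.max(js)]]$module_id
    as.integer(sub("^it(\\d+)_.*", "\\1", id))
  }
  simple_it <- vapply(truth[1:5], function(t) iter_of(t$genes), integer(1))
  complex_it <- vapply(truth[6:10], function(t) iter_of(t$genes), integer(1))
  expect_lte(mean(simple_it), mean(complex_it))
})

test_that("run_bootstraps is deterministic and scores test samples correctly", {
  sim <- generate_planted(planted_design(n_modules = 4, n_background_genes = 30,
                                         n_regulators = 20, m_samples = 100,
                                         seed = 2))
  cfg <- camodi_config(c1 = 4, c2 = 4, k = 6, var_fraction = 1, base_seed = 13)
  a <- run_bootstraps(sim$x, cfg, 2)
  b <- run_bootstraps(sim$x, cfg, 2)
  expect_identical(a, b)
  expect_gte(min(vapply(a, function(r) length(r$modules), integer(1))), 1)
  # test-side scores recompute from the test split alone
  xn <- normalize_genes(sim$x)
  r <- a[[1]]
  for (m in r$modules) {
    sc <- score_module(m, xn, r$split$test_sample_ids)
    expect_equal(m$r2_test, sc$r2, tolerance = 1e-12)
    expect_equal(m$adj_r2_test, sc$adj_r2, tolerance = 1e-12)
  }
})

test_that("tuning is a fixed point at an already-optimal grid and warns on empty grids", {
  sim <- generate_planted(planted_design(n_modules = 3, n_background_genes = 20,
                                         n_regulators = 15,
                                         genes_per_module = c(10, 10),
                                         m_samples = 80, seed = 4))
  start <- camodi_config(c1 = 4, c2 = 4, k = 5, var_fraction = 1, base_seed = 2)
  expect_warning(same <- tune_parameters(sim$x, start, list(), 1), "empty")
  expect_identical(same, start)
  got <- tune_parameters(sim$x, start, list(k = c(5)), n_bootstraps = 1)
  expect_identical(got, start)
})

test_that("tuning adopts a strictly better single-parameter move", {
  sim <- generate_planted(planted_design(n_modules = 4, n_background_genes = 20,
                                         n_regulators = 15,
                                         genes_per_module = c(12, 12),
                                         m_samples = 100, seed = 6))
  # p_keep = 100 forces every candidate cluster (including background noise
  # clusters) into the retained set, dragging the mean adjusted r2 down;
  # p_keep = 10 keeps only the well-explained clusters
  start <- camodi_config(c1 = 4, c2 = 4, k = 6, var_fraction = 1,
                         base_seed = 8, p_keep = 100, r_thresh = 2)
  tuned <- tune_parameters(sim$x, start,
                           list(p_keep = c(100, 10)), n_bootstraps = 1)
  expect_equal(tuned$p_keep, 10)
})
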