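# Programmatic fixtures shared across test files.

# random z-normalized expression matrix with the first n_reg genes flagged
# as regulators
make_toy_expr <- function(n_genes = 20, n_reg = 5, m = 30, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("R%02d", seq_len(n_reg)),
           sprintf("G%02d", seq_len(n_genes - n_reg)))
  v <- matrix(rnorm(n_genes * m), n_genes, m,
              dimnames = list(ids, sprintf("S%02d", seq_len(m))))
  x <- expression_matrix(v)
  x <- normalize_genes(x)
  set_regulators(x, ids[seq_len(n_reg)])
}

# random module over given pools (coefficients non-zero)
rand_module <- function(id, gene_pool, reg_pool, n_genes = 4, n_reg = 2) {
  genes <- sample(gene_pool, n_genes)
  regs <- sample(reg_pool, n_reg)
  coefs <- stats::setNames(runif(n_reg, 0.2, 1) * sample(c(-1, 1), n_reg, TRUE),
                           regs)
  new_module(id, genes, coefs,
             cv_r2 = runif(1), r2_train = runif(1),
             r2_test = runif(1), adj_r2_test = runif(1, -0.2, 1))
}

rand_module_set <- function(n, gene_pool, reg_pool, prefix = "m") {
  lapply(seq_len(n), function(i)
    rand_module(paste0(prefix, i), gene_pool, reg_pool,
                n_genes = sample(3:6, 1), n_reg = sample(1:3, 1)))
}

# small expression TSV on disk; returns the path
write_toy_tsv <- function(lines, dir = tempdir()) {
  path <- tempfile("expr", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

# expression matrix with planted one-to-one structure: each gene is a noisy
# copy of scale * one planted regulator
make_planted_pairs <- function(n_reg = 10, genes_per_reg = 5, m = 80,
                               noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  reg_ids <- sprintf("R%02d", seq_len(n_reg))
  reg <- matrix(rnorm(n_reg * m), n_reg, m, dimnames = list(reg_ids, NULL))
  planted <- rep(reg_ids, each = genes_per_reg)
  gids <- sprintf("G%03d", seq_along(planted))
  genes <- reg[planted, , drop = FALSE] +
    matrix(rnorm(length(planted) * m, sd = noise_sd), length(planted), m)
  rownames(genes) <- gids
  v <- rbind(reg, genes)
  colnames(v) <- sprintf("S%03d", seq_len(m))
  x <- normalize_genes(expression_matrix(v))
  x <- set_regulators(x, reg_ids)
  list(x = x, planted = stats::setNames(planted, gids))
}

# configuration sized for the ~300-gene planted world (target average
# cluster size ~20 genes, mirroring the full-scale default k)
planted_world_config <- function(seed) {
  camodi_config(c1 = 6, c2 = 6, k = 15, var_fraction = 1, base_seed = seed)
}
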