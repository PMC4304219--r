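#' Describe a planted-module simulation design
#'
#' The generator emulates the structure the discovery model assumes: a pool
#' of regulator genes with independent standard-normal expression, a set of
#' planted modules whose member genes are one shared noisy linear
#' combination of a small regulator subset, and unstructured background
#' genes. Planted modules never share genes but may share regulators.
#'
#' @param n_regulators Size of the regulator pool (default 50).
#' @param n_modules Number of planted modules (default 10).
#' @param regulators_per_module Length-2 integer range of regulators drawn
#'   per module (default `c(2, 4)`).
#' @param genes_per_module Length-2 integer range of member genes per module
#'   (default `c(20, 20)`).
#' @param n_background_genes Pure-noise genes (default 100).
#' @param noise_sd Standard deviation of the additive gene noise
#'   (default 0.2; the signal components are unit-variance).
#' @param coefficient_range Absolute-coefficient interval (default
#'   `c(0.5, 1.5)`); signs are random unless `nonnegative`.
#' @param m_samples Sample count (default 200).
#' @param seed Integer seed (default 1).
#' @param nonnegative Force non-negative coefficients (default `FALSE`).
#' @return A validated `PlantedDesign` list.
#' @export
planted_design <- function(n_regulators = 50, n_modules = 10,
                           regulators_per_module = c(2, 4),
                           genes_per_module = c(20, 20),
                           n_background_genes = 100,
                           noise_sd = 0.2, coefficient_range = c(0.5, 1.5),
                           m_samples = 200, seed = 1, nonnegative = FALSE) {
  d <- list(n_regulators = as.integer(n_regulators),
            n_modules = as.integer(n_modules),
            regulators_per_module = as.integer(regulators_per_module),
            genes_per_module = as.integer(genes_per_module),
            n_background_genes = as.integer(n_background_genes),
            noise_sd = as.numeric(noise_sd),
            coefficient_range = as.numeric(coefficient_range),
            m_samples = as.integer(m_samples), seed = as.integer(seed),
            nonnegative = isTRUE(nonnegative))
  if (max(d$regulators_per_module) > d$n_regulators)
    camodi_stop("regulators_per_module exceeds the regulator pool")
  if (d$noise_sd < 0) camodi_stop("'noise_sd' must be >= 0")
  if (d$m_samples < 4) camodi_stop("'m_samples' must be >= 4")
  if (min(d$genes_per_module) < 1 || min(d$regulators_per_module) < 1)
    camodi_stop("per-module ranges must be positive")
  if (any(d$coefficient_range <= 0) || d$coefficient_range[1] > d$coefficient_range[2])
    camodi_stop("'coefficient_range' must be a positive increasing interval")
  structure(d, class = "PlantedDesign")
}

#' Generate an expression matrix with planted module structure
#'
#' Regulator expression is drawn i.i.d. standard normal per sample. Each
#' planted module draws its regulator subset and shared coefficients; every
#' member gene is the coefficient-weighted regulator sum plus independent
#' normal noise. Background genes are pure standard normal. All gene rows
#' are z-normalized, so the output satisfies the container's invariants and
#' matches the preprocessing convention.
#'
#' @param design A [planted_design()].
#' @return List with `x` (an `ExpressionMatrix`, regulators flagged) and
#'   `truth` (a `PlantedTruth`: per-module gene ids, regulator ids and true
#'   coefficients, plus the background gene ids).
#' @export
generate_planted <- function(design) {
  stopifnot(inherits(design, "PlantedDesign"))
  d <- design
  with_seed(d$seed, {
    m <- d$m_samples
    reg_ids <- sprintf("TF%03d", seq_len(d$n_regulators))
    reg <- matrix(stats::rnorm(d$n_regulators * m), d$n_regulators, m,
                  dimnames = list(reg_ids, NULL))
    rows <- list()
    truth_modules <- list()
    gene_counter <- 0L
    for (j in seq_len(d$n_modules)) {
      nr <- if (d$regulators_per_module[1] == d$regulators_per_module[2])
        d$regulators_per_module[1] else
          sample(seq(d$regulators_per_module[1], d$regulators_per_module[2]), 1)
      ng <- if (d$genes_per_module[1] == d$genes_per_module[2])
        d$genes_per_module[1] else
          sample(seq(d$genes_per_module[1], d$genes_per_module[2]), 1)
      regs_j <- sample(reg_ids, nr)
      coefs <- stats::runif(nr, d$coefficient_range[1], d$coefficient_range[2])
      if (!d$nonnegative) coefs <- coefs * sample(c(-1, 1), nr, replace = TRUE)
      names(coefs) <- regs_j
      signal <- drop(coefs %*% reg[regs_j, , drop = FALSE])
      gids <- sprintf("G%04d", gene_counter + seq_len(ng))
      gene_counter <- gene_counter + ng
      block <- matrix(rep(signal, each = ng), ng, m, dimnames = list(gids, NULL)) +
        matrix(stats::rnorm(ng * m, sd = d$noise_sd), ng, m)
      rows[[j]] <- block
      truth_modules[[j]] <- list(module_id = sprintf("planted%02d", j),
                                 genes = gids, regulators = regs_j,
                                 coefficients = coefs)
    }
    bg_ids <- if (d$n_background_genes > 0)
      sprintf("BG%04d", seq_len(d$n_background_genes)) else character(0)
    bg <- matrix(stats::rnorm(d$n_background_genes * m),
                 d$n_background_genes, m, dimnames = list(bg_ids, NULL))
    values <- rbind(reg, do.call(rbind, rows), bg)
    colnames(values) <- sprintf("S%03d", seq_len(m))
    x <- expression_matrix(values)
    x <- normalize_genes(x)
    x <- suppressWarnings(set_regulators(x, reg_ids))
    truth <- structure(list(modules = truth_modules, background = bg_ids),
                       class = "PlantedTruth")
    list(x = x, truth = truth)
  })
}

#' Score recovery of planted modules
#'
#' Matches every planted module to the discovered module with the highest
#' gene-set Jaccard index, and computes micro-averaged regulator precision
#' and recall over the matched pairs.
#'
#' @param discovered List of `Module`s (e.g. from [run_camodi()]).
#' @param truth A `PlantedTruth` from [generate_planted()].
#' @return List with `mean_jaccard` (mean best-match gene-set Jaccard over
#'   planted modules), `regulator_precision` and `regulator_recall`.
#' @export
score_recovery <- function(discovered, truth) {
  stopifnot(inherits(truth, "PlantedTruth"))
  if (length(discovered) == 0)
    return(list(mean_jaccard = 0, regulator_precision = NA_real_,
                regulator_recall = 0))
  jacc <- numeric(length(truth$modules))
  inter <- 0; n_disc <- 0; n_true <- 0
  for (i in seq_along(truth$modules)) {
    tm <- truth$modules[[i]]
    js <- vapply(discovered, function(m) jaccard(tm$genes, m$genes), numeric(1))
    best <- which.max(js)
    jacc[i] <- js[best]
    inter <- inter + length(intersect(tm$regulators,
                                      discovered[[best]]$regulators))
    n_disc <- n_disc + length(discovered[[best]]$regulators)
    n_true <- n_true + length(tm$regulators)
  }
  list(mean_jaccard = mean(jacc),
       regulator_precision = if (n_disc > 0) inter / n_disc else NA_real_,
       regulator_recall = inter / n_true)
}
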