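test_that("predict_module is the shared weighted regulator sum", {
  v <- matrix(c(1, 2, 3,
                -1, 0, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("s1", "s2", "s3")))
  m1 <- new_module("m1", "g1", c(r1 = 1))
  expect_equal(unname(predict_module(m1, v)), c(1, 2, 3))
  m0 <- suppressWarnings(new_module("m0", "g1", numeric(0)))
  expect_equal(unname(predict_module(m0, v)), c(0, 0, 0))
  m2 <- new_module("m2", c("g1", "g2"), c(r1 = 0.3, r2 = -0.7))
  expect_equal(unname(predict_module(m2, v)),
               c(0.3 * 1 - 0.7 * -1, 0.3 * 2 - 0.7 * 0, 0.3 * 3 - 0.7 * 2))
  expect_error(predict_module(new_module("m", "g", c(r9 = 1)), v), "r9")
})

test_that("score_module: perfect prediction scores 1, and the closed-form
           adjusted value holds", {
  # gene rows both equal to r1: prediction with alpha = 1 is exact
  v <- rbind(r1 = c(1, -1, 0.5, -0.5), g1 = c(1, -1, 0.5, -0.5),
             g2 = c(1, -1, 0.5, -0.5))
  colnames(v) <- paste0("s", 1:4)
  x <- expression_matrix(v, c(TRUE, FALSE, FALSE))
  m <- new_module("m", c("g1", "g2"), c(r1 = 1))
  sc <- score_module(m, x, paste0("s", 1:4))
  expect_equal(sc$r2, 1)
  expect_equal(sc$adj_r2, 1)

  # craft r2 = 0.5 with one regulator over m = 3 samples: adjusted must be 0
  v2 <- rbind(r1 = c(0, 0, -1), g1 = c(1, 0, -1))
  colnames(v2) <- paste0("s", 1:3)
  x2 <- expression_matrix(v2, c(TRUE, FALSE))
  m2 <- new_module("m2", "g1", c(r1 = 1))
  sc2 <- score_module(m2, x2, paste0("s", 1:3))  # num = 1, den = 2
  expect_equal(sc2$r2, 0.5)
  expect_equal(sc2$adj_r2, 0.5 - (1 - 0.5) * 1 / (3 - 1 - 1))
  expect_equal(sc2$adj_r2, 0)
})

test_that("score_module matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- make_toy_expr(n_genes = 12, n_reg = 4, m = 10, seed = seed + 100)
    m <- rand_module(paste0("m", seed), setdiff(gene_ids(x), regulator_ids(x)),
                     regulator_ids(x), n_genes = 4, n_reg = 2)
    sc <- score_module(m, x, sample_ids(x))
    oc <- oracle_score_module(m, x, sample_ids(x))
    expect_equal(sc$r2, oc$r2, tolerance = 1e-12)
    expect_equal(sc$adj_r2, oc$adj_r2, tolerance = 1e-12)
  }
})

test_that("score_module guards its domain", {
  x <- make_toy_expr(n_genes = 8, n_reg = 3, m = 10, seed = 1)
  m <- new_module("m", c("G01", "G02"), c(R01 = 0.5, R02 = 0.4))
  expect_error(score_module(m, x, sample_ids(x)[1:3]), "undefined")
})

test_that("fit_centroid recovers simple planted centroids", {
  set.seed(19)
  Q <- qr.Q(qr(matrix(rnorm(60 * 8), 60, 8))) * sqrt(59)
  reg <- t(Q)
  rownames(reg) <- sprintf("r%02d", 1:8)
  cands <- fit_centroid(reg["r03", ], reg[-3, , drop = FALSE], c2 = 3,
                        l2_penalty = 0)
  # best single surrogate for an orthogonal design is noise-level: instead
  # fit a centroid that IS a basis regulator
  cands2 <- fit_centroid(drop(reg["r03", ]) + rnorm(60, sd = 1e-8), reg,
                         c2 = 3, l2_penalty = 0)
  expect_equal(names(which(cands2$reps[1, ] != 0)), "r03")

  centroid <- 0.5 * reg["r01", ] + 0.5 * reg["r02", ]
  cands3 <- fit_centroid(centroid, reg, c2 = 3, l2_penalty = 0)
  expect_setequal(names(which(cands3$reps[2, ] != 0)), c("r01", "r02"))
  expect_equal(unname(cands3$reps[2, c("r01", "r02")]), c(0.5, 0.5),
               tolerance = 0.05)
  cands4 <- fit_centroid(centroid, reg, c2 = 3, l2_penalty = 0, refit = TRUE)
  expect_equal(unname(cands4$reps[2, c("r01", "r02")]), c(0.5, 0.5),
               tolerance = 1e-6)
  one <- fit_centroid(centroid, reg, c2 = 1, l2_penalty = 0)
  expect_equal(nrow(one$reps), 1)
})

test_that("cross-validated sparsity selection behaves on structured and null clusters", {
  set.seed(33)
  reg <- matrix(rnorm(12 * 100), 12, 100,
                dimnames = list(sprintf("r%02d", 1:12), NULL))
  # identical (noiseless) copies of one regulator: p = 1, cv_r2 ~ 1
  copies <- matrix(rep(reg["r05", ], 6), 6, 100, byrow = TRUE,
                   dimnames = list(paste0("g", 1:6), NULL))
  sel <- select_sparsity_cv(copies, reg, c2 = 4, l2_penalty = 0,
                            n_folds = 3, seed = 1)
  expect_equal(sel$p, 1L)
  expect_equal(names(sel$coefficients), "r05")
  expect_gt(sel$cv_r2, 0.999)

  # pure-noise cluster: held-out r2 near zero or below
  noise <- matrix(rnorm(6 * 100), 6, 100, dimnames = list(paste0("n", 1:6), NULL))
  sel_n <- select_sparsity_cv(noise, reg, c2 = 4, l2_penalty = 0,
                              n_folds = 3, seed = 2)
  expect_lt(sel_n$cv_r2, 0.15)
})

test_that("cv picks the planted sparsity for three-regulator clusters", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed + 500)
    reg <- matrix(rnorm(15 * 120), 15, 120,
                  dimnames = list(sprintf("r%02d", 1:15), NULL))
    signal <- drop(c(1, -0.9, 0.8) %*% reg[c("r01", "r02", "r03"), ])
    genes <- matrix(rep(signal, 8), 8, 120, byrow = TRUE) +
      matrix(rnorm(8 * 120, sd = 0.2), 8, 120)
    rownames(genes) <- paste0("g", 1:8)
    sel <- select_sparsity_cv(genes, reg, c2 = 5, l2_penalty = 0.01,
                              n_folds = 4, seed = seed)
    if (sel$p == 3L) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("cv selection never prefers a dominated sparsity and reduces folds", {
  set.seed(44)
  reg <- matrix(rnorm(8 * 60), 8, 60, dimnames = list(paste0("r", 1:8), NULL))
  genes <- matrix(rep(reg["r2", ], 3), 3, 60, byrow = TRUE) +
    matrix(rnorm(180, sd = 0.3), 3, 60)
  rownames(genes) <- paste0("g", 1:3)
  expect_warning(sel <- select_sparsity_cv(genes, reg, c2 = 3, n_folds = 10,
                                           seed = 3), "leave-one-out")
  expect_equal(sel$cv_r2, max(sel$cv_curve))
  expect_true(all(sel$cv_curve[seq_len(sel$p - 1)] < sel$cv_r2))
  expect_error(select_sparsity_cv(genes[1, , drop = FALSE], reg, c2 = 2),
               "at least 2 genes")
})

test_that("a useless extra regulator does not raise adjusted r2 in expectation", {
  diffs <- numeric(200)
  for (i in 1:200) {
    set.seed(i + 2000)
    m_tr <- 40; m_te <- 30
    r1 <- rnorm(m_tr + m_te); r2 <- rnorm(m_tr + m_te)
    genes <- matrix(rep(0.8 * r1, 4), 4, m_tr + m_te, byrow = TRUE) +
      matrix(rnorm(4 * (m_tr + m_te), sd = 0.5), 4, m_tr + m_te)
    v <- rbind(r1 = r1, r2 = r2, genes)
    rownames(v) <- c("r1", "r2", paste0("g", 1:4))
    colnames(v) <- paste0("s", seq_len(m_tr + m_te))
    x <- expression_matrix(v, c(TRUE, TRUE, rep(FALSE, 4)))
    tr <- paste0("s", 1:m_tr); te <- paste0("s", (m_tr + 1):(m_tr + m_te))
    centroid <- colMeans(v[3:6, tr])
    b1 <- stats::lsfit(cbind(v["r1", tr]), centroid, intercept = FALSE)$coefficients
    b2 <- stats::lsfit(t(v[c("r1", "r2"), tr]), centroid, intercept = FALSE)$coefficients
    mA <- new_module("a", paste0("g", 1:4), c(r1 = unname(b1)))
    mB <- new_module("b", paste0("g", 1:4),
                     stats::setNames(as.numeric(b2), c("r1", "r2")))
    diffs[i] <- score_module(mB, x, te)$adj_r2 - score_module(mA, x, te)$adj_r2
  }
  # one-sided check: the mean improvement is not significantly positive
  expect_lt(mean(diffs), 2 * sd(diffs) / sqrt(length(diffs)))
})
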