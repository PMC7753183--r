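test_that("identical seeds give bit-identical forests; different seeds differ", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- drop(scale(X[, 1] + rnorm(60)))
  cfg <- forest_config(n_trees = 50, m_try = 3, seed = 99)
  f1 <- fit_forest(X, y, cfg)
  f2 <- fit_forest(X, y, cfg)
  expect_identical(f1$fitted_values, f2$fitted_values)
  expect_identical(f1$importances, f2$importances)
  f3 <- fit_forest(X, y, cfg, seed = 100)
  expect_false(identical(f1$fitted_values, f3$fitted_values))
})

test_that("a step-function signal concentrates importance on its predictor", {
  set.seed(2)
  p <- 300
  X <- matrix(rnorm(p * 10), p, 10, dimnames = list(NULL, paste0("P", 1:10)))
  y <- ifelse(X[, 1] > 0, 1, -1)  # noiseless 2-level step of predictor 1
  f <- fit_forest(X, y, forest_config(n_trees = 100, m_try = 4, seed = 3))
  imp <- f$importances
  expect_identical(names(which.max(imp)), "P1")
  expect_gt(imp[["P1"]], 5 * median(imp[-1]))
})

test_that("the degenerate config reproduces an exhaustive best stump", {
  set.seed(4)
  # single predictor: m_try = 1 is exhaustive
  x <- rnorm(40)
  y <- x^2 + 0.1 * rnorm(40)
  cfg1 <- forest_config(n_trees = 1, m_try = 1, max_leaf_nodes = 2,
                        bootstrap = FALSE, seed = 5)
  f <- fit_forest(matrix(x, ncol = 1, dimnames = list(NULL, "P1")), y, cfg1)
  oracle <- brute_stump_1d(x, y)
  expect_equal(f$fitted_values, oracle$fitted, tolerance = 1e-12)
  expect_equal(f$importances[["P1"]], oracle$gain, tolerance = 1e-12)
  # multiple predictors, m_try = all: exhaustive over predictors too
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("P", 1:4)))
  cfgq <- forest_config(n_trees = 1, m_try = 4, max_leaf_nodes = 2,
                        bootstrap = FALSE, seed = 6)
  fq <- fit_forest(X, y, cfgq)
  oq <- brute_stump(X, y)
  expect_equal(fq$fitted_values, oq$fitted, tolerance = 1e-12)
  expect_identical(names(which.max(fq$importances)), paste0("P", oq$feature))
})

test_that("never-selected predictors have importance exactly 0", {
  set.seed(7)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("P", 1:6)))
  y <- X[, 2]
  # one stump per tree, all predictors visible: only P2 is ever split on
  f <- fit_forest(X, y, forest_config(n_trees = 20, m_try = 6,
                                      max_leaf_nodes = 2, seed = 8))
  expect_true(all(f$importances[paste0("P", c(1, 3:6))] == 0))
  expect_gt(f$importances[["P2"]], 0)
  expect_true(all(f$importances >= 0))
})

test_that("a single 2-leaf tree predicts at most 2 distinct values", {
  set.seed(9)
  x <- rnorm(50)
  y <- x + rnorm(50)
  f <- fit_forest(matrix(x, ncol = 1), y,
                  forest_config(n_trees = 1, m_try = 1, max_leaf_nodes = 2,
                                seed = 10))
  expect_lte(length(unique(f$fitted_values)), 2L)
})

test_that("forest in-sample SSE never exceeds the constant-mean SSE", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    X <- matrix(rnorm(80 * 5), 80, 5)
    y <- drop(scale(X[, 1] * X[, 2] + rnorm(80)))
    f <- fit_forest(X, y, forest_config(n_trees = 50, m_try = 2, seed = seed))
    expect_lte(sum((y - f$fitted_values)^2), sum((y - mean(y))^2))
  }
})

test_that("permuting predictor columns permutes importances (all-predictor sampling)", {
  # With m_try = all predictors no RNG draw depends on column order, so the
  # forest is permutation-equivariant up to exact gain ties. Stump forests
  # split on the full root sample, where ties are not a concern.
  set.seed(14)
  X <- matrix(rnorm(70 * 5), 70, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- drop(scale(X[, 1] + X[, 4]^2 + rnorm(70)))
  cfg <- forest_config(n_trees = 30, m_try = 5, max_leaf_nodes = 2, seed = 15)
  f <- fit_forest(X, y, cfg)
  perm <- c(3, 5, 1, 2, 4)
  fp <- fit_forest(X[, perm], y, cfg)
  expect_identical(fp$fitted_values, f$fitted_values)
  expect_identical(unname(fp$importances), unname(f$importances[perm]))
  # deeper trees: equal-gain ties at small nodes can reattribute importance
  # across columns, but without bootstrap the partition (hence the fitted
  # values) is still permutation-invariant
  cfg4 <- forest_config(n_trees = 30, m_try = 5, max_leaf_nodes = 4,
                        bootstrap = FALSE, seed = 16)
  f4 <- fit_forest(X, y, cfg4)
  fp4 <- fit_forest(X[, perm], y, cfg4)
  expect_identical(fp4$fitted_values, f4$fitted_values)
})

test_that("fit_forest validates inputs", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_forest(X, rep(1, 10), forest_config(m_try = 2)),
               "degenerate target")
  expect_error(fit_forest(X, rnorm(10), forest_config(m_try = 5)),
               "m_try.*exceeds")
  expect_error(forest_config(max_leaf_nodes = 1), "at least 2")
  expect_error(forest_config(n_trees = 0), "positive")
})

test_that("RANFORC scores lie in [-1,1], are seed-reproducible, and see sign flips", {
  set.seed(16)
  base <- rnorm(150)
  pn <- ts_panel(cbind(R1 = base, R2 = -base + 0.1 * rnorm(150),
                       R3 = rnorm(150), R4 = rnorm(150), R5 = rnorm(150)))
  cfg <- forest_config(n_trees = 100, m_try = 3, seed = 17)
  sc <- ranforc_subject(pn, cfg)$scores
  expect_true(all(abs(sc) <= 1))
  expect_identical(ranforc_subject(pn, cfg)$scores, sc)
  # the anticorrelated pair out-scores the panel median
  expect_gt(sc[["R1"]], median(sc))
  expect_gt(sc[["R2"]], median(sc))
})

test_that("per-fit seed streams are stable to the subject's identity only", {
  pn <- rand_panel(18, p = 60, N = 4, id = "subA")
  cfg <- forest_config(n_trees = 20, m_try = 2, seed = 19)
  sc1 <- ranforc_subject(pn, cfg)$scores
  pn2 <- ts_panel(pn$data, pn$region_labels, "subB")
  sc2 <- ranforc_subject(pn2, cfg)$scores
  expect_false(identical(sc1, sc2))  # different subject, different stream
  expect_identical(ranforc_subject(pn, cfg)$scores, sc1)
})

test_that("quadratic-only coupling is seen by RANFORC but not RIDGEC", {
  rules <- list(list(target = 1, sources = 2, weight = 1, form = "quadratic"))
  pn <- generate_panel(panel_spec(N = 8, p = 300, ar_phi = 0.3,
                                  coupling = rules, seed = 20))
  rf <- ranforc_subject(pn, forest_config(n_trees = 200, m_try = 4, seed = 21))
  rid <- ridgec_subject(pn, lambda = 10)
  expect_gt(rf$scores[["R1"]], rid$scores[["R1"]])
})

test_that("importance matrix is nonnegative with an NA diagonal", {
  pn <- rand_panel(22, p = 60, N = 5)
  res <- ranforc_subject(pn, forest_config(n_trees = 20, m_try = 3, seed = 23),
                         keep_importances = TRUE)
  im <- res$importances
  expect_true(all(is.na(diag(im))))
  expect_true(all(im[row(im) != col(im)] >= 0))
})

test_that("out-of-bag scoring runs and stays within [-1,1]", {
  pn <- rand_panel(24, p = 80, N = 4)
  cfg <- forest_config(n_trees = 100, m_try = 2, seed = 25, scoring = "oob")
  sc <- ranforc_subject(pn, cfg)$scores
  expect_true(all(abs(sc) <= 1))
})
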