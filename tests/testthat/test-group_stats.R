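make_maps <- function(n, N, seed, method = "ridgec", fisher = TRUE,
                      scores_fun = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(s) {
    sc <- if (is.null(scores_fun)) rnorm(N, 0, 0.3) else scores_fun(s)
    names(sc) <- paste0("R", seq_len(N))
    connectivity_vector(sc, method, sprintf("sub%03d", s), fisher_z = fisher)
  })
}

test_that("group_average reduces correctly and matches a loop oracle", {
  maps <- make_maps(5, 4, seed = 1)
  expect_equal(group_average(maps[c(1, 1)]), maps[[1]]$scores)
  neg <- maps[[1]]; neg$scores <- -neg$scores; neg$subject_id <- "neg"
  expect_equal(unname(group_average(list(maps[[1]], neg))), rep(0, 4))
  avg <- group_average(maps)
  oracle <- sapply(1:4, function(j) mean(sapply(maps, function(m) m$scores[j])))
  expect_equal(unname(avg), oracle)
  bad <- maps; bad[[2]]$method <- "ranforc"
  expect_error(group_average(bad), "mixed")
})

test_that("two_sample_t is the pooled-variance Student t", {
  set.seed(2)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  r <- two_sample_t(a, b)
  # independent oracle
  o <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r$df, unname(o$parameter))
  expect_equal(r$p, o$p.value, tolerance = 1e-10)
  # identical groups: t = 0, p = 1; swap: antisymmetric t, same p
  r0 <- two_sample_t(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  rs <- two_sample_t(b, a)
  expect_equal(rs$t, -r$t, tolerance = 1e-12)
  expect_equal(rs$p, r$p, tolerance = 1e-12)
  expect_error(two_sample_t(a, 1), "at least 2")
  expect_error(two_sample_t(rep(1, 5), rep(1, 4)), "zero pooled variance")
})

test_that("ttest_from_summary agrees with two_sample_t on its own summaries", {
  set.seed(3)
  a <- rnorm(20, 1); b <- rnorm(15)
  r1 <- two_sample_t(a, b)
  r2 <- ttest_from_summary(mean(a), sd(a), 20, mean(b), sd(b), 15)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 3, 12)$t, 0)
  expect_error(ttest_from_summary(1, 1, 1, 0, 1, 10), "at least 2")
})

test_that("region_lm recovers a noiseless age effect and matches OLS oracle", {
  n <- 24
  design <- cohort_design(sprintf("s%02d", 1:n), rep(0:1, n / 2),
                          age = seq(20, 60, length.out = n))
  scores <- 0.02 * design$age
  # summary.lm warns about the (intentionally) perfect fit
  r <- suppressWarnings(region_lm(scores, design, "age + sex"))
  expect_equal(r$estimate, 0.02, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)
  # random data vs normal-equations oracle
  set.seed(4)
  y <- rnorm(n)
  r2 <- region_lm(y, design, "age + sex")
  X <- cbind(1, design$age, design$sex)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r2$estimate, beta[2], tolerance = 1e-10)
  # focal sex variant
  r3 <- region_lm(y, design, "sex + age")
  expect_equal(r3$estimate, beta[3], tolerance = 1e-10)
})

test_that("region_lm reports aliased columns on rank-deficient designs", {
  design <- cohort_design(paste0("s", 1:10), rep(1, 10), age = rep(35, 10))
  expect_error(region_lm(rnorm(10), design, "age + sex"), "aliased")
})

test_that("region_lm supports the region's gray-matter covariate", {
  n <- 30
  set.seed(5)
  gm <- matrix(rbeta(n * 3, 8, 4), n, 3, dimnames = list(NULL, paste0("R", 1:3)))
  design <- cohort_design(paste0("s", 1:n), rep(0:1, 15),
                          age = runif(n, 20, 60), gm = gm)
  y <- 0.01 * design$age + rnorm(n, 0, 0.05)
  r_plain <- region_lm(y, design, "age + sex")
  r_gm <- region_lm(y, design, "age + sex + gm", gm_region = "R2")
  # gm is independent of the scores: focal estimate barely moves
  se <- sqrt(0.05^2 / var(design$age) / n)
  expect_lt(abs(r_gm$estimate - r_plain$estimate), 2 * se)
  expect_error(region_lm(y, design, "age + sex + gm"), "gm_region")
})

test_that("permuting age destroys the association detected by region_lm", {
  n <- 40
  ok <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    design <- cohort_design(paste0("s", 1:n), rep(0:1, n / 2),
                            age = runif(n, 20, 60))
    y <- rnorm(n)  # null scores
    design_perm <- design
    design_perm$age <- sample(design$age)
    t_obs <- abs(region_lm(y, design_perm, "age + sex")$t)
    t_null <- replicate(100, {
      d <- design; d$age <- sample(design$age)
      abs(region_lm(y, d, "age + sex")$t)
    })
    if (t_obs <= quantile(t_null, 0.99)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)  # >= 95% of replicates
})

test_that("fdr_bh implements the step-up rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_bh(rep(1, 6))$reject, rep(FALSE, 6))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  # invariance to input order; adjusted p monotone in raw p
  set.seed(6)
  p <- runif(30)
  o <- sample(30)
  r1 <- fdr_bh(p); r2 <- fdr_bh(p[o])
  expect_identical(r1$reject[o], r2$reject)
  expect_equal(r1$p_adjusted[o], r2$p_adjusted)
  expect_true(all(diff(r1$p_adjusted[order(p)]) >= -1e-15))
  # adjusted p agrees with the stats reference implementation
  expect_equal(r1$p_adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("group_pipeline with one region reduces to the raw test", {
  n <- 20
  set.seed(7)
  maps <- lapply(1:n, function(s) {
    sc <- c(R1 = rnorm(1, 0, 0.2))
    connectivity_vector(sc, "ridgec", sprintf("sub%03d", s))
  })
  design <- cohort_design(sprintf("sub%03d", 1:n), rep(0:1, n / 2),
                          age = runif(n, 20, 60))
  res <- group_pipeline(maps, design, "age_regression")
  expect_identical(nrow(res), 1L)
  expect_equal(res$p_adjusted, res$p)
  direct <- region_lm(atanh(sapply(maps, function(m) m$scores)), design,
                      "age + sex")
  expect_equal(res$t, direct$t, tolerance = 1e-12)
})

test_that("group_pipeline sex analysis uses the matched subsample", {
  n <- 30
  set.seed(8)
  sex <- rep(0:1, 15)
  maps <- lapply(1:n, function(s) {
    sc <- c(R1 = rnorm(1, 0.5 * sex[s], 0.2), R2 = rnorm(1, 0, 0.2))
    connectivity_vector(sc, "ranforc", sprintf("sub%03d", s))
  })
  matched <- c(rep(TRUE, 20), rep(FALSE, 10))
  design <- cohort_design(sprintf("sub%03d", 1:n), sex,
                          age = runif(n, 20, 60), matched = matched)
  res <- group_pipeline(maps, design, "sex_ttest_matched")
  z <- atanh(sapply(maps, function(m) m$scores["R1"]))
  manual <- two_sample_t(z[matched & sex == 1], z[matched & sex == 0])
  expect_equal(res$t[res$region == "R1"], manual$t, tolerance = 1e-12)
  expect_identical(res$df[1], 18)
  expect_true(res$significant[res$region == "R1"])
})
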