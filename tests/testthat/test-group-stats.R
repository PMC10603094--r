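test_that("normality gate routes to the appropriate test", {
  spec <- simulation_spec(seed = 41)
  g <- generate_group_table(spec, n_per_group = 30, shift = 1)
  plan <- choose_test(g$value, g$condition)
  expect_equal(plan$test, "t")
  expect_true(plan$normal)

  gl <- generate_group_table(simulation_spec(seed = 42), n_per_group = 60,
                             distribution = "lognormal", sd = 1)
  plan2 <- choose_test(gl$value, gl$condition)
  expect_equal(plan2$test, "mann_whitney")

  set.seed(43)
  vals <- rnorm(40); grp <- rep(letters[1:4], each = 10)
  expect_equal(choose_test(vals, grp)$test, "kruskal_dunn")
  # pairing promotes to the paired t-test
  gp <- generate_group_table(simulation_spec(seed = 44), n_per_group = 10)
  plan3 <- choose_test(gp$value, gp$condition, pairing = rep(1:10, 2))
  expect_equal(plan3$test, "paired_t")
  expect_error(choose_test(c(1, 2, 1, 2), c("a", "a", "b", "b")), "n >= 3")
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  plan <- structure(list(test = "mann_whitney"), class = "test_plan")
  # hand case: A = {1,2}, B = {3,4} -> two-tailed p = 1/3
  r <- run_tests(plan, c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw_exact_p_enum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:15) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)   # continuous: tie-free
    p_pkg <- run_tests(plan, c(a, b), rep(c("a", "b"), c(na, nb)))$p
    expect_equal(p_pkg, mw_exact_p_enum(a, b), tolerance = 1e-12)
  }
  # perfectly interleaved groups (U at its null expectation): p = 1
  p_null <- run_tests(plan, c(1, 4, 5, 8, 2, 3, 6, 7),
                      rep(c("a", "b"), each = 4))$p
  expect_gte(p_null, 0.9)
})

test_that("Kruskal-Wallis plus Dunn behaves on null and ordered groups", {
  vals <- rep(c(1, 2, 3, 4, 5), 3)
  grp <- rep(c("a", "b", "c"), each = 5)
  plan <- structure(list(test = "kruskal_dunn"), class = "test_plan")
  r <- run_tests(plan, vals, grp)
  expect_gte(r$p, 0.99)                   # three identical groups
  expect_equal(nrow(r$comparisons), 3)    # all pairs
  expect_true(all(r$comparisons$p_adjusted >= r$comparisons$p))

  # all-vs-control family has k-1 comparisons
  d <- dunn_test(vals, grp, control = "a")
  expect_equal(nrow(d), 2)
  expect_equal(d$group1, c("a", "a"))

  # strongly separated groups: omnibus and extreme pair significant
  set.seed(11)
  vals2 <- c(rnorm(8), rnorm(8, 5), rnorm(8, 10))
  r2 <- run_tests(plan, vals2, grp <- rep(c("a", "b", "c"), each = 8))
  expect_lt(r2$p, 0.001)
  ac <- r2$comparisons[r2$comparisons$group1 == "a" &
                         r2$comparisons$group2 == "c", ]
  expect_lt(ac$p_adjusted, 0.01)
})

test_that("Cohen's d matches hand computation and its invariances", {
  d <- cohens_d(c(1, 2, 3), c(3, 4, 5))
  expect_equal(d$d, 2)
  expect_equal(d$se, sqrt(6 / 9 + 4 / 12), tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 6), c(5, 6))$d, 0)
  set.seed(12)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(2 * a, 2 * b)$d, cohens_d(a, b)$d, tolerance = 1e-12)
  expect_equal(cohens_d(b, a)$d, -cohens_d(a, b)$d, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("common-language effect size counts exceedance pairs", {
  expect_equal(cles_theta(c(1, 3), c(2, 4))$theta, 0.25)
  expect_equal(cles_theta(c(10, 11), c(1, 2))$theta, 1)
  set.seed(13)
  x <- rnorm(15)
  expect_equal(cles_theta(x, x)$theta, 0.5)      # ties counted half
  a <- rnorm(9); b <- rnorm(11)
  expect_equal(cles_theta(a, b)$theta + cles_theta(b, a)$theta, 1,
               tolerance = 1e-12)
  # U-statistic SE shrinks with n and is 0 for complete separation
  big <- cles_theta(rnorm(200), rnorm(200, 0.3))
  sml <- cles_theta(rnorm(10), rnorm(10, 0.3))
  expect_lt(big$se, sml$se + 0.1)
})

test_that("the boundary decision rule gates significance", {
  expect_true(significance_decision(0.01, 0.9, 0.05, 0.5)$significant)
  expect_false(significance_decision(0.01, 0.52, 0.05, 0.5)$significant)
  expect_false(significance_decision(0.2, 0.9, 0.01, 0.5)$significant)
  # alternate "beyond" reading: point estimate past the boundary suffices
  r <- significance_decision(0.01, 1.05, 0.5, boundary = 1, rule = "beyond")
  expect_true(r$significant)
  expect_false(significance_decision(0.01, 1.05, 0.5, boundary = 1,
                                     rule = "exclude")$significant)
})

test_that("percent change and delta-delta-Ct follow their conventions", {
  expect_equal(percent_change(10, 5), 50)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 5), "zero control")
  # constructed 41% reduction
  ctrl <- rep(100, 5); trt <- rep(59, 5)
  expect_equal(percent_change(mean(ctrl), mean(trt)), 41)

  expect_equal(ddct_fold_change(15, 15, 15, 15)$fold_change, 1)
  expect_equal(ddct_fold_change(22, 21, 15, 15)$ddct, -1)
  expect_equal(ddct_fold_change(22, 21, 15, 15)$fold_change, 2)
  expect_equal(ddct_fold_change(22, 20, 15, 15)$fold_change, 4)
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})
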