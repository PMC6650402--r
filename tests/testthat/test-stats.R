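test_that("Steel test reproduces the exact micro-example and its oracle", {
  st <- steel_test(c(1, 2), list(trt = c(3, 4)), alternative = "greater")
  expect_equal(st$table$p_adj, 1 / 6)
  expect_equal(st$method, "exact_permutation")
  expect_equal(st$n_permutations, 6)
  # brute-force enumeration oracle agrees, one- and two-sided
  expect_equal(st$table$p_adj,
               steel_oracle(c(1, 2), list(c(3, 4)), "greater"))
  st2 <- steel_test(c(1, 2), list(trt = c(3, 4)), alternative = "two.sided")
  expect_equal(st2$table$p_adj,
               steel_oracle(c(1, 2), list(c(3, 4)), "two.sided"))
})

test_that("Steel test matches the enumeration oracle on multi-treatment data", {
  set.seed(31)
  ctrl <- rnorm(3)
  trts <- list(a = rnorm(3, 1), b = rnorm(3, -0.5))
  st <- steel_test(ctrl, trts, alternative = "two.sided", max_exact = 2000)
  expect_equal(st$method, "exact_permutation")
  expect_equal(st$table$p_adj, steel_oracle(ctrl, trts, "two.sided"))
  # with ties present the midrank path must agree too
  ctrl_t <- c(1, 2, 2)
  trts_t <- list(a = c(2, 3, 4), b = c(1, 1, 2))
  st_t <- steel_test(ctrl_t, trts_t, alternative = "two.sided",
                     max_exact = 2000)
  expect_equal(st_t$table$p_adj, steel_oracle(ctrl_t, trts_t, "two.sided"))
})

test_that("a treatment identical to the control is never significant", {
  st <- steel_test(c(1, 2, 3), list(same = c(1, 2, 3)))
  expect_equal(st$table$p_adj, 1)
  expect_warning(steel_test(c(5, 5), list(a = c(5, 5), b = c(5, 5))),
                 "tied")
})

test_that("single-treatment exact Steel reduces to the exact Wilcoxon rank-sum test", {
  for (seed in 1:3) {
    set.seed(seed)
    ctrl <- rnorm(4)
    trt <- rnorm(4, 0.8)
    st <- steel_test(ctrl, list(t = trt), alternative = "greater")
    wt <- stats::wilcox.test(trt, ctrl, alternative = "greater",
                             exact = TRUE)
    expect_equal(st$table$p_adj, wt$p.value)
  }
})

test_that("Monte-Carlo and exact Steel p-values agree within sampling error", {
  run_both <- function(ctrl, trts) {
    ex <- steel_test(ctrl, trts, max_exact = 40000)
    mc <- steel_test(ctrl, trts, max_exact = 1, n_perm = 10000, seed = 99)
    expect_equal(ex$method, "exact_permutation")
    expect_equal(mc$method, "monte_carlo")
    se <- sqrt(ex$table$p_adj * (1 - ex$table$p_adj) / 10000)
    expect_true(all(abs(mc$table$p_adj - ex$table$p_adj) <=
                      3 * se + 2e-4))
  }
  set.seed(41)
  run_both(rnorm(4), list(a = rnorm(4, 1), b = rnorm(4)))      # tie-free
  run_both(c(1, 2, 2, 3), list(a = c(2, 3, 3, 4), b = c(1, 1, 2, 2)))  # ties
})

test_that("Steel p-values are invariant under monotone transforms", {
  set.seed(51)
  ctrl <- rlnorm(4)
  trts <- list(a = rlnorm(4, 0.5), b = rlnorm(4, -0.5))
  st1 <- steel_test(ctrl, trts, max_exact = 40000)
  st2 <- steel_test(log(ctrl), lapply(trts, log), max_exact = 40000)
  expect_equal(st1$table$p_adj, st2$table$p_adj)
  expect_equal(st1$table$statistic, st2$table$statistic)
})

test_that("family-wise error is controlled (conservatively) under the null", {
  reject <- vapply(1:100, function(i) {
    set.seed(7000 + i)
    x <- matrix(rnorm(24), ncol = 6)
    st <- steel_test(x[, 1], list(a = x[, 2], b = x[, 3], c = x[, 4],
                                  d = x[, 5], e = x[, 6]),
                     n_perm = 10000, seed = 7500 + i)
    any(st$table$p_adj <= 0.05)
  }, logical(1))
  expect_lte(mean(reject), 0.05)
})

test_that("significance flags follow the conventional asterisk levels", {
  st <- steel_test(c(1, 2), list(trt = c(3, 4)), alternative = "greater")
  expect_equal(st$table$signif, "")  # p = 1/6
  expect_output(print(st), "Steel")
})

test_that("Spearman correlation on midranks with its square", {
  r <- spearman_correlation(1:5, c(1, 2, 3, 5, 4))
  expect_equal(r$rho, 0.9)
  expect_equal(r$rho_squared, 0.81)
  x <- c(0.3, 1.1, 2.5, 7, 9)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  # invariant under monotone transforms of either argument
  expect_equal(spearman_correlation(exp(x), y^3)$rho,
               spearman_correlation(x, y)$rho)
  expect_equal(spearman_correlation(1:4, 4:1)$rho, -1)
  expect_warning(r0 <- spearman_correlation(1:5, rep(2, 5)), "constant")
  expect_true(is.na(r0$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("coefficient of variation in percent, SEM or SD based", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  # sd of {9, 11} is sqrt(2); SEM = sqrt(2)/sqrt(2) = 1
  expect_equal(coefficient_of_variation(c(9, 11)), 10)
  expect_equal(coefficient_of_variation(c(9, 11), "sd"), 100 * sqrt(2) / 10)
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 100 * (2 / sqrt(3)) / 10)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
  expect_error(coefficient_of_variation(5), "length >= 2")
})
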