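test_that("spearman correlation handles monotone, anti-monotone and ties", {
  expect_equal(spearman_test(1:5, 2 * (1:5))$effect, 1)
  expect_equal(spearman_test(1:5, rev(2 * (1:5)))$effect, -1)
  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
  # ties use average ranks: rho must match cor() on midranks
  x <- c(1, 1, 2, 3, 3, 4); y <- c(2, 3, 3, 5, 6, 6)
  expect_equal(spearman_test(x, y)$effect,
               cor(rank(x), rank(y)))
})

test_that("spearman t-approximation p agrees with a permutation oracle", {
  set.seed(42)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  p_t <- spearman_test(x, y)$p_value
  obs <- abs(cor(x, y, method = "spearman"))
  perm <- replicate(10000, abs(cor(x, sample(y), method = "spearman")))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("rank-sum test matches exhaustive enumeration and detects shifts", {
  same <- c(3, 1, 4, 1, 5)
  expect_gte(ranksum_test(same, same)$p_value, 0.9)
  expect_equal(ranksum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(7)
  expect_lt(ranksum_test(rnorm(200), rnorm(200) + 2)$p_value, 1e-6)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("fisher exact test reproduces enumeration results", {
  expect_equal(fisher_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_2x2(matrix(c(-1, 0, 0, 2), 2)), "non-negative")
})

test_that("hypergeometric enrichment equals direct combinatorics", {
  expect_equal(hypergeom_enrich(2, 2, 2, 4)$p_value, 1 / 6)
  expect_equal(hypergeom_enrich(0, 3, 2, 10)$p_value, 1)
  expect_error(hypergeom_enrich(3, 2, 5, 10), "exceeds")
})

test_that("hypergeometric upper tail agrees with an urn-sampling oracle", {
  set.seed(11)
  p <- hypergeom_enrich(6, 10, 15, 60)$p_value
  draws <- replicate(100000, {
    sum(sample(c(rep(1, 15), rep(0, 45)), 10) == 1) >= 6
  })
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(mean(draws) - p), 3 * se + 1e-4)
})

test_that("binomial upper tail matches enumeration of sign vectors", {
  expect_equal(binom_upper_tail(8, 10, 0.5), 56 / 1024)
  expect_equal(binom_upper_tail(0, 10, 0.5), 1)
  expect_equal(binom_upper_tail(20, 20, 0.5), 2^-20)
  expect_error(binom_upper_tail(3, 10, 1.5), "p_e")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(3)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_gte(min(adj), min(p))
  expect_true(all(adj >= p) && all(adj <= 1))
  # a flat adjusted profile is a fixed point of the step-up rule
  expect_equal(bh_adjust(rep(0.03, 3)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Kaplan-Meier estimate matches the hand-computed product limit", {
  surv <- survival_data(c("a", "b", "c"), c(1, 2, 3), c(1, 0, 1))
  km <- km_fit(surv)
  expect_equal(km$surv_at(0), 1)
  expect_equal(km$surv_at(1), 2 / 3)
  expect_equal(km$surv_at(2.5), 2 / 3)   # censoring does not drop the curve
  expect_equal(km$surv_at(3), 0)
})

test_that("log-rank test separates planted early/late groups", {
  set.seed(5)
  surv <- survival_data(sprintf("s%03d", 1:100),
                        c(rexp(50, 0.2), rexp(50, 0.02)), rep(1, 100))
  g <- rep(c("early", "late"), each = 50)
  expect_lt(logrank_test(surv, g)$p_value, 0.001)

  dup <- survival_data(sprintf("s%03d", 1:40),
                       rep(round(rexp(20, 0.1), 2), 2), rep(1, 40))
  expect_gte(logrank_test(dup, rep(c("a", "b"), each = 20))$p_value, 0.9)
  expect_error(logrank_test(dup, rep("a", 40)), "one group")
})

test_that("univariate Cox is null-calibrated and matches the joint fit", {
  set.seed(9)
  n <- 200
  surv <- survival_data(sprintf("s%03d", 1:n), rexp(n, 0.05),
                        rbinom(n, 1, 0.8))
  x <- rnorm(n)
  f1 <- cox_fit(surv, x)
  expect_true(f1$converged)
  expect_lt(abs(f1$beta), 0.3)    # no association planted
  fm <- cox_fit_multi(surv, data.frame(x = x))
  expect_equal(fm$x$beta, f1$beta, tolerance = 1e-7)
  expect_equal(fm$x$se, f1$se, tolerance = 1e-7)
})

test_that("multivariate Cox isolates the prognostic covariate", {
  set.seed(13)
  n <- 400
  good <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  surv <- survival_data(sprintf("s%03d", 1:n),
                        rexp(n, 0.05 * exp(log(3) * good)),
                        rbinom(n, 1, 0.85))
  fits <- cox_fit_multi(surv, data.frame(good = good, noise = noise))
  expect_lt(fits$good$p_value, 1e-4)
  expect_gt(fits$noise$p_value, 0.05)
  expect_error(cox_fit_multi(surv, data.frame(good = good, k = 1)),
               "collinear|constant")
})

test_that("C-index handles separation, ties, and monotone rescaling", {
  surv <- survival_data(c("a", "b", "c", "d"), c(1, 2, 10, 12),
                        c(1, 1, 1, 1))
  expect_equal(c_index(surv, c(4, 3, 2, 1)), 1)
  # binary high/low split: the two within-group pairs are score ties and
  # count 0.5 each, so perfect 2-vs-2 separation scores 5/6
  expect_equal(c_index(surv, c(1, 1, 0, 0)), 5 / 6)
  expect_equal(c_index(surv, rep(5, 4)), 0.5)
  set.seed(21)
  sc <- rnorm(30)
  sv <- survival_data(sprintf("s%02d", 1:30), rexp(30, 0.1),
                      rbinom(30, 1, 0.7))
  expect_equal(c_index(sv, sc), c_index(sv, exp(3 * sc)))
})

test_that("C-index equals the brute-force double loop on random instances", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    time <- sample(1:8, n, replace = TRUE)     # force ties
    event <- rbinom(n, 1, 0.6)
    score <- sample(1:4, n, replace = TRUE)
    if (sum(event) == 0) event[1] <- 1
    sv <- survival_data(sprintf("s%02d", 1:n), time, event)
    expect_equal(c_index(sv, score), bf_cindex(time, event, score))
  }
})
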