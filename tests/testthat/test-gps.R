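test_that("pair enumeration is canonical and complete", {
  genes30 <- sprintf("g%02d", 1:30)
  pairs <- enumerate_gene_pairs(genes30)
  expect_equal(nrow(pairs), choose(30, 2))
  expect_true(all(pairs$gene_a < pairs$gene_b))
  expect_false(anyDuplicated(unordered_key(pairs$gene_a, pairs$gene_b)) > 0)
  expect_equal(nrow(enumerate_gene_pairs(c("b", "a"))), 1L)
  expect_error(enumerate_gene_pairs("solo"), "at least 2")
})

test_that("pair screening retains a planted reversal pair with its direction", {
  retained <- sapply(1:25, function(s) {
    set.seed(s)
    n <- 200
    z <- rbinom(n, 1, 0.5)
    expr <- matrix(rnorm(12 * n, 7, 2), 12, n,
                   dimnames = list(sprintf("g%02d", 1:12),
                                   sprintf("s%03d", 1:n)))
    expr["g01", ] <- 7 + ifelse(z == 1, 0.6, -0.6) + rnorm(n, 0, 0.1)
    expr["g02", ] <- 7 - ifelse(z == 1, 0.6, -0.6) + rnorm(n, 0, 0.1)
    surv <- survival_data(colnames(expr),
                          rexp(n, 0.02 * exp(log(4) * z)),
                          rbinom(n, 1, 0.85))
    rules <- suppressWarnings(screen_gene_pairs(
      expression_matrix(expr), surv,
      enumerate_gene_pairs(rownames(expr))))
    i <- which(rules$gene_a == "g01" & rules$gene_b == "g02")
    length(i) == 1 && rules$direction[i] == "a_gt_b_risky"
  })
  expect_gte(sum(retained), 24)
})

test_that("degenerate pairs are excluded from the screen", {
  e <- tiny_expr(4, 30, seed = 3)
  e["g02", ] <- e["g01", ]            # always tied: indicator constant
  surv <- survival_data(colnames(e), rexp(30, 0.05), rbinom(30, 1, 0.8))
  expect_warning(
    rules <- screen_gene_pairs(e, surv,
                               data.frame(gene_a = "g01", gene_b = "g02"),
                               fdr = 1),
    "constant|degenerate")
  expect_equal(nrow(rules), 0L)
})

test_that("ranking is stable, deterministic, and breaks ties as documented", {
  rules <- data.frame(
    gene_a = c("a", "c", "b"), gene_b = c("x", "y", "z"),
    beta = 1, p_value = c(0.01, 0.001, 0.001), fdr = 0.01,
    c_index = c(0.6, 0.6, 0.6), direction = "a_gt_b_risky")
  r1 <- rank_gene_pairs(rules)
  expect_equal(r1$gene_a, c("b", "c", "a"))  # p then lexicographic
  r2 <- rank_gene_pairs(rules[3:1, ])
  expect_equal(r1, r2)
})

test_that("forward selection equals an independent greedy oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- 60
    n_genes <- 8
    expr <- expression_matrix(
      matrix(rnorm(n_genes * n, 7, 1), n_genes, n,
             dimnames = list(sprintf("g%02d", 1:n_genes),
                             sprintf("s%03d", 1:n))))
    surv <- survival_data(colnames(expr), rexp(n, 0.05),
                          rbinom(n, 1, 0.8))
    cand <- suppressWarnings(screen_gene_pairs(
      expr, surv, enumerate_gene_pairs(rownames(expr)), fdr = 1.01))
    cand <- rank_gene_pairs(cand)
    cand <- head(cand, 10)
    for (pol in c("skip-and-continue", "stop-first-failure")) {
      sig <- forward_select_pairs(cand, expr, surv, policy = pol)
      oracle <- bf_forward_select(cand, expr, surv, policy = pol)
      expect_equal(sig$rules, cand[oracle$accepted, ],
                   ignore_attr = TRUE)
      path <- attr(sig, "c_index_path")
      expect_equal(path[length(path)], oracle$c_index)
      expect_true(all(diff(path) > 0))
      expect_gte(path[length(path)], path[1])
    }
  }
})

test_that("single-candidate selection returns that rule", {
  e <- tiny_expr(4, 40, seed = 5)
  surv <- survival_data(colnames(e), rexp(40, 0.05), rbinom(40, 1, 0.8))
  cand <- suppressWarnings(screen_gene_pairs(
    e, surv, data.frame(gene_a = "g01", gene_b = "g02"), fdr = 1.01))
  sig <- forward_select_pairs(cand, e, surv)
  expect_equal(nrow(sig$rules), 1L)
})

test_that("the fitted signature object behaves like a classed model fit", {
  cfg <- sim_config(n_genes = 80, n_samples = 150, n_planted_pairs = 3,
                    n_candidate_genes = 12, n_holdout = 50, seed = 12)
  sim <- simulate_cohort(cfg)
  fit <- suppressWarnings(reo_gps(sim$expr, sim$surv,
                                  genes = sim$truth$candidate_genes))
  expect_s3_class(fit, "reo_gps")
  expect_s3_class(fit, "gene_pair_signature")
  expect_true(all(diff(fit$c_index_path) > 0))
  expect_equal(unname(fit$cascade["candidate_genes"]), 12)
  expect_lte(unname(fit$cascade["signature_pairs"]),
             unname(fit$cascade["set1_pairs"]))
  expect_named(coef(fit))
  expect_output(print(fit), "filter cascade")
  lab <- predict(fit, sim$holdout_expr)
  expect_s3_class(lab, "factor")
  expect_equal(length(lab), 50L)
  sc <- predict(fit, sim$holdout_expr, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
  rep <- summary(fit)
  expect_s3_class(rep, "reo_strat_report")
})

test_that("signature building fails informatively when nothing is prognostic", {
  set.seed(42)
  e <- tiny_expr(10, 60, seed = 42)
  surv <- survival_data(colnames(e), rexp(60, 0.05), rbinom(60, 1, 0.8))
  expect_error(
    suppressWarnings(reo_gps(e, surv, genes = rownames(e),
                             fdr_pairs = 1e-8)),
    "no prognostic pairs")
})

test_that("permuted survival yields chance-level hold-out discrimination", {
  cfg <- sim_config(n_genes = 80, n_samples = 200, n_planted_pairs = 3,
                    n_candidate_genes = 12, n_holdout = 100, seed = 14)
  sim <- simulate_cohort(cfg)
  set.seed(15)
  perm <- sim$surv
  perm$time <- sample(perm$time)
  perm$event <- sample(perm$event)
  hoc <- tryCatch({
    fit <- suppressWarnings(reo_gps(sim$expr, perm,
                                    genes = sim$truth$candidate_genes,
                                    fdr_pairs = 0.5))
    lab <- suppressWarnings(predict(fit, sim$holdout_expr))
    c_index(sim$holdout_surv, as.numeric(lab == "high"))
  }, error = function(e) 0.5)
  expect_lt(abs(hoc - 0.5), 0.12)
})
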