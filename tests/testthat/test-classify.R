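test_that("the bundled signature has six risky rules over eleven genes", {
  sig <- six_gps()
  expect_equal(nrow(sig$rules), 6L)
  expect_equal(length(unique(c(sig$rules$gene_a, sig$rules$gene_b))), 11L)
  expect_true(all(sig$rules$direction == "a_gt_b_risky"))
  expect_true(all(sig$rules$beta > 0))
})

test_that("majority voting follows the at-least-half rule with ties high", {
  sig <- six_gps()
  all_risky <- classify_sample(sig, six_gps_sample(rep(1, 6)))
  expect_equal(all_risky$label, "high")
  expect_equal(all_risky$votes_high, 6L)

  none <- classify_sample(sig, six_gps_sample(rep(0, 6)))
  expect_equal(none$label, "low")

  tie <- classify_sample(sig, six_gps_sample(c(1, 1, 1, 0, 0, 0)))
  expect_equal(tie$label, "high")          # 3 of 6 goes to high risk

  two <- classify_sample(sig, six_gps_sample(c(1, 1, 0, 0, 0, 0)))
  expect_equal(two$label, "low")
})

test_that("missing genes abstain and can make a sample unclassifiable", {
  sig <- six_gps()
  v <- six_gps_sample(rep(1, 6))
  one_missing <- classify_sample(sig, v[setdiff(names(v), "CHTOP")])
  expect_equal(one_missing$votes_abstain, 1L)
  expect_equal(one_missing$label, "high")

  # abstaining on more than half the rules is reported, never guessed
  few <- classify_sample(sig, v[c("CHTOP", "CAPN2", "MRPL4", "AXL")])
  expect_equal(few$votes_abstain, 4L)
  expect_true(is.na(few$label))

  expect_error(classify_sample(sig, c(foo = 1, bar = 2)), "abstain")
})

test_that("a sample's call never depends on the rest of the cohort", {
  sig <- six_gps()
  pats <- expand.grid(rep(list(0:1), 6))
  expr <- sapply(seq_len(nrow(pats)), function(i)
    six_gps_sample(as.numeric(pats[i, ])))
  colnames(expr) <- sprintf("p%02d", seq_len(ncol(expr)))
  full <- classify_cohort(sig, expr)
  solo <- classify_cohort(sig, expr[, 7, drop = FALSE])
  expect_equal(full[7, ], solo, ignore_attr = TRUE)
})

test_that("calls are invariant to monotone per-sample transforms", {
  set.seed(4)
  cfg <- sim_config(n_genes = 60, n_samples = 40, n_planted_pairs = 3,
                    n_candidate_genes = 10, n_holdout = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  sig <- six_gps()
  rules <- data.frame(gene_a = sim$truth$pairs$gene_a,
                      gene_b = sim$truth$pairs$gene_b,
                      beta = 1, p_value = 0.01, fdr = 0.01, c_index = 0.6,
                      direction = "a_gt_b_risky")
  sig <- gene_pair_signature(rules)
  base <- classify_cohort(sig, sim$expr)
  for (kind in c("exp", "affine-positive", "rank", "cube")) {
    tr <- apply_monotone_transform(sim$expr, kind)
    expect_equal(classify_cohort(sig, tr), base, info = kind)
  }
  # adding a constant to all genes of each sample also preserves orderings
  shifted <- sweep(sim$expr, 2, seq_len(ncol(sim$expr)), `+`)
  expect_equal(classify_cohort(sig, shifted), base)
})

test_that("rank differences measure within-sample gaps and are rank-invariant", {
  two <- expression_matrix(matrix(c(1, 5, 2, 7), 2, 2,
                                  dimnames = list(c("gA", "gB"),
                                                  c("s1", "s2"))))
  sig <- gene_pair_signature(data.frame(
    gene_a = "gA", gene_b = "gB", beta = -1, p_value = 0.01, fdr = 0.01,
    c_index = 0.6, direction = "a_gt_b_protective"))
  gaps <- rank_difference(sig, two)
  expect_equal(as.vector(gaps), 1)
  expect_equal(attr(gaps, "universe_size"), 2L)

  e <- tiny_expr(50, 8, seed = 6)
  e["g01", ] <- 100   # extreme separation: top vs bottom of every sample
  e["g02", ] <- -100
  sig2 <- gene_pair_signature(data.frame(
    gene_a = "g01", gene_b = "g02", beta = 1, p_value = 0.01, fdr = 0.01,
    c_index = 0.6, direction = "a_gt_b_risky"))
  expect_equal(as.vector(rank_difference(sig2, e)), 49)
  expect_equal(rank_difference(sig2, apply_monotone_transform(e, "exp")),
               rank_difference(sig2, e))
})

test_that("stratification reports recover planted hazard ratios", {
  set.seed(17)
  reps <- replicate(20, {
    n <- 400
    lab <- rbinom(n, 1, 0.5)
    surv <- survival_data(sprintf("s%03d", 1:n),
                          rexp(n, 0.03 * exp(log(3) * lab)),
                          rbinom(n, 1, 0.8))
    calls <- data.frame(sample_id = surv$sample_id, votes_high = lab,
                        votes_low = 1 - lab, votes_abstain = 0,
                        label = ifelse(lab == 1, "high", "low"))
    stratify_report(calls, surv)$cox$hr
  })
  expect_gte(mean(reps > 2 & reps < 4.5), 0.9)
})

test_that("swapping high and low inverts the hazard ratio", {
  set.seed(19)
  n <- 120
  lab <- rbinom(n, 1, 0.5)
  surv <- survival_data(sprintf("s%03d", 1:n),
                        rexp(n, 0.03 * exp(lab)), rbinom(n, 1, 0.8))
  mk <- function(l) data.frame(sample_id = surv$sample_id,
                               votes_high = as.numeric(l == "high"),
                               votes_low = as.numeric(l == "low"),
                               votes_abstain = 0, label = l)
  hi <- ifelse(lab == 1, "high", "low")
  r1 <- stratify_report(mk(hi), surv)
  r2 <- stratify_report(mk(ifelse(lab == 1, "low", "high")), surv)
  expect_equal(r1$cox$hr, 1 / r2$cox$hr, tolerance = 1e-6)
  expect_equal(r1$logrank$p_value, r2$logrank$p_value)
})

test_that("null labels give hazard-ratio intervals covering 1", {
  set.seed(23)
  n <- 300
  surv <- survival_data(sprintf("s%03d", 1:n), rexp(n, 0.03),
                        rbinom(n, 1, 0.8))
  lab <- ifelse(rbinom(n, 1, 0.5) == 1, "high", "low")
  calls <- data.frame(sample_id = surv$sample_id,
                      votes_high = as.numeric(lab == "high"),
                      votes_low = as.numeric(lab == "low"),
                      votes_abstain = 0, label = lab)
  rep <- stratify_report(calls, surv)
  expect_true(rep$cox$ci95[1] < 1 && rep$cox$ci95[2] > 1)
})

test_that("cell-line classification links resistance calls to GI50", {
  cfg <- sim_config(seed = 31)
  panel <- simulate_cell_panel(cfg)
  rules <- data.frame(gene_a = "g0001", gene_b = "g0002", beta = 1,
                      p_value = 0.01, fdr = 0.01, c_index = 0.6,
                      direction = "a_gt_b_risky")
  # build a signature from truly coupled genes: positive vs negative
  cg <- panel$truth$coupled_genes
  rules$gene_a <- names(cg)[cg > 0][1]
  rules$gene_b <- names(cg)[cg < 0][1]
  res <- classify_cell_lines(gene_pair_signature(rules), panel$expr,
                             panel$sens)
  expect_lt(res$test$p_value, 0.01)
  expect_gt(res$mean_gi50_resistant, res$mean_gi50_sensitive)

  # degenerate one-way classification warns instead of testing
  allhi <- panel$expr
  allhi[rules$gene_a, ] <- 100
  expect_warning(res2 <- classify_cell_lines(gene_pair_signature(rules),
                                             allhi, panel$sens),
                 "one way")
  expect_null(res2$test)
})
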