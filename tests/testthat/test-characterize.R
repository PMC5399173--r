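mk_labels <- function(n_high, n_low) {
  setNames(rep(c("high", "low"), c(n_high, n_low)),
           sprintf("s%03d", seq_len(n_high + n_low)))
}

test_that("DEG detection recovers planted shifts and flips with the labels", {
  set.seed(61)
  n <- 100
  labels <- mk_labels(50, 50)
  e <- matrix(rnorm(2000 * n, 7, 1), 2000, n,
              dimnames = list(sprintf("g%04d", 1:2000), names(labels)))
  planted <- sprintf("g%04d", 1:100)
  e[planted, labels == "high"] <- e[planted, labels == "high"] + 2
  e <- expression_matrix(e)
  degs <- detect_degs(e, labels)
  expect_gte(sum(planted %in% degs$gene_id), 95)
  expect_true(all(degs$direction[degs$gene_id %in% planted] ==
                    "up_in_high"))

  flipped <- setNames(ifelse(labels == "high", "low", "high"),
                      names(labels))
  degs2 <- detect_degs(e, flipped)
  shared <- intersect(degs$gene_id, degs2$gene_id)
  expect_gt(length(shared), 50)
  expect_true(all(degs$direction[match(shared, degs$gene_id)] !=
                    degs2$direction[match(shared, degs2$gene_id)]))
})

test_that("DEG detection stays near zero under identical distributions", {
  set.seed(63)
  counts <- sapply(1:5, function(i) {
    labels <- mk_labels(25, 25)
    e <- expression_matrix(
      matrix(rnorm(1000 * 50, 7, 1), 1000, 50,
             dimnames = list(sprintf("g%04d", 1:1000), names(labels))))
    nrow(detect_degs(e, labels))
  })
  expect_lte(mean(counts), 10)   # ~0 of 1000 genes expected
})

test_that("pathway enrichment singles out a fully hit pathway", {
  sets <- gene_set_collection(list(
    hit = sprintf("a%02d", 1:10),
    other = sprintf("b%02d", 1:10),
    third = sprintf("c%02d", 1:10)))
  res <- enrich_pathways(sprintf("a%02d", 1:10), sets)
  expect_equal(res$pathway[res$significant], "hit")
  expect_error(enrich_pathways(c("zz1", "zz2"), sets), "universe")
  # enrichment p matches the direct combinatorial value on the toy urn
  expect_equal(res$p_value[res$pathway == "hit"],
               bf_hyper(10, 10, 10, 30))
})

test_that("frequency contrasts find planted differences and respect labels", {
  labels <- mk_labels(90, 90)
  feat <- matrix(0, 3, 180, dimnames = list(c("all_high", "balanced",
                                              "absent"), names(labels)))
  feat["all_high", labels == "high"] <- 1
  feat["balanced", ] <- rep(c(1, 0), 90)
  res <- contrast_frequencies(feat, labels, correction = "bh")
  expect_equal(res$higher_in[res$feature_id == "all_high"], "high")
  expect_lt(res$p_fisher[res$feature_id == "all_high"], 1e-20)
  expect_equal(res$p_fisher[res$feature_id == "balanced"], 1)
  expect_false("absent" %in% res$feature_id)   # zero variance skipped

  swapped <- setNames(ifelse(labels == "high", "low", "high"),
                      names(labels))
  res2 <- contrast_frequencies(feat, swapped, correction = "bh")
  expect_equal(res$p_fisher, res2$p_fisher)
  expect_true(all(res$higher_in != res2$higher_in |
                    res$feature_id == "balanced"))
})

test_that("direction bias counts the majority side with an exact tail", {
  df <- data.frame(feature_id = paste0("f", 1:2),
                   higher_in = c("high", "low"))
  half <- direction_bias(df)
  expect_equal(half$score, 0.5)

  df321 <- data.frame(feature_id = paste0("g", 1:321),
                      higher_in = c(rep("low", 320), "high"))
  bias <- direction_bias(df321)
  expect_equal(bias$s, 320L)
  expect_equal(attr(bias, "majority_side"), "low")
  expect_equal(bias$p_binomial, binom_upper_tail(320, 321, 0.5))

  set.seed(65)
  for (i in 1:10) {
    k <- sample(2:12, 1)
    side <- sample(c("high", "low"), k, replace = TRUE)
    d <- direction_bias(data.frame(feature_id = paste0("x", 1:k),
                                   higher_in = side))
    expect_equal(d$p_binomial, bf_binom(d$s, k))
  }
})

test_that("pathway alteration prevalence matches hand enumeration", {
  m <- matrix(c(1, 0, 0,
                0, 0, 0,
                1, 1, 0,
                0, 0, 1,
                0, 0, 0), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), sprintf("s%d", 1:5)))
  sets <- gene_set_collection(list(p1 = c("gA", "gB"), p2 = "gC",
                                   p3 = "gZ"))
  res <- pathway_prevalence(m, sets)
  expect_equal(res$prevalence[res$pathway == "p1"], 2 / 5)
  expect_equal(res$prevalence[res$pathway == "p2"], 1 / 5)
  expect_true(is.na(res$prevalence[res$pathway == "p3"]))

  none <- pathway_prevalence(m * 0, sets[1:2])
  expect_true(all(none$prevalence == 0))
})

test_that("expression-omics correlation screens by sign", {
  set.seed(67)
  n <- 40
  e <- expression_matrix(
    matrix(rnorm(30 * n, 7, 1), 30, n,
           dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:n))))
  meth <- plogis(2 - 0.5 * e)        # strictly decreasing in expression
  res <- expr_omics_correlation(e, meth, sign_filter = "negative")
  expect_equal(nrow(res), 30L)
  expect_equal(nrow(expr_omics_correlation(e, meth,
                                           sign_filter = "positive")), 0L)
  indep <- matrix(runif(30 * n), 30, n, dimnames = dimnames(e))
  expect_lte(nrow(expr_omics_correlation(e, indep,
                                         sign_filter = "negative")), 2)
  expect_error(expr_omics_correlation(e[, 1:3], meth[, 1:3]),
               "4 aligned")
})

test_that("PPI link enrichment reproduces hand counts on a star graph", {
  # hub connected to a1..a3; isolated tail t1..t4 chained
  net <- ppi_network(c("hub", "hub", "hub", "t1", "t2", "t3"),
                     c("a1", "a2", "a3", "t2", "t3", "t4"))
  res <- ppi_link_enrichment(set_a = c("a1", "a2", "a3"),
                             anchors = "hub", network = net,
                             comparison = c("t1", "t2", "t3", "t4"))
  expect_equal(res$frac_a, 1)
  expect_equal(res$frac_comparison, 0)
  expect_equal(res$p_value, bf_fisher(matrix(c(3, 0, 0, 4), 2)))
  expect_error(ppi_link_enrichment("zz", "hub", net, "t1"), "empty")
})

test_that("MSI contrast matches the exact test on published-style counts", {
  # 27.71% vs 12.05% of 83 each: 23 and 10 MSI-High samples
  labels <- mk_labels(83, 83)
  msi <- setNames(rep("MSS", 166), names(labels))
  msi[names(labels)[labels == "high"][1:10]] <- "MSI-High"
  msi[names(labels)[labels == "low"][1:23]] <- "MSI-High"
  res <- msi_contrast(msi, labels)
  expect_equal(res$count_high, 10L)
  expect_equal(res$count_low, 23L)
  expect_equal(res$higher_in, "low")
  expect_lt(res$p_fisher, 0.05)
  expect_equal(res$p_fisher,
               bf_fisher(matrix(c(10, 73, 23, 60), 2)))

  swapped <- setNames(ifelse(labels == "high", "low", "high"),
                      names(labels))
  expect_equal(msi_contrast(msi, swapped)$p_fisher, res$p_fisher)

  even <- setNames(rep(c("MSI-High", "MSS"), 83), names(labels))
  expect_gt(msi_contrast(even, labels)$p_fisher, 0.9)
})

test_that("CNA binarization thresholds follow the configured mode", {
  cna <- matrix(c(-2, -1, 0, 1, 2, 0), 2, 3,
                dimnames = list(c("r1", "r2"), c("s1", "s2", "s3")))
  expect_equal(sum(binarize_cna(cna, "any")), 4)
  expect_equal(sum(binarize_cna(cna, "deep")), 2)
})
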