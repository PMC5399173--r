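# shared fixtures and independent brute-force oracles

options(reosig.verbose = FALSE)

tiny_expr <- function(n_genes = 5, n_samples = 4, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_samples, 7, 1), n_genes,
                           n_samples,
                           dimnames = list(sprintf("g%02d", 1:n_genes),
                                           sprintf("s%02d", 1:n_samples))))
}

tiny_surv <- function(n = 4, seed = 1) {
  set.seed(seed)
  survival_data(sprintf("s%02d", 1:n), round(rexp(n, 0.05), 2),
                rbinom(n, 1, 0.7))
}

# Harrell C by explicit double loop (permissible-pair definition:
# shorter time must have the event; tied times with one event usable;
# tied times with two events excluded)
bf_cindex <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      early <- if (event[i] == 1) i else j
    } else {
      early <- if (time[i] < time[j]) i else j
      if (event[early] != 1) next
    }
    late <- setdiff(c(i, j), early)
    den <- den + 1
    if (score[early] > score[late]) num <- num + 1
    else if (score[early] == score[late]) num <- num + 0.5
  }
  num / den
}

# two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins and summing probabilities <= the observed one
bf_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating every assignment of the
# pooled ranks to group A
bf_wilcox <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  idx <- combn(length(pooled), na)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  w_all <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# BH step-up by the definition: sort, p_(i) * m / i, cumulative min from
# the largest, cap at 1
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by direct combinatorics
bf_hyper <- function(hits, set_size, marked, universe) {
  ks <- hits:min(set_size, marked)
  sum(choose(marked, ks) * choose(universe - marked, set_size - ks)) /
    choose(universe, set_size)
}

# upper-tail binomial by summing the mass function
bf_binom <- function(s, k, p = 0.5) {
  if (s <= 0) return(1)
  sum(choose(k, s:k) * p^(s:k) * (1 - p)^(k - (s:k)))
}

# independent greedy forward selection over ranked rules: recompute the
# votes straight from the expression matrix and score candidate sets with
# the brute-force C-index
bf_forward_select <- function(rules, expr, surv,
                              policy = c("skip-and-continue",
                                         "stop-first-failure")) {
  policy <- match.arg(policy)
  vote_of <- function(r) {
    ind <- expr[rules$gene_a[r], surv$sample_id] >
      expr[rules$gene_b[r], surv$sample_id]
    if (rules$direction[r] == "a_gt_b_risky") as.numeric(ind)
    else as.numeric(!ind)
  }
  label_of <- function(sel) {
    vm <- vapply(sel, vote_of, numeric(nrow(surv)))
    vh <- rowSums(vm)
    as.numeric(vh >= length(sel) / 2)
  }
  ci_of <- function(sel)
    bf_cindex(surv$time, surv$event, label_of(sel))
  acc <- 1L
  best <- ci_of(acc)
  for (r in seq_len(nrow(rules))[-1]) {
    ci <- ci_of(c(acc, r))
    if (ci > best) {
      acc <- c(acc, r); best <- ci
    } else if (policy == "stop-first-failure") break
  }
  list(accepted = acc, c_index = best)
}

# expression values realizing an arbitrary vote pattern for the bundled
# six-pair signature (rule 3 and rule 6 share SLC19A1, pinned at 5)
six_gps_sample <- function(risky) {
  stopifnot(length(risky) == 6)
  v <- c(SLC19A1 = 5,
         CHTOP = if (risky[1]) 6 else 4, CAPN2 = 5,
         MRPL4 = if (risky[2]) 6 else 4, AXL = 5,
         NREP = if (risky[3]) 4 else 6,
         PUS1 = if (risky[4]) 6 else 4, LTBP2 = 5,
         MCM2 = if (risky[5]) 6 else 4, IFRD2 = 5,
         WWC2 = if (risky[6]) 4 else 6)
  v
}

unordered_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
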