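# Stage 2: gene-pair screening, C-index ranking and forward selection of
# the REO signature.  reo_gps() is the user-facing fitting function.

#' Enumerate all unordered gene pairs
#'
#' @param genes character vector of at least 2 unique gene ids.
#' @return data.frame with columns `gene_a`, `gene_b`, each unordered pair
#'   once in canonical (lexicographic) orientation.
#' @export
enumerate_gene_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  .assert(length(genes) >= 2, "need at least 2 genes to form pairs")
  idx <- combn(length(genes), 2)
  data.frame(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Screen gene pairs whose within-sample ordering predicts survival
#'
#' For each pair, the binary within-sample indicator I(gene_a > gene_b)
#' is fitted as the sole covariate of a univariate Cox model of
#' relapse-free survival.  P-values are Benjamini-Hochberg adjusted over
#' all tested pairs and pairs below the FDR threshold are retained
#' ("Set1").  The rule direction follows the sign of the coefficient
#' (beta > 0: the ordering is a risk factor).  Each retained rule also
#' carries its solo C-index, computed from the rule's own binary risk
#' vote, which is the ranking key of the next stage.
#'
#' Pairs whose indicator is constant across samples (including always-tied
#' expression) are excluded with a warning; non-converged fits are
#' excluded and logged.
#'
#' @param expr expression matrix.
#' @param surv survival data (matched by sample id).
#' @param pairs data.frame of pairs from [enumerate_gene_pairs()].
#' @param fdr FDR threshold (default 0.05).
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @return data.frame of retained rules (`gene_a`, `gene_b`, `beta`,
#'   `p_value`, `fdr`, `c_index`, `direction`), attribute `"n_tested"`.
#' @export
screen_gene_pairs <- function(expr, surv, pairs, fdr = 0.05,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .assert(all(c(pairs$gene_a, pairs$gene_b) %in% rownames(expr)),
          "pair genes absent from the expression matrix")
  shared <- .align_ids(colnames(expr), surv$sample_id, "samples")
  .assert(length(shared) >= 2, "need shared samples between expr and surv")
  e <- expr[, shared, drop = FALSE]
  sv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  y <- .as_surv(sv)
  n_const <- 0L; n_bad <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    ind <- as.numeric(e[a, ] > e[b, ])
    ok <- !is.na(ind)
    if (length(unique(ind[ok])) < 2 ||
        length(unique(ind[ok & sv$event == 1])) < 2) {
      n_const <- n_const + 1L
      next
    }
    f <- if (all(ok)) .cox1(y, ind, ties = ties)
         else .cox1(.as_surv(sv[ok, , drop = FALSE]), ind[ok], ties = ties)
    if (!f$converged) {
      n_bad <- n_bad + 1L
      next
    }
    rows[[i]] <- data.frame(
      gene_a = a, gene_b = b, beta = f$beta,
      p_value = 2 * pnorm(-abs(f$beta / f$se)), stringsAsFactors = FALSE)
  }
  if (n_const > 0)
    warning(sprintf("%d pair(s) with constant/degenerate ordering excluded",
                    n_const))
  if (n_bad > 0)
    reo_log("pair screen: %d non-converged fit(s) excluded", n_bad)
  tab <- do.call(rbind, rows)
  n_tested <- if (is.null(tab)) 0L else nrow(tab)
  if (n_tested == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      beta = numeric(), p_value = numeric(),
                      fdr = numeric(), c_index = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  tab$fdr <- bh_adjust(tab$p_value)
  keep <- tab$fdr < fdr
  out <- tab[keep, , drop = FALSE]
  out$direction <- ifelse(out$beta > 0, "a_gt_b_risky", "a_gt_b_protective")
  # solo C-index from the rule's own binary risk vote
  out$c_index <- vapply(seq_len(nrow(out)), function(r) {
    ind <- as.numeric(e[out$gene_a[r], ] > e[out$gene_b[r], ])
    vote <- if (out$beta[r] > 0) ind else 1 - ind
    c_index(sv, vote)
  }, numeric(1))
  out <- out[c("gene_a", "gene_b", "beta", "p_value", "fdr", "c_index",
               "direction")]
  rownames(out) <- NULL
  reo_log("pair screen: %d pairs tested, %d retained at FDR < %g",
          n_tested, nrow(out), fdr)
  attr(out, "n_tested") <- n_tested
  out
}

#' Rank screened gene pairs by solo C-index ("Set2")
#'
#' Stable descending sort by solo C-index; ties broken by smaller p-value,
#' then by lexicographic pair id, so the order never depends on the input
#' order.
#'
#' @param rules data.frame of rules from [screen_gene_pairs()].
#' @return the same rules, reordered.
#' @export
rank_gene_pairs <- function(rules) {
  if (nrow(rules) <= 1) return(rules)
  o <- order(-rules$c_index, rules$p_value, rules$gene_a, rules$gene_b)
  out <- rules[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-select a gene-pair signature by training C-index ("Set3")
#'
#' Seeds the signature with the top-ranked rule, then walks down the
#' ranked list: each rule is tentatively added, all samples are
#' re-classified by majority vote, and the rule is kept only when the
#' C-index of the resulting binary risk labels strictly increases.  Under
#' the default `"skip-and-continue"` policy a rule that fails to increase
#' the C-index is skipped and the scan continues down the list;
#' `"stop-first-failure"` instead halts the walk at the first failure.
#' The stricter stop policy mirrors a literal single-run reading of
#' "add until the C-index does not increase", but a single sampling
#' fluctuation then discards every remaining candidate, so the tolerant
#' scan is the default.
#'
#' @param rules ranked rules from [rank_gene_pairs()] (at least 1).
#' @param expr training expression matrix.
#' @param surv training survival data.
#' @param policy `"skip-and-continue"` (default) or `"stop-first-failure"`.
#' @return a [gene_pair_signature()]; attribute `"c_index_path"` records
#'   the training C-index after each accepted rule.
#' @export
forward_select_pairs <- function(rules, expr, surv,
                                 policy = c("skip-and-continue",
                                            "stop-first-failure")) {
  policy <- match.arg(policy)
  .assert(nrow(rules) >= 1, "need at least one candidate rule")
  shared <- .align_ids(colnames(expr), surv$sample_id, "samples")
  e <- expr[, shared, drop = FALSE]
  sv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  sig_all <- gene_pair_signature(rules)
  votes <- .vote_matrix(sig_all, e)       # rules x samples risk votes
  score_of <- function(sel) {
    v <- votes[sel, , drop = FALSE]
    calls <- .calls_from_votes(v)
    as.numeric(calls$label == "high")     # NA for unclassifiable
  }
  accepted <- 1L
  best <- c_index(sv, score_of(accepted))
  path <- best
  for (r in seq_len(nrow(rules))[-1]) {
    ci <- c_index(sv, score_of(c(accepted, r)))
    if (ci > best) {
      accepted <- c(accepted, r)
      best <- ci
      path <- c(path, best)
    } else if (policy == "stop-first-failure") {
      break
    }
  }
  sig <- gene_pair_signature(rules[accepted, , drop = FALSE],
                             provenance = sprintf(
                               "forward-selected from %d ranked pairs (policy %s)",
                               nrow(rules), policy))
  attr(sig, "c_index_path") <- path
  reo_log("forward selection: %d of %d rules accepted, training C-index %.3f",
          length(accepted), nrow(rules), best)
  sig
}

#' Fit a REO gene-pair prognostic signature
#'
#' The full signature-building procedure on a training cohort: enumerate
#' all unordered pairs of the candidate genes, screen each pair's
#' within-sample ordering against survival with a univariate Cox model
#' (FDR-controlled, "Set1"), rank the surviving rules by their solo
#' C-index ("Set2"), and forward-select the final signature by training
#' C-index ("Set3").  Because every rule is a within-sample comparison,
#' the fitted signature and all its classifications are invariant to any
#' strictly monotone per-sample transform of the expression data.
#'
#' @param expr training expression matrix (genes x samples, log2 scale).
#' @param surv training survival data ([survival_data()]).
#' @param genes candidate gene ids (e.g. the clinically relevant
#'   drug-resistance genes from the upstream screens).
#' @param fdr_pairs FDR threshold of the pair screen (default 0.05).
#' @param policy forward-selection policy, see [forward_select_pairs()].
#' @param ties Cox tie handling.
#' @return object of class `reo_gps` (extends `gene_pair_signature`) with
#'   components `rules`, `cascade` (counts at each stage), `train_c_index`,
#'   `training` (risk calls and stratification report on the training
#'   cohort) and `call`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @examples
#' cfg <- sim_config(n_genes = 40, n_samples = 120, n_planted_pairs = 2,
#'                   n_candidate_genes = 8, n_holdout = 0, seed = 7)
#' sim <- simulate_cohort(cfg)
#' fit <- reo_gps(sim$expr, sim$surv, genes = sim$truth$candidate_genes)
#' fit
#' @export
reo_gps <- function(expr, surv, genes, fdr_pairs = 0.05,
                    policy = c("skip-and-continue", "stop-first-failure"),
                    ties = c("efron", "breslow")) {
  policy <- match.arg(policy)
  ties <- match.arg(ties)
  cl <- match.call()
  genes <- unique(as.character(genes))
  pairs <- enumerate_gene_pairs(genes)
  reo_log("signature build: %d candidate genes -> %d unordered pairs",
          length(genes), nrow(pairs))
  set1 <- screen_gene_pairs(expr, surv, pairs, fdr = fdr_pairs, ties = ties)
  .assert(nrow(set1) >= 1, "no prognostic pairs at FDR threshold %g",
          fdr_pairs)
  set2 <- rank_gene_pairs(set1)
  sig <- forward_select_pairs(set2, expr, surv, policy = policy)
  shared <- intersect(colnames(expr), surv$sample_id)
  calls <- classify_cohort(sig, expr[, shared, drop = FALSE])
  report <- stratify_report(calls, surv)
  fit <- structure(list(
    rules = sig$rules,
    vote_threshold = sig$vote_threshold,
    provenance = sig$provenance,
    cascade = c(candidate_genes = length(genes),
                pairs_enumerated = nrow(pairs),
                pairs_tested = attr(set1, "n_tested"),
                set1_pairs = nrow(set1),
                signature_pairs = nrow(sig$rules)),
    c_index_path = attr(sig, "c_index_path"),
    train_c_index = attr(sig, "c_index_path")[length(attr(sig, "c_index_path"))],
    training = list(calls = calls, report = report,
                    surv = surv[match(shared, surv$sample_id), ,
                                drop = FALSE]),
    call = cl), class = c("reo_gps", "gene_pair_signature"))
  fit
}

#' @export
print.reo_gps <- function(x, ...) {
  cat("REO gene-pair signature fit\n")
  cat("filter cascade: ",
      paste(sprintf("%s = %d", names(x$cascade), x$cascade),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("training C-index: %.3f\n\n", x$train_c_index))
  print.gene_pair_signature(x)
  invisible(x)
}

#' @describeIn reo_gps training-set stratification summary (group sizes,
#'   log-rank test, hazard ratio, C-index).
#' @param object,x a fitted `reo_gps`.
#' @param ... unused.
#' @export
summary.reo_gps <- function(object, ...) {
  object$training$report
}

#' @describeIn reo_gps rule coefficients (log hazard ratio of each REO),
#'   named "gene_a>gene_b".
#' @export
coef.reo_gps <- function(object, ...) {
  setNames(object$rules$beta,
           paste0(object$rules$gene_a, ">", object$rules$gene_b))
}

#' @describeIn reo_gps classify new samples; `type = "label"` returns the
#'   high/low factor, `"calls"` the full vote table, `"score"` the
#'   fraction of non-abstaining rules voting high.
#' @param newdata expression matrix of samples to classify.
#' @param type output type.
#' @export
predict.reo_gps <- function(object, newdata,
                            type = c("label", "calls", "score"), ...) {
  type <- match.arg(type)
  calls <- classify_cohort(object, newdata)
  switch(type,
         label = setNames(factor(calls$label, levels = c("low", "high")),
                          calls$sample_id),
         calls = calls,
         score = setNames(
           calls$votes_high / pmax(calls$votes_high + calls$votes_low, 1),
           calls$sample_id))
}

#' @describeIn reo_gps Kaplan-Meier curves of the training risk groups.
#' @export
plot.reo_gps <- function(x, ...) {
  m <- merge(x$training$calls[!is.na(x$training$calls$label),
                              c("sample_id", "label")],
             x$training$surv, by = "sample_id")
  fit <- survival::survfit(survival::Surv(time, event) ~ label, data = m)
  plot(fit, col = c("high" = "firebrick", "low" = "steelblue")[
         sub("label=", "", names(fit$strata))],
       xlab = "months", ylab = "relapse-free survival", ...)
  legend("bottomleft", legend = sub("label=", "", names(fit$strata)),
         col = c("high" = "firebrick", "low" = "steelblue")[
           sub("label=", "", names(fit$strata))], lty = 1, bty = "n")
  invisible(x)
}
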