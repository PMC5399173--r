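# Applying a gene-pair signature: per-sample majority voting over REO
# rules.  Every call depends only on the sample's own expression values.

# risk-vote matrix: rules x samples, 1 = votes high, 0 = votes low,
# NA = abstain (gene missing).  Ties Ga == Gb make the strict indicator
# I(Ga > Gb) false.
.vote_matrix <- function(sig, expr) {
  rules <- sig$rules
  nr <- nrow(rules)
  votes <- matrix(NA_real_, nr, ncol(expr),
                  dimnames = list(NULL, colnames(expr)))
  n_ties <- 0L
  for (r in seq_len(nr)) {
    a <- rules$gene_a[r]; b <- rules$gene_b[r]
    if (!(a %in% rownames(expr)) || !(b %in% rownames(expr))) next
    ga <- expr[a, ]; gb <- expr[b, ]
    ind <- ga > gb                       # NA where either value missing
    n_ties <- n_ties + sum(ga == gb, na.rm = TRUE)
    votes[r, ] <- if (rules$direction[r] == "a_gt_b_risky") as.numeric(ind)
                  else as.numeric(!ind)
  }
  if (n_ties > 0)
    reo_log("vote matrix: %d tied expression value pair(s) (strict ordering not met)",
            n_ties)
  votes
}

.calls_from_votes <- function(votes) {
  nr <- nrow(votes)
  vh <- colSums(votes == 1, na.rm = TRUE)
  vl <- colSums(votes == 0, na.rm = TRUE)
  va <- nr - vh - vl
  active <- vh + vl
  label <- ifelse(active == 0 | va > nr / 2, NA_character_,
                  ifelse(vh >= active / 2, "high", "low"))
  data.frame(sample_id = colnames(votes), votes_high = as.integer(vh),
             votes_low = as.integer(vl), votes_abstain = as.integer(va),
             label = label, stringsAsFactors = FALSE)
}

#' Classify one sample with a gene-pair signature
#'
#' Each rule votes high risk iff its risky ordering holds in the sample
#' (for a risky rule, gene_a strictly above gene_b).  A rule abstains when
#' either gene is missing.  The sample is called high risk when the high
#' votes are at least half of the non-abstaining votes (a tie goes to high
#' risk); a sample abstaining on more than half of the rules is reported
#' unclassifiable (`label = NA`).
#'
#' @param sig a [gene_pair_signature()].
#' @param values named numeric vector of the sample's expression values
#'   (names are gene ids).
#' @param sample_id identifier used in the returned call.
#' @return one-row data.frame: `sample_id`, `votes_high`, `votes_low`,
#'   `votes_abstain`, `label`.
#' @export
classify_sample <- function(sig, values, sample_id = "sample") {
  .assert(!is.null(names(values)), "sample values must be named by gene id")
  expr <- matrix(as.numeric(values), ncol = 1,
                 dimnames = list(names(values), sample_id))
  call <- .calls_from_votes(.vote_matrix(sig, expr))
  .assert(call$votes_abstain < nrow(sig$rules),
          "all rules abstain: sample shares no genes with the signature")
  call
}

#' Classify every sample of an expression matrix
#'
#' Samples are called independently (the call for one sample never depends
#' on any other sample).  Unclassifiable samples (all rules abstaining, or
#' abstention on more than half the rules) are labelled `NA` with a
#' warning, never silently dropped.
#'
#' @param sig a [gene_pair_signature()].
#' @param expr expression matrix (genes x samples).
#' @return data.frame of per-sample calls (see [classify_sample()]).
#' @export
classify_cohort <- function(sig, expr) {
  calls <- .calls_from_votes(.vote_matrix(sig, expr))
  n_na <- sum(is.na(calls$label))
  if (n_na > 0)
    warning(sprintf("%d sample(s) unclassifiable (too many abstentions)",
                    n_na))
  reo_log("classified %d samples: %d high, %d low, %d unclassifiable",
          nrow(calls), sum(calls$label == "high", na.rm = TRUE),
          sum(calls$label == "low", na.rm = TRUE), n_na)
  calls
}

#' Mean within-sample rank difference of each signature pair
#'
#' For each rule, the mean over samples of |rank(gene_a) - rank(gene_b)|
#' where ranks are taken within each sample over all genes of the supplied
#' matrix (average ranks for ties).  Pairs separated by large rank gaps
#' are hard to reverse by measurement noise, so large values indicate a
#' robust signature.  The rank universe is the supplied matrix; its size
#' is attached as attribute `"universe_size"` because the gap scales with
#' it.
#'
#' @param sig a [gene_pair_signature()].
#' @param expr expression matrix with at least 2 genes.
#' @return named numeric vector of mean rank gaps, one per rule.
#' @export
rank_difference <- function(sig, expr) {
  .assert(nrow(expr) >= 2, "need at least 2 genes")
  ranks <- apply(expr, 2, rank, na.last = "keep")
  gaps <- vapply(seq_len(nrow(sig$rules)), function(r) {
    a <- sig$rules$gene_a[r]; b <- sig$rules$gene_b[r]
    if (!(a %in% rownames(expr)) || !(b %in% rownames(expr)))
      return(NA_real_)
    mean(abs(ranks[a, ] - ranks[b, ]), na.rm = TRUE)
  }, numeric(1))
  names(gaps) <- paste0(sig$rules$gene_a, ">", sig$rules$gene_b)
  attr(gaps, "universe_size") <- nrow(expr)
  gaps
}

#' Survival stratification report for classified samples
#'
#' Builds the standard evaluation of a risk split: per-group Kaplan-Meier
#' curves, log-rank test, univariate Cox hazard ratio of the high-risk
#' label, Harrell C-index, and (when covariates are supplied) a
#' multivariate Cox model adjusting the signature for them.
#'
#' @param calls classification calls from [classify_cohort()].
#' @param surv survival data; matched to `calls` by `sample_id`.
#' @param covariates optional covariate data.frame keyed by `sample_id`
#'   (e.g. stage, gender, age group, tumor location, MMR status, BRAF/KRAS
#'   mutation).
#' @return object of class `reo_strat_report`.
#' @export
stratify_report <- function(calls, surv, covariates = NULL) {
  m <- merge(calls[!is.na(calls$label), c("sample_id", "label")], surv,
             by = "sample_id")
  .assert(nrow(m) > 0, "no classified samples with survival data")
  n_high <- sum(m$label == "high"); n_low <- sum(m$label == "low")
  out <- list(n_high = n_high, n_low = n_low,
              km = lapply(split(m, m$label),
                          function(d) km_fit(d[c("time", "event")])))
  if (n_high == 0 || n_low == 0) {
    out$logrank <- NULL
    out$note <- "single-group classification: group comparison not applicable"
  } else {
    score <- as.numeric(m$label == "high")
    out$logrank <- logrank_test(m[c("time", "event")], m$label)
    out$cox <- cox_fit(m[c("time", "event")], score)
    out$c_index <- c_index(m[c("time", "event")], score)
    if (!is.null(covariates)) {
      mm <- merge(m, covariates, by = "sample_id")
      covdf <- data.frame(risk_high = as.numeric(mm$label == "high"),
                          mm[setdiff(names(covariates), "sample_id")],
                          stringsAsFactors = TRUE)
      out$multivariate <- cox_fit_multi(mm[c("time", "event")], covdf)
    }
  }
  structure(out, class = "reo_strat_report")
}

#' @export
print.reo_strat_report <- function(x, ...) {
  cat(sprintf("Risk stratification: %d high-risk, %d low-risk\n",
              x$n_high, x$n_low))
  if (!is.null(x$note)) {
    cat(x$note, "\n")
  } else {
    cat(sprintf("log-rank: chi-square = %.2f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
    cat(sprintf("high vs low: HR = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                x$cox$hr, x$cox$ci95[1], x$cox$ci95[2], x$cox$p_value))
    cat(sprintf("C-index = %.3f\n", x$c_index))
    if (!is.null(x$multivariate)) {
      cat("multivariate adjustment:\n")
      for (nm in names(x$multivariate)) {
        f <- x$multivariate[[nm]]
        cat(sprintf("  %-24s HR = %.2f (%.2f-%.2f), p = %.3g\n", nm,
                    f$hr, f$ci95[1], f$ci95[2], f$p_value))
      }
    }
  }
  invisible(x)
}

#' Classify cell lines as drug-resistant or sensitive
#'
#' Applies the signature to a cell-line panel, mapping the high-risk label
#' to "resistant", and compares the drug sensitivity (GI50) between the
#' resistant and sensitive groups with the Wilcoxon rank-sum test.
#'
#' @param sig a [gene_pair_signature()].
#' @param expr cell-line expression matrix.
#' @param sens [drug_sensitivity()] data for (a subset of) the lines.
#' @return list with `calls` (adds a `resistant` column), group sizes and
#'   means, and `test` (the rank-sum comparison, NULL with a warning when
#'   one group is empty).
#' @export
classify_cell_lines <- function(sig, expr, sens) {
  calls <- classify_cohort(sig, expr)
  calls$resistant <- calls$label == "high"
  m <- merge(calls, sens, by.x = "sample_id", by.y = "cell_line")
  gi_r <- m$gi50[m$resistant %in% TRUE]
  gi_s <- m$gi50[m$resistant %in% FALSE]
  test <- NULL
  if (length(gi_r) == 0 || length(gi_s) == 0) {
    warning("all cell lines classified one way: GI50 comparison skipped")
  } else {
    test <- ranksum_test(gi_r, gi_s)
  }
  list(calls = calls, n_resistant = length(gi_r), n_sensitive = length(gi_s),
       mean_gi50_resistant = if (length(gi_r)) mean(gi_r) else NA_real_,
       mean_gi50_sensitive = if (length(gi_s)) mean(gi_s) else NA_real_,
       test = test)
}
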