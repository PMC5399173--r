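# Statistical kernel shared by every pipeline stage.  Standard tests are
# delegated to base R / survival; the Harrell C-index is implemented here
# because its permissible-pair convention must match the one used by the
# signature forward selection exactly (see c_index).

.reo_test <- function(statistic, p_value, effect, n_used, ...) {
  structure(list(statistic = statistic, p_value = p_value, effect = effect,
                 n_used = n_used, ...), class = "reo_test")
}

#' @export
print.reo_test <- function(x, ...) {
  cat(sprintf("test result: statistic = %.4g, effect = %.4g, p = %.4g (n = %d)\n",
              x$statistic, x$effect, x$p_value, x$n_used))
  invisible(x)
}

#' Spearman rank correlation test
#'
#' Rho with average ranks for ties; the two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped; at
#'   least 4 complete pairs are required.
#' @return a test result with `effect` = rho.
#' @examples
#' spearman_test(1:5, c(2, 4, 6, 8, 10))$effect  # 1
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .assert(n >= 4, "need at least 4 complete pairs, got %d", n)
  .assert(length(unique(x)) > 1 && length(unique(y)) > 1,
          "correlation undefined for constant input")
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  .reo_test(statistic = tstat, p_value = p, effect = rho, n_used = n)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact when both groups have at most 12 untied observations, otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty after removing NA).
#' @return a test result with `effect` = difference of medians (a - b).
#' @export
ranksum_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .assert(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  exact <- length(a) <= 12 && length(b) <= 12
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  .reo_test(statistic = unname(wt$statistic), p_value = wt$p.value,
            effect = median(a) - median(b),
            n_used = length(a) + length(b))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided by summing hypergeometric probabilities no larger than the
#' observed table's (the R convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a test result with `effect` = odds ratio (conditional MLE).
#' @examples
#' fisher_2x2(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  .assert(all(dim(table) == c(2, 2)), "need a 2x2 table")
  .assert(all(table >= 0) && all(table == round(table)),
          "counts must be non-negative integers")
  ft <- fisher.test(table)
  ft$p.value <- min(ft$p.value, 1)   # guard tiny floating-point overshoot
  .reo_test(statistic = unname(ft$estimate), p_value = ft$p.value,
            effect = unname(ft$estimate), n_used = sum(table),
            conf_int = unname(ft$conf.int))
}

#' Hypergeometric enrichment (upper tail)
#'
#' `P(X >= hits_in_set)` where X is the overlap of a random draw of
#' `set_size` genes from `universe` with the `hits_total` marked genes.
#'
#' @param hits_in_set observed overlap.
#' @param set_size size of the gene set.
#' @param hits_total number of marked genes in the universe.
#' @param universe universe size.
#' @return a test result with `effect` = fold enrichment over expectation.
#' @examples
#' hypergeom_enrich(2, 2, 2, 4)$p_value  # 1/6
#' @export
hypergeom_enrich <- function(hits_in_set, set_size, hits_total, universe) {
  for (v in list(hits_in_set, set_size, hits_total, universe))
    .assert(.is_count(v), "all arguments must be non-negative integers")
  .assert(hits_in_set <= min(set_size, hits_total),
          "hits_in_set exceeds min(set_size, hits_total)")
  .assert(set_size <= universe && hits_total <= universe,
          "set sizes exceed the universe")
  p <- phyper(hits_in_set - 1, hits_total, universe - hits_total, set_size,
              lower.tail = FALSE)
  expected <- set_size * hits_total / universe
  .reo_test(statistic = hits_in_set, p_value = p,
            effect = if (expected > 0) hits_in_set / expected else NA_real_,
            n_used = universe)
}

#' Upper-tail cumulative binomial probability
#'
#' `P(X >= s)` for `X ~ Binomial(k, p_e)`; the null model behind the
#' concordance-score significance test (`p_e = 0.5`).
#'
#' @param s observed count, `0 <= s <= k`.
#' @param k number of trials.
#' @param p_e success probability.
#' @examples
#' binom_upper_tail(8, 10)  # 56/1024
#' @export
binom_upper_tail <- function(s, k, p_e = 0.5) {
  .assert(.is_count(s) && .is_count(k) && s <= k, "need 0 <= s <= k")
  .assert(is.numeric(p_e) && p_e >= 0 && p_e <= 1, "p_e must be in [0, 1]")
  pbinom(s - 1, k, p_e, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  .assert(all(p_values[ok] >= 0 & p_values[ok] <= 1),
          "p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

.as_surv <- function(surv) {
  if (inherits(surv, "Surv")) return(surv)
  .assert(is.data.frame(surv) && all(c("time", "event") %in% names(surv)),
          "survival data needs 'time' and 'event' columns")
  survival::Surv(surv$time, surv$event)
}

#' Kaplan-Meier estimate of the survival function
#'
#' @param surv survival data ([survival_data()] data.frame).
#' @return object of class `reo_km`: data.frame of event times with columns
#'   `time`, `n_risk`, `n_event`, `surv` plus a `surv_at(t)` evaluator
#'   (right-continuous step function, S(0) = 1).
#' @export
km_fit <- function(surv) {
  fit <- survival::survfit(.as_surv(surv) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(table = out, surv_at = sf), class = "reo_km")
}

#' @export
print.reo_km <- function(x, ...) {
  cat("Kaplan-Meier estimate:\n")
  print(x$table)
  invisible(x)
}

#' Log-rank test comparing survival between two or more groups
#'
#' @param surv survival data.
#' @param labels group labels aligned with the rows of `surv`.
#' @return a test result with the chi-square statistic and p-value.
#' @export
logrank_test <- function(surv, labels) {
  .assert(length(unique(stats::na.omit(labels))) >= 2,
          "all samples are in one group")
  .assert(sum(surv$event) >= 1, "log-rank needs at least one event")
  sd <- survival::survdiff(.as_surv(surv) ~ factor(labels))
  df <- length(sd$n) - 1
  .reo_test(statistic = sd$chisq,
            p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
            effect = NA_real_, n_used = sum(sd$n))
}

# fast univariate Cox fit used by the screening loops; identical numbers to
# coxph (same C code path) without formula overhead.  Warnings are captured
# into the convergence flag (monotone-likelihood separation etc.).
.cox1 <- function(y, x, ties = "efron", max_iter = 50) {
  ctrl <- survival::coxph.control(iter.max = max_iter, eps = 1e-9)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(matrix(as.numeric(x), ncol = 1), y, strata = NULL,
                        offset = NULL, init = NULL, control = ctrl,
                        weights = NULL, method = ties, rownames = NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  converged <- !warned && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15 && fit$iter < max_iter
  list(beta = beta, se = se, converged = converged, iter = fit$iter)
}

.cox_result <- function(beta, se, converged, n, n_event) {
  z <- beta / se
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
    p_value = 2 * pnorm(-abs(z)), z = z, converged = converged,
    n = n, n_event = n_event), class = "reo_cox")
}

#' @export
print.reo_cox <- function(x, ...) {
  cat(sprintf(
    "Cox fit: beta = %.3f (HR = %.2f, 95%% CI %.2f-%.2f), p = %.3g%s\n",
    x$beta, x$hr, x$ci95[1], x$ci95[2], x$p_value,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson partial-likelihood maximization (via the survival
#' package) with Efron tie handling by default.  Monotone-likelihood
#' separation is flagged as non-converged rather than raising an error, so
#' screening callers can exclude the fit.
#'
#' @param surv survival data.
#' @param covariate numeric covariate aligned with `surv` rows (at least 2
#'   distinct values among samples with events).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `reo_cox` with `beta`, `se`, `hr`, `ci95`,
#'   `p_value`, `converged`.
#' @export
cox_fit <- function(surv, covariate, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariate <- as.numeric(covariate)
  .assert(length(covariate) == nrow(surv),
          "covariate length does not match survival data")
  ok <- is.finite(covariate)
  ev <- surv$event[ok] == 1
  .assert(length(unique(covariate[ok][ev])) >= 2,
          "covariate has < 2 distinct values among samples with events")
  f <- .cox1(.as_surv(surv[ok, , drop = FALSE]), covariate[ok], ties = ties)
  .cox_result(f$beta, f$se, f$converged, sum(ok), sum(surv$event[ok]))
}

#' Multivariate Cox proportional-hazards fit
#'
#' @param surv survival data.
#' @param covariates data.frame or matrix of design columns aligned with
#'   `surv` rows; rows with any missing value are dropped; factors are
#'   expanded to treatment contrasts.  Collinear (including constant)
#'   columns are a hard error naming the columns.
#' @param ties `"efron"` or `"breslow"`.
#' @return named list of `reo_cox` results, one per design column, jointly
#'   fitted.
#' @export
cox_fit_multi <- function(surv, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  .assert(nrow(covariates) == nrow(surv),
          "covariates do not match survival data")
  cc <- stats::complete.cases(covariates)
  X <- model.matrix(~ ., data = covariates[cc, , drop = FALSE])[, -1,
                                                                drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1, ncol(X))]]
    stop(sprintf("collinear or constant design columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- survival::coxph(.as_surv(surv[cc, , drop = FALSE]) ~ X, ties = ties)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  names(beta) <- colnames(X)
  out <- lapply(seq_along(beta), function(j)
    .cox_result(unname(beta[j]), se[j], TRUE, sum(cc),
                sum(surv$event[cc])))
  names(out) <- colnames(X)
  out
}

#' Harrell's concordance index
#'
#' Over permissible patient pairs, the fraction in which the patient with
#' the higher risk score fails earlier (tied scores count 0.5).  A pair is
#' permissible iff the member with the shorter time has an event; for
#' equal times with exactly one event the event member is treated as the
#' earlier one; equal times with two events are excluded.
#'
#' For binary high/low risk labels, code high as the larger score.
#'
#' @param surv survival data.
#' @param risk_score numeric risk scores aligned with `surv` rows (NA
#'   scores drop the sample).
#' @return concordance index in \[0, 1\].
#' @export
c_index <- function(surv, risk_score) {
  .assert(length(risk_score) == nrow(surv),
          "risk scores do not match survival data")
  ok <- !is.na(risk_score)
  time <- surv$time[ok]; event <- surv$event[ok]
  score <- as.numeric(risk_score[ok])
  n <- length(time)
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(event, n, n) == 1; ej <- t(ei)
  # i strictly earlier with an event, or tied time where only i has the event
  perm <- (ti < tj & ei) | (ti == tj & ei & !ej)
  .assert(any(perm), "no permissible pairs under censoring")
  si <- matrix(score, n, n); sj <- t(si)
  conc <- (si > sj) + 0.5 * (si == sj)
  sum(conc[perm]) / sum(perm)
}
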