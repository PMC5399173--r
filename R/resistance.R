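# Stage 1: candidate drug-resistance genes from a cell-line panel,
# clinical filtering by survival association, and the concordance score
# linking the two screens.

#' Screen genes correlated with drug sensitivity across a cell-line panel
#'
#' Spearman correlation of each gene's expression with GI50 across the
#' shared cell lines; genes with two-sided p below `alpha` are candidate
#' drug-resistance genes.  When sensitivities are supplied as -log10 GI50
#' the correlation sign is flipped so records always carry the GI50-scale
#' sign (positive = higher expression in more resistant lines).
#'
#' @param expr cell-line expression matrix.
#' @param sens [drug_sensitivity()] data.
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame with columns `gene_id`, `rho_gi50`, `p_gi50`,
#'   `sign_gi50` (+1/-1); attribute `"n_tested"`.
#' @export
screen_gi50_genes <- function(expr, sens, alpha = 0.05) {
  shared <- .align_ids(colnames(expr), sens$cell_line, "cell lines")
  .assert(length(shared) >= 4,
          "need at least 4 shared cell lines, got %d", length(shared))
  e <- expr[, shared, drop = FALSE]
  g <- sens$gi50[match(shared, sens$cell_line)]
  flip <- identical(attr(sens, "scale"), "neglog10")
  n_const <- 0L
  rows <- lapply(rownames(e), function(gene) {
    x <- e[gene, ]
    ok <- is.finite(x) & is.finite(g)
    if (sum(ok) < 4 || length(unique(x[ok])) < 2) {
      n_const <<- n_const + 1L
      return(NULL)
    }
    t <- spearman_test(x[ok], g[ok])
    rho <- if (flip) -t$effect else t$effect
    data.frame(gene_id = gene, rho_gi50 = rho, p_gi50 = t$p_value,
               sign_gi50 = sign(rho), stringsAsFactors = FALSE)
  })
  if (n_const > 0)
    warning(sprintf("%d constant/short gene(s) skipped in GI50 screen",
                    n_const))
  tab <- do.call(rbind, rows)
  out <- tab[!is.na(tab$p_gi50) & tab$p_gi50 < alpha, , drop = FALSE]
  rownames(out) <- NULL
  reo_log("GI50 screen: %d genes tested, %d candidates at p < %g",
          nrow(tab), nrow(out), alpha)
  attr(out, "n_tested") <- nrow(tab)
  out
}

#' Screen candidate genes for survival association in treated patients
#'
#' One univariate Cox fit of relapse-free survival on each candidate
#' gene's expression values; Benjamini-Hochberg adjustment is applied
#' within the candidate list (not transcriptome-wide) and genes below the
#' FDR threshold are retained with the sign of their hazard coefficient.
#' Non-converged fits are excluded and logged.
#'
#' @param expr tumor expression matrix.
#' @param surv survival data; samples are matched by id.
#' @param candidates character vector of candidate gene ids (must be rows
#'   of `expr`).
#' @param fdr FDR threshold (default 0.20).
#' @return data.frame with columns `gene_id`, `cox_beta`, `p_rfs`,
#'   `fdr_rfs`, `sign_risk` (+1/-1); attribute `"n_tested"`.
#' @export
screen_rfs_genes <- function(expr, surv, candidates, fdr = 0.20) {
  if (length(candidates) == 0) {
    out <- data.frame(gene_id = character(), cox_beta = numeric(),
                      p_rfs = numeric(), fdr_rfs = numeric(),
                      sign_risk = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  missing <- setdiff(candidates, rownames(expr))
  .assert(length(missing) == 0, "candidate genes absent from expression: %s",
          paste(head(missing, 5), collapse = ", "))
  shared <- .align_ids(colnames(expr), surv$sample_id, "tumor samples")
  e <- expr[candidates, shared, drop = FALSE]
  sv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  y <- .as_surv(sv)
  n_bad <- 0L
  rows <- lapply(candidates, function(gene) {
    x <- e[gene, ]
    if (length(unique(x[sv$event == 1 & is.finite(x)])) < 2) {
      n_bad <<- n_bad + 1L
      return(NULL)
    }
    f <- .cox1(y, x)
    if (!f$converged) {
      n_bad <<- n_bad + 1L
      return(NULL)
    }
    p <- 2 * pnorm(-abs(f$beta / f$se))
    data.frame(gene_id = gene, cox_beta = f$beta, p_rfs = p,
               sign_risk = sign(f$beta), stringsAsFactors = FALSE)
  })
  if (n_bad > 0)
    reo_log("RFS screen: %d gene(s) excluded (non-converged or degenerate)",
            n_bad)
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    out <- data.frame(gene_id = character(), cox_beta = numeric(),
                      p_rfs = numeric(), fdr_rfs = numeric(),
                      sign_risk = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  tab$fdr_rfs <- bh_adjust(tab$p_rfs)
  tab <- tab[c("gene_id", "cox_beta", "p_rfs", "fdr_rfs", "sign_risk")]
  out <- tab[tab$fdr_rfs < fdr, , drop = FALSE]
  rownames(out) <- NULL
  reo_log("RFS screen: %d candidates tested, %d retained at FDR < %g",
          nrow(tab), nrow(out), fdr)
  attr(out, "n_tested") <- nrow(tab)
  out
}

.concordance_result <- function(s, k) {
  structure(list(k = k, s = s, score = s / k,
                 p_binomial = binom_upper_tail(s, k, 0.5)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d / %d = %.2f%% (binomial upper-tail p = %.3g)\n",
              x$s, x$k, 100 * x$score, x$p_binomial))
  invisible(x)
}

#' Concordance score between two signed gene screens
#'
#' For the genes shared by two screens, the fraction whose association
#' signs agree; under the default convention a gene is concordant when its
#' GI50-correlation sign equals its hazard sign (higher expression in
#' resistant cell lines going with higher relapse hazard).  Significance
#' is the upper-tail cumulative binomial at chance probability 0.5.
#'
#' @param signs_a,signs_b named numeric vectors of +1/-1 association signs
#'   keyed by gene id (e.g. `sign_gi50` from [screen_gi50_genes()] and
#'   `sign_risk` from [screen_rfs_genes()]).
#' @param convention `"match"` (concordant iff equal signs, default) or
#'   `"mirror"` (concordant iff opposite signs).
#' @return object of class `concordance_result` with `k`, `s`, `score`,
#'   `p_binomial`.
#' @export
concordance_score <- function(signs_a, signs_b,
                              convention = c("match", "mirror")) {
  convention <- match.arg(convention)
  .assert(!is.null(names(signs_a)) && !is.null(names(signs_b)),
          "sign vectors must be named by gene id")
  shared <- intersect(names(signs_a), names(signs_b))
  .assert(length(shared) >= 1, "no overlapping genes between the two lists")
  eq <- sign(signs_a[shared]) == sign(signs_b[shared])
  s <- if (convention == "match") sum(eq) else sum(!eq)
  .concordance_result(as.integer(s), length(shared))
}

#' Concordance of differential-expression directions across data sets
#'
#' For genes called differentially expressed in two independent data sets
#' (relative to the same high-risk vs low-risk group ordering), the
#' fraction with the same direction, with the binomial significance test.
#'
#' @param degs_a,degs_b named character vectors of directions
#'   (`"up_in_high"`/`"down_in_high"`) keyed by gene id, e.g. built from
#'   [detect_degs()] output.
#' @return object of class `concordance_result`.
#' @export
deg_concordance <- function(degs_a, degs_b) {
  .assert(!is.null(names(degs_a)) && !is.null(names(degs_b)),
          "direction vectors must be named by gene id")
  shared <- intersect(names(degs_a), names(degs_b))
  .assert(length(shared) >= 1, "no overlapping genes between the DEG lists")
  s <- sum(degs_a[shared] == degs_b[shared])
  .concordance_result(as.integer(s), length(shared))
}
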