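# Stage 3: transcriptional, genomic and epigenomic contrasts between the
# high- and low-risk groups.

.check_labels <- function(labels, ids) {
  .assert(!is.null(names(labels)), "risk labels must be named by sample id")
  .assert(all(stats::na.omit(labels) %in% c("high", "low")),
          "labels must be 'high' or 'low'")
  shared <- intersect(ids, names(labels)[!is.na(labels)])
  .assert(length(shared) > 0, "no samples shared with the risk labels")
  shared
}

#' Differentially expressed genes between the risk groups
#'
#' Per-gene Wilcoxon rank-sum test of high-risk vs low-risk samples, with
#' Benjamini-Hochberg adjustment over all tested genes.  The direction is
#' recorded relative to the high-risk group (`up_in_high` /
#' `down_in_high`), with the difference of group medians as the effect.
#'
#' @param expr expression matrix.
#' @param labels named high/low labels (e.g. from [classify_cohort()]
#'   calls: `setNames(calls$label, calls$sample_id)`).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame of significant genes (`gene_id`, `p_value`, `fdr`,
#'   `direction`, `effect`); attribute `"n_tested"`.
#' @export
detect_degs <- function(expr, labels, fdr = 0.05) {
  shared <- .check_labels(labels, colnames(expr))
  lab <- labels[shared]
  .assert(sum(lab == "high") >= 2 && sum(lab == "low") >= 2,
          "need at least 2 samples per group")
  e <- expr[, shared, drop = FALSE]
  hi <- lab == "high"
  n_skip <- 0L
  rows <- lapply(rownames(e), function(g) {
    x <- e[g, ]
    if (length(unique(x[is.finite(x)])) < 2) {
      n_skip <<- n_skip + 1L
      return(NULL)
    }
    t <- ranksum_test(x[hi], x[!hi])
    data.frame(gene_id = g, p_value = t$p_value, effect = t$effect,
               stringsAsFactors = FALSE)
  })
  if (n_skip > 0) reo_log("DEG scan: %d constant gene(s) skipped", n_skip)
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$p_value)
  tab$direction <- ifelse(tab$effect >= 0, "up_in_high", "down_in_high")
  out <- tab[tab$fdr < fdr, c("gene_id", "p_value", "fdr", "direction",
                              "effect")]
  rownames(out) <- NULL
  reo_log("DEG scan: %d genes tested, %d DEGs at FDR < %g", nrow(tab),
          nrow(out), fdr)
  attr(out, "n_tested") <- nrow(tab)
  out
}

#' Hypergeometric pathway enrichment of a gene list
#'
#' Upper-tail hypergeometric test of each set against the universe (the
#' collection's explicit universe when declared, otherwise the union of
#' its sets), Benjamini-Hochberg adjusted over sets.
#'
#' @param gene_list character vector of genes of interest.
#' @param collection a [gene_set_collection()].
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame per set: `pathway`, `hits`, `set_size`,
#'   `list_size`, `universe`, `p_value`, `fdr`, `significant`.
#' @export
enrich_pathways <- function(gene_list, collection, fdr = 0.05) {
  universe <- attr(collection, "universe") %||%
    unique(unlist(collection, use.names = FALSE))
  gene_list <- intersect(unique(gene_list), universe)
  .assert(length(gene_list) > 0,
          "gene list shares no genes with the universe")
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    hits <- length(intersect(gene_list, set))
    t <- hypergeom_enrich(hits, length(set), length(gene_list),
                          length(universe))
    data.frame(pathway = nm, hits = hits, set_size = length(set),
               list_size = length(gene_list), universe = length(universe),
               p_value = t$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$p_value)
  tab$significant <- tab$fdr < fdr
  tab[order(tab$p_value), ]
}

#' Fisher contrasts of binary feature frequencies between risk groups
#'
#' Per feature (copy-number region or mutated gene), a 2x2 Fisher exact
#' test of presence frequency in the high- vs low-risk samples.  Copy
#' number matrices should first be binarized with [binarize_cna()].
#' Correction is configurable because the two applications differ:
#' region-level copy-number contrasts use BH FDR while gene-level
#' mutation contrasts use uncorrected p-values.
#'
#' @param features binary feature x sample matrix (0/1).
#' @param labels named high/low risk labels.
#' @param threshold significance threshold on the corrected (or raw)
#'   value (default 0.05).
#' @param correction `"bh"` (default) or `"none"`.
#' @return data.frame per tested feature: `feature_id`, `count_high`,
#'   `n_high`, `count_low`, `n_low`, `p_fisher`, `fdr`, `higher_in`,
#'   `significant`.  Zero-variance features are skipped.
#' @export
contrast_frequencies <- function(features, labels, threshold = 0.05,
                                 correction = c("bh", "none")) {
  correction <- match.arg(correction)
  .assert(all(is.na(features) | features %in% c(0, 1)),
          "feature matrix must be binary")
  shared <- .check_labels(labels, colnames(features))
  lab <- labels[shared]
  f <- features[, shared, drop = FALSE]
  hi <- lab == "high"
  n_high <- sum(hi); n_low <- sum(!hi)
  rows <- lapply(rownames(f), function(id) {
    x <- f[id, ]
    ch <- sum(x[hi] == 1, na.rm = TRUE)
    cl <- sum(x[!hi] == 1, na.rm = TRUE)
    nh <- sum(!is.na(x[hi])); nl <- sum(!is.na(x[!hi]))
    if ((ch + cl) == 0 || (ch + cl) == (nh + nl)) return(NULL)
    t <- fisher_2x2(matrix(c(ch, nh - ch, cl, nl - cl), 2))
    data.frame(feature_id = id, count_high = ch, n_high = nh,
               count_low = cl, n_low = nl, p_fisher = t$p_value,
               higher_in = if (ch / nh >= cl / nl) "high" else "low",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    reo_log("frequency contrast: no variable features")
    return(data.frame(feature_id = character(), count_high = integer(),
                      n_high = integer(), count_low = integer(),
                      n_low = integer(), p_fisher = numeric(),
                      fdr = numeric(), higher_in = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  tab$fdr <- bh_adjust(tab$p_fisher)
  tab$significant <- if (correction == "bh") tab$fdr < threshold
                     else tab$p_fisher < threshold
  reo_log("frequency contrast: %d features tested (%d high / %d low), %d significant",
          nrow(tab), n_high, n_low, sum(tab$significant))
  rownames(tab) <- NULL
  tab
}

#' Binarize discrete copy-number calls
#'
#' @param cna integer matrix of GISTIC-style calls in \{-2..2\}.
#' @param mode `"any"` (default; altered iff |call| >= 1) or `"deep"`
#'   (altered iff |call| = 2).
#' @return binary matrix of the same shape.
#' @export
binarize_cna <- function(cna, mode = c("any", "deep")) {
  mode <- match.arg(mode)
  .assert(all(is.na(cna) | cna %in% (-2:2)), "CNA calls must be in -2..2")
  thr <- if (mode == "any") 1 else 2
  out <- (abs(cna) >= thr) + 0
  out
}

#' Direction bias of a set of frequency contrasts
#'
#' Given feature contrasts, tests whether the side with the higher
#' frequency is lopsided across features: s = features favoring the
#' majority side, k = total, with an upper-tail binomial p at chance 0.5.
#'
#' @param contrasts data.frame from [contrast_frequencies()] (typically
#'   pre-filtered to the significant features).
#' @return object of class `concordance_result`; the majority side is
#'   attached as attribute `"majority_side"`.
#' @export
direction_bias <- function(contrasts) {
  .assert(nrow(contrasts) >= 1, "need at least one contrast")
  k <- nrow(contrasts)
  n_high <- sum(contrasts$higher_in == "high")
  side <- if (n_high >= k - n_high) "high" else "low"
  s <- max(n_high, k - n_high)
  out <- .concordance_result(as.integer(s), k)
  attr(out, "majority_side") <- side
  out
}

#' Per-pathway prevalence of alteration in a sample group
#'
#' The fraction of samples in which at least one member gene of the
#' pathway is altered.
#'
#' @param altered binary gene x sample matrix (restricted to one risk
#'   group).
#' @param collection a [gene_set_collection()].
#' @return data.frame: `pathway`, `n_genes_present`, `n_samples_altered`,
#'   `n_samples`, `prevalence` (NA when no pathway gene is in the
#'   matrix).
#' @export
pathway_prevalence <- function(altered, collection) {
  .assert(all(is.na(altered) | altered %in% c(0, 1)),
          "alteration matrix must be binary")
  rows <- lapply(names(collection), function(nm) {
    g <- intersect(collection[[nm]], rownames(altered))
    if (length(g) == 0)
      return(data.frame(pathway = nm, n_genes_present = 0L,
                        n_samples_altered = NA_integer_,
                        n_samples = ncol(altered), prevalence = NA_real_,
                        stringsAsFactors = FALSE))
    hit <- colSums(altered[g, , drop = FALSE] == 1, na.rm = TRUE) > 0
    data.frame(pathway = nm, n_genes_present = length(g),
               n_samples_altered = sum(hit), n_samples = ncol(altered),
               prevalence = mean(hit), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes whose expression correlates with a paired omics profile
#'
#' Per-gene Spearman correlation between expression and a second
#' gene-level omics matrix (copy number dosage, promoter methylation
#' beta, ...) across the shared samples, BH-adjusted, FDR-thresholded and
#' filtered to the requested correlation sign — e.g. positive for
#' copy-number dosage effects, negative for promoter methylation
#' silencing.
#'
#' @param expr expression matrix.
#' @param omics gene x sample numeric matrix sharing gene and sample ids
#'   with `expr`.
#' @param sign_filter `"positive"` or `"negative"`.
#' @param fdr FDR threshold (default 0.05).
#' @param samples optional restriction to a sample subset (e.g. one risk
#'   group).
#' @return data.frame of passing genes: `gene_id`, `rho`, `p_value`,
#'   `fdr`; attribute `"n_tested"`.
#' @export
expr_omics_correlation <- function(expr, omics,
                                   sign_filter = c("positive", "negative"),
                                   fdr = 0.05, samples = NULL) {
  sign_filter <- match.arg(sign_filter)
  genes <- .align_ids(rownames(expr), rownames(omics), "genes")
  .assert(length(genes) > 0, "no shared genes")
  ss <- .align_ids(colnames(expr), colnames(omics), "samples")
  if (!is.null(samples)) ss <- intersect(ss, samples)
  .assert(length(ss) >= 4, "need at least 4 aligned samples, got %d",
          length(ss))
  e <- expr[genes, ss, drop = FALSE]
  o <- omics[genes, ss, drop = FALSE]
  rows <- lapply(genes, function(g) {
    x <- e[g, ]; y <- o[g, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4 || length(unique(x[ok])) < 2 ||
        length(unique(y[ok])) < 2) return(NULL)
    t <- spearman_test(x[ok], y[ok])
    data.frame(gene_id = g, rho = t$effect, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  .assert(!is.null(tab), "no testable genes")
  tab$fdr <- bh_adjust(tab$p_value)
  want <- if (sign_filter == "positive") tab$rho > 0 else tab$rho < 0
  out <- tab[tab$fdr < fdr & want, , drop = FALSE]
  rownames(out) <- NULL
  reo_log("expression-omics screen: %d genes tested, %d pass FDR < %g with %s sign",
          nrow(tab), nrow(out), fdr, sign_filter)
  attr(out, "n_tested") <- nrow(tab)
  out
}

#' Enrichment of direct PPI links to an anchor gene set
#'
#' Tests whether genes of `set_a` have a direct network edge to at least
#' one anchor gene more often than genes of the explicit comparison set
#' (2x2 Fisher exact test).  All sets are first restricted to network
#' nodes.
#'
#' @param set_a genes of interest.
#' @param anchors anchor genes (e.g. drug activity-related genes).
#' @param network a [ppi_network()].
#' @param comparison explicit comparison gene set.
#' @return a test result; the linked fractions are attached as fields
#'   `frac_a` and `frac_comparison`.
#' @export
ppi_link_enrichment <- function(set_a, anchors, network, comparison) {
  .assert(inherits(network, "ppi_network"), "not a ppi_network")
  set_a <- intersect(unique(set_a), network$nodes)
  comparison <- intersect(unique(comparison), network$nodes)
  anchors <- intersect(unique(anchors), network$nodes)
  .assert(length(anchors) > 0, "no anchor genes in the network")
  .assert(length(set_a) > 0 && length(comparison) > 0,
          "empty gene set after restriction to network nodes")
  ea <- network$edges[, 1]; eb <- network$edges[, 2]
  partners <- unique(c(eb[ea %in% anchors], ea[eb %in% anchors]))
  la <- sum(set_a %in% partners)
  lc <- sum(comparison %in% partners)
  t <- fisher_2x2(matrix(c(la, length(set_a) - la,
                           lc, length(comparison) - lc), 2))
  t$frac_a <- la / length(set_a)
  t$frac_comparison <- lc / length(comparison)
  reo_log("PPI link enrichment: %.2f%% (%d/%d) vs %.2f%% (%d/%d), p = %.3g",
          100 * t$frac_a, la, length(set_a), 100 * t$frac_comparison, lc,
          length(comparison), t$p_value)
  t
}

#' MSI-High frequency contrast between risk groups
#'
#' Binarizes microsatellite status as MSI-High vs \{MSI-Low, MSS\} and
#' compares the MSI-High frequency between the high- and low-risk groups
#' with a 2x2 Fisher exact test.
#'
#' @param msi named character vector of MSI categories.
#' @param labels named high/low risk labels.
#' @return one-row data.frame in the [contrast_frequencies()] layout with
#'   the Fisher p-value.
#' @export
msi_contrast <- function(msi, labels) {
  shared <- .check_labels(labels, names(msi)[!is.na(msi)])
  lab <- labels[shared]
  hi <- lab == "high"
  .assert(sum(hi) > 0 && sum(!hi) > 0, "a risk group is empty")
  x <- msi[shared] == "MSI-High"
  ch <- sum(x[hi]); cl <- sum(x[!hi])
  t <- fisher_2x2(matrix(c(ch, sum(hi) - ch, cl, sum(!hi) - cl), 2))
  data.frame(feature_id = "MSI-High", count_high = ch, n_high = sum(hi),
             count_low = cl, n_low = sum(!hi), p_fisher = t$p_value,
             fdr = NA_real_,
             higher_in = if (ch / sum(hi) >= cl / sum(!hi)) "high" else "low",
             significant = t$p_value < 0.05, stringsAsFactors = FALSE)
}
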