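# End-to-end orchestration: screen -> build -> classify -> report ->
# characterize, with a run manifest recording the filter cascade.

#' Run the full signature workflow from a configuration
#'
#' Stages are executed in order and each is skipped when its inputs are
#' absent from the config:
#' \enumerate{
#'   \item GI50 screen on the cell panel (needs `panel_expr` + `gi50`),
#'   \item survival screen of the candidates on the training cohort,
#'   \item concordance score linking the two screens,
#'   \item signature build ([reo_gps()]) — skipped when a `signature` is
#'     supplied instead,
#'   \item cohort classification and stratification report,
#'   \item multi-omics characterization (needs `omics`; optionally
#'     `gene_sets` and `ppi`).
#' }
#'
#' The config may be a named list or the path to a YAML file.  Inputs can
#' be given as in-memory objects or as file paths (strings are read with
#' the matching reader).  Thresholds default to `alpha_gi50 = 0.05`,
#' `fdr_genes = 0.20`, `fdr_pairs = 0.05`, `fdr_deg = 0.05`,
#' `fdr_cna = 0.05`, `p_mut = 0.05`.
#'
#' @param config named list or YAML path.  Recognized entries: `expr`,
#'   `clinical` (or `surv`/`covariates`), `panel_expr`, `gi50`,
#'   `gi50_scale`, `candidate_genes`, `signature`, `omics`, `gene_sets`,
#'   `ppi`, the thresholds above, and `out_dir`.
#' @return list with the produced artifacts (`screen`, `signature`,
#'   `calls`, `report`, `characterization`) and `manifest` (config
#'   snapshot, stage cascade counts, output paths, timestamp).  When
#'   `out_dir` is set, the signature, risk calls and manifest are also
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  .assert(is.list(config), "config must be a list or a YAML path")
  thr <- list(alpha_gi50 = 0.05, fdr_genes = 0.20, fdr_pairs = 0.05,
              fdr_deg = 0.05, fdr_cna = 0.05, p_mut = 0.05)
  for (nm in names(thr)) thr[[nm]] <- config[[nm]] %||% thr[[nm]]

  load_expr <- function(x) if (is.character(x)) read_expression(x) else x
  .assert(!is.null(config$expr), "config must name the cohort expression")
  .assert(!is.null(config$clinical) || !is.null(config$surv),
          "config must name the clinical/survival input")
  expr <- load_expr(config$expr)
  if (!is.null(config$clinical) && is.character(config$clinical)) {
    clin <- read_clinical(config$clinical)
    surv <- clin$survival; covariates <- clin$covariates
  } else {
    surv <- config$surv %||% config$clinical$survival
    covariates <- config$covariates %||% config$clinical$covariates
  }
  .assert(is.data.frame(surv), "no usable survival data in config")

  artifacts <- list()
  cascade <- c(candidate_genes = NA_integer_, crg_genes = NA_integer_,
               set1_pairs = NA_integer_, signature_pairs = NA_integer_)

  # stage 1: resistance screens
  gi50_records <- NULL; rfs_records <- NULL; conc <- NULL
  if (!is.null(config$panel_expr) && !is.null(config$gi50)) {
    panel <- load_expr(config$panel_expr)
    sens <- if (is.character(config$gi50))
      read_drug_sensitivity(config$gi50,
                            scale = config$gi50_scale %||% "gi50")
    else config$gi50
    gi50_records <- screen_gi50_genes(panel, sens, alpha = thr$alpha_gi50)
  }
  candidates <- config$candidate_genes %||%
    (if (!is.null(gi50_records))
       intersect(gi50_records$gene_id, rownames(expr))
     else rownames(expr))
  cascade["candidate_genes"] <- length(candidates)
  rfs_records <- screen_rfs_genes(expr, surv, candidates,
                                  fdr = thr$fdr_genes)
  cascade["crg_genes"] <- nrow(rfs_records)
  if (!is.null(gi50_records) && nrow(rfs_records) > 0) {
    conc <- concordance_score(
      setNames(gi50_records$sign_gi50, gi50_records$gene_id),
      setNames(rfs_records$sign_risk, rfs_records$gene_id))
  }
  artifacts$screen <- list(gi50 = gi50_records, rfs = rfs_records,
                           concordance = conc)

  # stage 2: signature
  if (!is.null(config$signature)) {
    sig <- if (is.character(config$signature)) {
      if (identical(config$signature, "builtin:6gps")) six_gps()
      else read_signature(config$signature)
    } else config$signature
    cascade["set1_pairs"] <- NA_integer_
  } else {
    build_genes <- if (nrow(rfs_records) > 0) rfs_records$gene_id
                   else candidates
    sig <- reo_gps(expr, surv, genes = build_genes,
                   fdr_pairs = thr$fdr_pairs)
    cascade["set1_pairs"] <- unname(sig$cascade["set1_pairs"])
  }
  cascade["signature_pairs"] <- nrow(sig$rules)
  artifacts$signature <- sig

  # stage 3: classify and report
  calls <- classify_cohort(sig, expr)
  artifacts$calls <- calls
  artifacts$report <- stratify_report(calls, surv, covariates)

  # stage 4: characterization
  if (!is.null(config$omics) || !is.null(config$gene_sets)) {
    labels <- setNames(calls$label, calls$sample_id)
    ch <- list()
    ch$degs <- detect_degs(expr, labels, fdr = thr$fdr_deg)
    gene_sets <- if (is.character(config$gene_sets))
      read_gene_sets(config$gene_sets) else config$gene_sets
    if (!is.null(gene_sets) && nrow(ch$degs) > 0)
      ch$enrichment <- enrich_pathways(ch$degs$gene_id, gene_sets,
                                       fdr = 0.05)
    omics <- config$omics
    if (!is.null(omics)) {
      if (!is.null(omics$cna)) {
        ch$cna <- contrast_frequencies(binarize_cna(omics$cna), labels,
                                       threshold = thr$fdr_cna,
                                       correction = "bh")
        if (!is.null(gene_sets))
          ch$cna_prevalence <- pathway_prevalence(
            binarize_cna(omics$cna)[, names(labels)[labels %in% "high"],
                                    drop = FALSE], gene_sets)
      }
      if (!is.null(omics$mutation)) {
        ch$mutation <- contrast_frequencies(omics$mutation, labels,
                                            threshold = thr$p_mut,
                                            correction = "none")
        sig_mut <- ch$mutation[ch$mutation$significant, , drop = FALSE]
        if (nrow(sig_mut) > 0) ch$mutation_bias <- direction_bias(sig_mut)
      }
      if (!is.null(omics$msi)) ch$msi <- msi_contrast(omics$msi, labels)
      if (!is.null(omics$methylation))
        ch$methylation <- expr_omics_correlation(expr, omics$methylation,
                                                 sign_filter = "negative",
                                                 fdr = 0.05)
    }
    if (!is.null(config$ppi) && !is.null(config$ppi_anchors) &&
        !is.null(config$ppi_comparison) && !is.null(config$ppi_set))
      ch$ppi <- ppi_link_enrichment(config$ppi_set, config$ppi_anchors,
                                    config$ppi, config$ppi_comparison)
    artifacts$characterization <- ch
  }

  manifest <- list(command = "run",
                   thresholds = thr,
                   cascade = as.list(cascade),
                   n_samples = ncol(expr), n_genes = nrow(expr),
                   n_high = sum(calls$label == "high", na.rm = TRUE),
                   n_low = sum(calls$label == "low", na.rm = TRUE),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      signature = file.path(config$out_dir, "signature.tsv"),
      calls = file.path(config$out_dir, "risk_calls.tsv"),
      manifest = file.path(config$out_dir, "manifest.yaml"))
    write_signature(if (inherits(sig, "reo_gps"))
      gene_pair_signature(sig$rules, provenance = sig$provenance)
      else sig, paths$signature)
    write.table(calls, paths$calls, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$outputs <- paths
    yaml::write_yaml(manifest, paths$manifest)
  }
  artifacts$manifest <- manifest
  reo_log("pipeline complete: cascade %s",
          paste(sprintf("%s=%s", names(cascade), cascade), collapse = ", "))
  artifacts
}
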