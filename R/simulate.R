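# Synthetic-data generator: cohorts with planted reversal gene pairs
# driving a proportional-hazards relapse process, a cell-line panel with
# GI50-coupled genes, and group-differential multi-omics profiles.  All
# generators are deterministic given the config seed; each component uses
# a fixed offset of the global seed as its substream.

#' Configuration of the synthetic study
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: a 300-patient training cohort (plus a 150-patient hold-out
#' set) with six planted reversal gene pairs of per-ordering log-hazard
#' log 3 among 400 noise genes, a 58-line cell panel with 50 GI50-coupled
#' genes, and group-differential omics frequencies mirroring published
#' colorectal contrasts (copy-number 95.6% vs 43.5%, MSI-High 12.1% vs
#' 27.7%, mutations enriched in the low-risk group).
#'
#' @param n_genes total genes in the cohort expression matrix (planted
#'   pair genes included).
#' @param n_samples training cohort size.
#' @param n_holdout additional hold-out samples drawn from the same
#'   process.
#' @param n_planted_pairs number of planted reversal gene pairs.
#' @param pair_effect log-hazard contributed by each risky ordering.
#' @param baseline_hazard baseline relapse hazard, events/month.
#' @param censor_rate independent exponential censoring rate, per month.
#' @param followup_months administrative censoring horizon.
#' @param margin_range within-sample log2 separation of a planted pair
#'   (uniform draw per pair), large relative to `pair_noise_sd` so the
#'   planted ordering is essentially deterministic given the latent state.
#' @param pair_noise_sd per-sample noise on the planted pair genes.
#' @param pair_risky_rate_high,pair_risky_rate_low probability that a
#'   planted pair shows its risky ordering in a sample of the high (resp.
#'   low) latent risk state; either may be a vector over pairs (recycled),
#'   so pair strengths can be graded.  The cohort is a two-population mixture: a
#'   latent binary risk state per sample drives all planted orderings,
#'   each an independent noisy reporter of it.  The asymmetry (risky
#'   orderings frequent in high-state samples, rare in low-state ones)
#'   mirrors heterogeneous resistance mechanisms — each high-risk tumor
#'   carries most but not all of the risky orderings — and gives the
#'   majority vote a genuine gain over every single rule.
#' @param pair_center_spacing spacing between consecutive planted-pair
#'   expression centers (centered on `expr_mean`).  The two genes of a
#'   pair swap within a narrow band around their own center; spacing the
#'   centers further apart than the band width makes comparisons between
#'   genes of different pairs constant (hence uninformative), so each
#'   planted pair's own ordering is the dominant signal for its latent
#'   state.
#' @param expr_mean,expr_sd background log2 expression distribution.
#' @param n_candidate_genes size of the candidate gene list handed to the
#'   signature builder (planted genes plus noise genes), mirroring the
#'   upstream resistance screen's output size.
#' @param n_cell_lines,n_coupled_genes,coupling,gi50_noise_sd cell-panel
#'   parameters: `coupling` is the slope tying a coupled gene's
#'   expression to the latent resistance score.
#' @param n_regions,n_diff_regions,region_freq_high,region_freq_low,region_freq_null
#'   copy-number region battery: the first `n_diff_regions` regions are
#'   altered with the group-specific frequencies, the rest with the null
#'   frequency in both groups.
#' @param n_mut_genes,n_diff_mut_genes,mut_freq_high,mut_freq_low,mut_freq_null
#'   mutation battery (differential genes are more mutated in the
#'   low-risk group).
#' @param msi_high_freq_high,msi_high_freq_low MSI-High frequency per
#'   group.
#' @param n_meth_genes,meth_coupling,meth_noise_sd methylation: beta
#'   values of coupled genes follow
#'   `plogis(-meth_coupling * z(expression) + noise)`.
#' @param batch_shift_sd standard deviation of gene-wise additive batch
#'   shifts for robustness experiments.
#' @param seed global integer seed; substreams are derived from it.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 412, n_samples = 300, n_holdout = 150,
                       n_planted_pairs = 6, pair_effect = log(3),
                       baseline_hazard = 0.02, censor_rate = 0.01,
                       followup_months = 120, margin_range = c(0.8, 1.2),
                       pair_noise_sd = 0.15, pair_center_spacing = 2,
                       pair_risky_rate_high = 0.6, pair_risky_rate_low = 0.15,
                       expr_mean = 7, expr_sd = 2,
                       n_candidate_genes = 30,
                       n_cell_lines = 58,
                       n_coupled_genes = 50, coupling = 1.2,
                       gi50_noise_sd = 0.5,
                       n_regions = 20, n_diff_regions = 10,
                       region_freq_high = 0.956, region_freq_low = 0.4348,
                       region_freq_null = 0.3,
                       n_mut_genes = 100, n_diff_mut_genes = 30,
                       mut_freq_high = 0.05, mut_freq_low = 0.25,
                       mut_freq_null = 0.05,
                       msi_high_freq_high = 0.1205,
                       msi_high_freq_low = 0.2771,
                       n_meth_genes = 50, meth_coupling = 1.5,
                       meth_noise_sd = 0.5,
                       batch_shift_sd = 1, seed = 1L) {
  cfg <- as.list(environment())
  .assert(all(unlist(cfg[grep("freq", names(cfg))]) >= 0) &&
            all(unlist(cfg[grep("^(region|mut|msi)_", names(cfg))]) <= 1),
          "frequencies must be probabilities in [0, 1]")
  .assert(cfg$n_genes >= 2 * cfg$n_planted_pairs + 1,
          "not enough genes for %d planted pairs", cfg$n_planted_pairs)
  .assert(cfg$n_planted_pairs <= choose(cfg$n_genes, 2),
          "planted pairs exceed the number of possible pairs")
  .assert(cfg$n_candidate_genes >= 2 * cfg$n_planted_pairs &&
            cfg$n_candidate_genes <= cfg$n_genes,
          "n_candidate_genes must cover the planted genes")
  .assert(cfg$n_samples >= 2 && cfg$n_holdout >= 0, "bad cohort sizes")
  .assert(cfg$baseline_hazard > 0 && cfg$censor_rate >= 0,
          "hazard rates must be positive")
  .assert(.is_count(cfg$seed %% 2^31), "seed must be an integer")
  structure(cfg, class = "sim_config")
}

# planted-pair structure (gene positions, margins) shared between the
# cohort and the cell-panel generators via a dedicated substream
.planted_structure <- function(cfg, seed) {
  set.seed((seed + 500) %% 2^31)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  pos <- sample(cfg$n_genes, 2 * cfg$n_planted_pairs)
  k <- cfg$n_planted_pairs
  list(gene_ids = gene_ids,
       pair_a = gene_ids[pos[2 * seq_len(k) - 1]],
       pair_b = gene_ids[pos[2 * seq_len(k)]],
       margins = runif(k, cfg$margin_range[1], cfg$margin_range[2]),
       centers = cfg$expr_mean +
         cfg$pair_center_spacing * (seq_len(k) - (k + 1) / 2))
}

#' Simulate a patient cohort with planted reversal gene pairs
#'
#' Background expression is i.i.d. normal on the log2 scale (log-normal
#' abundance).  Each sample carries a latent binary risk state; every
#' planted pair reports that state through which of its two genes sits
#' higher, by a margin large relative to the noise (see
#' `pair_risky_rate_high`/`pair_risky_rate_low` in [sim_config()]).
#' Relapse times follow an exponential proportional-hazards model whose
#' linear predictor is `pair_effect` times the (centered) number of risky
#' orderings; censoring is independent exponential plus an administrative
#' horizon.
#'
#' @param cfg a [sim_config()].
#' @param seed override of the config seed.
#' @return list with `expr` and `surv` (training cohort), `holdout_expr`
#'   and `holdout_surv` (when `n_holdout > 0`), and `truth` (planted pair
#'   table, per-sample risky-ordering counts, true high/low labels,
#'   candidate gene list, config).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = cfg$seed) {
  struct <- .planted_structure(cfg, seed)
  set.seed(seed %% 2^31)
  n <- cfg$n_samples + cfg$n_holdout
  gene_ids <- struct$gene_ids
  sample_ids <- sprintf("s%04d", seq_len(n))
  expr <- matrix(rnorm(cfg$n_genes * n, cfg$expr_mean, cfg$expr_sd),
                 cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
  state <- rbinom(n, 1, 0.5)          # latent per-sample risk state
  risky <- matrix(0L, cfg$n_planted_pairs, n)
  pair_a <- struct$pair_a; pair_b <- struct$pair_b
  for (p in seq_len(cfg$n_planted_pairs)) {
    ia <- match(pair_a[p], gene_ids); ib <- match(pair_b[p], gene_ids)
    center <- struct$centers[p]
    margin <- struct$margins[p]
    q_p <- rep(cfg$pair_risky_rate_high,
               length.out = cfg$n_planted_pairs)[p]
    r_p <- rep(cfg$pair_risky_rate_low,
               length.out = cfg$n_planted_pairs)[p]
    z <- rbinom(n, 1, ifelse(state == 1, q_p, r_p))
    hi <- center + margin / 2 + rnorm(n, 0, cfg$pair_noise_sd)
    lo <- center - margin / 2 + rnorm(n, 0, cfg$pair_noise_sd)
    expr[ia, ] <- ifelse(z == 1, hi, lo)
    expr[ib, ] <- ifelse(z == 1, lo, hi)
    risky[p, ] <- z
  }
  risky_count <- colSums(risky)
  lp <- cfg$pair_effect * (risky_count - cfg$n_planted_pairs / 2)
  t_event <- rexp(n, cfg$baseline_hazard * exp(lp))
  t_cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate) else Inf
  t_cens <- pmin(t_cens, cfg$followup_months)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)
  surv <- survival_data(sample_ids, time, event)
  noise_genes <- setdiff(gene_ids, c(pair_a, pair_b))
  candidates <- c(pair_a, pair_b,
                  sample(noise_genes,
                         cfg$n_candidate_genes - 2 * cfg$n_planted_pairs))
  tr <- seq_len(cfg$n_samples)
  truth <- list(
    pairs = data.frame(gene_a = pair_a, gene_b = pair_b,
                       stringsAsFactors = FALSE),
    risky_count = setNames(risky_count, sample_ids),
    label = setNames(ifelse(state == 1, "high", "low"), sample_ids),
    candidate_genes = candidates, config = cfg, seed = seed)
  out <- list(expr = expression_matrix(expr[, tr, drop = FALSE]),
              surv = surv[tr, , drop = FALSE], truth = truth)
  if (cfg$n_holdout > 0) {
    out$holdout_expr <- expression_matrix(expr[, -tr, drop = FALSE])
    out$holdout_surv <- surv[-tr, , drop = FALSE]
  }
  reo_log("simulated cohort: %d+%d samples, %d genes, %d planted pairs, %d events (train)",
          cfg$n_samples, cfg$n_holdout, cfg$n_genes, cfg$n_planted_pairs,
          sum(out$surv$event))
  out
}

#' Simulate a cell-line panel with drug-sensitivity-coupled genes
#'
#' A latent per-line resistance score generates both the GI50 values and,
#' through a signed linear coupling, the expression of the coupled genes;
#' the remaining genes are independent noise.  The panel shares the
#' cohort's gene universe and the planted pair genes are among the
#' coupled genes — the first gene of each pair positively, the second
#' negatively — so (i) the resistance screen and the survival screen find
#' sign-concordant genes, as the concordance score assumes, and (ii) a
#' signature fitted on the cohort calls high-GI50 lines resistant.
#'
#' @param cfg a [sim_config()].
#' @param seed override of the derived substream seed (the planted
#'   structure always follows the config seed so it matches the cohort).
#' @return list with `expr`, `sens` ([drug_sensitivity()], GI50 scale) and
#'   `truth` (coupled genes with their GI50-scale signs, latent score).
#' @export
simulate_cell_panel <- function(cfg = sim_config(),
                                seed = cfg$seed + 1000L) {
  struct <- .planted_structure(cfg, cfg$seed)
  set.seed(seed %% 2^31)
  line_ids <- sprintf("cl%03d", seq_len(cfg$n_cell_lines))
  gene_ids <- struct$gene_ids
  score <- rnorm(cfg$n_cell_lines)
  gi50 <- score + rnorm(cfg$n_cell_lines, 0, cfg$gi50_noise_sd)
  expr <- matrix(rnorm(cfg$n_genes * cfg$n_cell_lines, cfg$expr_mean, 1),
                 cfg$n_genes, cfg$n_cell_lines,
                 dimnames = list(gene_ids, line_ids))
  planted <- c(rbind(struct$pair_a, struct$pair_b))
  planted_signs <- rep(c(1, -1), cfg$n_planted_pairs)
  n_extra <- max(0, cfg$n_coupled_genes - length(planted))
  extra <- sample(setdiff(gene_ids, planted), n_extra)
  coupled <- c(planted, extra)
  signs <- c(planted_signs, rep(c(1, -1), length.out = n_extra))
  for (j in seq_along(coupled))
    expr[coupled[j], ] <- cfg$expr_mean + signs[j] * cfg$coupling * score +
      rnorm(cfg$n_cell_lines)
  truth <- list(coupled_genes = setNames(signs, coupled),
                score = setNames(score, line_ids), seed = seed)
  list(expr = expression_matrix(expr),
       sens = drug_sensitivity(line_ids, gi50, scale = "gi50"),
       truth = truth)
}

#' Simulate group-differential multi-omics profiles
#'
#' Copy-number regions, somatic mutations and MSI status are Bernoulli
#' draws with group-specific frequencies (the differential features use
#' the configured high/low frequencies, the rest a shared null
#' frequency).  When an expression matrix is supplied, promoter
#' methylation beta values are generated for a subset of its genes as
#' `plogis(-meth_coupling * z(expression) + noise)` so the negative
#' methylation-expression screen has planted truth; an equally sized
#' uncoupled gene set is added as null.
#'
#' @param cfg a [sim_config()].
#' @param labels named high/low risk labels defining the groups.
#' @param expr optional expression matrix over the same samples (enables
#'   the methylation component).
#' @param seed override of the derived substream seed.
#' @return list with `omics` (an [omics_bundle()]) and `truth`
#'   (differential region/mutation ids, region signs, methylation-coupled
#'   genes).
#' @export
simulate_omics <- function(cfg = sim_config(), labels, expr = NULL,
                           seed = cfg$seed + 2000L) {
  set.seed(seed %% 2^31)
  .assert(!is.null(names(labels)), "labels must be named by sample id")
  ids <- names(labels)
  hi <- labels == "high"
  n <- length(ids)
  region_ids <- sprintf("region%02d", seq_len(cfg$n_regions))
  region_sign <- rep(c(1, -1), length.out = cfg$n_regions)
  cna <- matrix(0L, cfg$n_regions, n, dimnames = list(region_ids, ids))
  for (r in seq_len(cfg$n_regions)) {
    f_hi <- if (r <= cfg$n_diff_regions) cfg$region_freq_high
            else cfg$region_freq_null
    f_lo <- if (r <= cfg$n_diff_regions) cfg$region_freq_low
            else cfg$region_freq_null
    altered <- rbinom(n, 1, ifelse(hi, f_hi, f_lo))
    cna[r, ] <- altered * region_sign[r] * (1L + rbinom(n, 1, 0.5))
  }
  mut_ids <- sprintf("mg%04d", seq_len(cfg$n_mut_genes))
  mut <- matrix(0L, cfg$n_mut_genes, n, dimnames = list(mut_ids, ids))
  for (g in seq_len(cfg$n_mut_genes)) {
    f_hi <- if (g <= cfg$n_diff_mut_genes) cfg$mut_freq_high
            else cfg$mut_freq_null
    f_lo <- if (g <= cfg$n_diff_mut_genes) cfg$mut_freq_low
            else cfg$mut_freq_null
    mut[g, ] <- rbinom(n, 1, ifelse(hi, f_hi, f_lo))
  }
  msi_high <- rbinom(n, 1, ifelse(hi, cfg$msi_high_freq_high,
                                  cfg$msi_high_freq_low)) == 1
  msi <- setNames(ifelse(msi_high, "MSI-High",
                         sample(c("MSS", "MSI-Low"), n, replace = TRUE,
                                prob = c(0.8, 0.2))), ids)
  meth <- NULL
  meth_coupled <- character()
  if (!is.null(expr)) {
    ss <- intersect(colnames(expr), ids)
    n_meth <- min(cfg$n_meth_genes, floor(nrow(expr) / 2))
    pick <- sample(nrow(expr), 2 * n_meth)
    coupled_rows <- pick[seq_len(n_meth)]
    null_rows <- pick[-seq_len(n_meth)]
    meth_coupled <- rownames(expr)[coupled_rows]
    z <- t(scale(t(expr[pick, ss, drop = FALSE])))
    beta <- matrix(rnorm(length(pick) * length(ss), 0, 1), length(pick))
    beta[seq_len(n_meth), ] <- -cfg$meth_coupling * z[seq_len(n_meth), ] +
      rnorm(n_meth * length(ss), 0, cfg$meth_noise_sd)
    meth <- plogis(beta)
    dimnames(meth) <- list(rownames(expr)[pick], ss)
  }
  omics <- omics_bundle(cna = cna, mutation = mut, methylation = meth,
                        msi = msi, samples = ids)
  truth <- list(diff_regions = region_ids[seq_len(cfg$n_diff_regions)],
                region_sign = setNames(region_sign, region_ids),
                diff_mut_genes = mut_ids[seq_len(cfg$n_diff_mut_genes)],
                meth_coupled_genes = meth_coupled, seed = seed)
  list(omics = omics, truth = truth)
}

#' Apply a strictly monotone per-sample transform
#'
#' All four kinds preserve every within-sample ordering exactly, so REO
#' classifications are provably unchanged.
#'
#' @param expr expression matrix.
#' @param kind `"exp"` (2^x), `"affine-positive"` (per-sample a*x + b with
#'   a > 0, deterministic in the sample index), `"rank"` (within-sample
#'   average ranks) or `"cube"` (x^3).
#' @return transformed expression matrix.
#' @export
apply_monotone_transform <- function(expr,
                                     kind = c("exp", "affine-positive",
                                              "rank", "cube")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    "exp" = 2^expr,
    "affine-positive" = {
      a <- 1 + seq_len(ncol(expr)) / ncol(expr)
      b <- seq_len(ncol(expr)) %% 5
      sweep(sweep(expr, 2, a, `*`), 2, b, `+`)
    },
    "rank" = apply(expr, 2, rank, na.last = "keep"),
    "cube" = expr^3)
  dimnames(out) <- dimnames(expr)
  out
}

#' Apply gene-wise additive batch shifts
#'
#' One offset per gene, shared by all samples — the classic additive
#' batch effect.  Unlike monotone per-sample transforms this can change
#' within-sample orderings, so it is the probe for measuring (rather than
#' proving) REO robustness.
#'
#' @param expr expression matrix.
#' @param sd standard deviation of the gene-wise shifts.
#' @param seed RNG seed for the shifts.
#' @return shifted expression matrix.
#' @export
apply_batch_shift <- function(expr, sd = 1, seed = 1L) {
  set.seed(seed %% 2^31)
  expr + rnorm(nrow(expr), 0, sd)
}
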