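#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of genes x samples on a
#' continuous (typically log2) scale, with unique gene ids as row names and
#' unique sample ids as column names.  Missing values are allowed (`NA`);
#' non-finite values are not.
#'
#' @param values numeric matrix (genes in rows).
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return the validated numeric matrix with dimnames set.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .assert(!is.null(gene_ids) && !is.null(sample_ids),
          "expression matrix needs gene and sample ids")
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  .assert(nrow(values) >= 2, "need at least 2 genes, got %d", nrow(values))
  .assert(ncol(values) >= 1, "need at least 1 sample")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  .assert(length(dup) == 0, "duplicate gene ids: %s",
          paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  .assert(length(dup) == 0, "duplicate sample ids: %s",
          paste(dup, collapse = ", "))
  bad <- which(!is.na(values) & !is.finite(values))
  .assert(length(bad) == 0, "non-finite expression values at %d cells",
          length(bad))
  values
}

# read a TSV with ids in the first column into a numeric matrix; every
# non-numeric cell is a hard error with its address
.read_matrix_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = c("NA", ""))
  .assert(ncol(tab) >= 2, "%s: expected an id column plus data columns", path)
  ids <- tab[[1]]
  dup <- unique(ids[duplicated(ids)])
  .assert(length(dup) == 0, "%s: duplicate ids: %s", path,
          paste(dup, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s: non-numeric value '%s' at row '%s', column '%s'",
                 path, m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  num
}

#' Read an expression matrix from a tab-delimited file
#'
#' @param path path to a TSV file with one header row and ids in the first
#'   column.
#' @param dialect `"genes-in-rows"` (default) if rows are genes, or
#'   `"genes-in-columns"` if rows are samples; the returned matrix is always
#'   genes x samples.
#' @return a validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path,
                            dialect = c("genes-in-rows", "genes-in-columns")) {
  dialect <- match.arg(dialect)
  m <- .read_matrix_tsv(path)
  if (dialect == "genes-in-columns") m <- t(m)
  m <- expression_matrix(m)
  reo_log("read expression %s: %d genes x %d samples (%d missing cells)",
          path, nrow(m), ncol(m), sum(is.na(m)))
  m
}

#' Write an expression matrix to a tab-delimited file
#'
#' @param expr expression matrix.
#' @param path output path.
#' @param id_column header for the id column.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct survival data (time-to-relapse with censoring)
#'
#' @param sample_ids unique sample identifiers.
#' @param time non-negative follow-up time in months (relapse-free
#'   survival: surgery to relapse or last contact).
#' @param event 1 = relapse observed, 0 = censored.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
survival_data <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  .assert(!anyDuplicated(sample_ids), "duplicate sample ids in survival data")
  .assert(length(time) == length(sample_ids) &&
            length(event) == length(sample_ids),
          "survival fields must have equal length")
  time <- as.numeric(time)
  .assert(all(is.finite(time)) && all(time >= 0),
          "survival times must be finite and >= 0")
  event <- as.numeric(event)
  .assert(all(event %in% c(0, 1)), "event indicator must be 0 or 1")
  data.frame(sample_id = sample_ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

.surv_vocab <- list(
  stage = c("II", "III"), mmr_status = c("pMMR", "dMMR"),
  braf_mut = c("WT", "M"), kras_mut = c("WT", "M"))

#' Read a clinical table (survival plus optional covariates)
#'
#' Expects tab-delimited text with a sample-id column (first column or
#' `sample_id`), `time` and `event` columns, and any of the optional
#' covariate columns `stage` (II/III), `gender`, `age`, `tumor_location`,
#' `mmr_status` (pMMR/dMMR), `braf_mut` (WT/M), `kras_mut` (WT/M).
#' Samples with missing time or event are excluded (and counted in the
#' log); a negative time or an event value outside \{0, 1\} is a hard
#' error.  Unknown covariate values must be encoded as missing, never as a
#' new category.
#'
#' @param path path to the clinical TSV.
#' @return list with elements `survival` (see [survival_data()]) and
#'   `covariates` (data.frame keyed by `sample_id`, or NULL when no
#'   covariate column is present).
#' @export
read_clinical <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  idcol <- if ("sample_id" %in% names(tab)) "sample_id" else names(tab)[1]
  .assert(all(c("time", "event") %in% names(tab)),
          "%s: need 'time' and 'event' columns", path)
  keep <- !is.na(tab$time) & !is.na(tab$event)
  if (any(!keep))
    reo_log("read clinical %s: dropped %d samples with missing time/event",
            path, sum(!keep))
  tab <- tab[keep, , drop = FALSE]
  .assert(all(tab$time >= 0), "%s: negative survival time", path)
  .assert(all(tab$event %in% c(0, 1)),
          "%s: event indicator must be 0 or 1", path)
  surv <- survival_data(tab[[idcol]], tab$time, tab$event)
  covcols <- intersect(
    c("stage", "gender", "age", "tumor_location", "mmr_status",
      "braf_mut", "kras_mut"), names(tab))
  cov <- NULL
  if (length(covcols) > 0) {
    cov <- data.frame(sample_id = surv$sample_id,
                      tab[covcols], stringsAsFactors = FALSE)
    for (nm in intersect(names(.surv_vocab), covcols)) {
      bad <- setdiff(unique(stats::na.omit(cov[[nm]])), .surv_vocab[[nm]])
      .assert(length(bad) == 0, "%s: invalid %s value(s): %s", path, nm,
              paste(bad, collapse = ", "))
    }
  }
  reo_log("read clinical %s: %d samples, %d events", path, nrow(surv),
          sum(surv$event))
  list(survival = surv, covariates = cov)
}

#' Write a clinical table
#' @param surv survival data (see [survival_data()]).
#' @param path output path.
#' @param covariates optional covariate data.frame keyed by `sample_id`.
#' @export
write_clinical <- function(surv, path, covariates = NULL) {
  tab <- surv
  if (!is.null(covariates))
    tab <- merge(tab, covariates, by = "sample_id", all.x = TRUE, sort = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct drug-sensitivity data for a cell-line panel
#'
#' @param cell_line_ids unique cell-line identifiers.
#' @param gi50 drug sensitivity values; higher GI50 = more resistant.
#' @param scale `"gi50"` if values are on the GI50 scale, `"neglog10"` if
#'   they are -log10 GI50 (in which case correlation signs are flipped
#'   internally so screens always report GI50-scale signs).
#' @return data.frame with columns `cell_line`, `gi50` and a `"scale"`
#'   attribute.
#' @export
drug_sensitivity <- function(cell_line_ids, gi50,
                             scale = c("gi50", "neglog10")) {
  scale <- match.arg(scale)
  cell_line_ids <- as.character(cell_line_ids)
  .assert(!anyDuplicated(cell_line_ids), "duplicate cell line ids")
  gi50 <- as.numeric(gi50)
  .assert(all(is.finite(gi50)), "GI50 values must be finite")
  out <- data.frame(cell_line = cell_line_ids, gi50 = gi50,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  out
}

#' Read drug-sensitivity data from a two-column TSV
#' @param path TSV with cell-line ids in the first column, values in the
#'   second.
#' @inheritParams drug_sensitivity
#' @export
read_drug_sensitivity <- function(path, scale = c("gi50", "neglog10")) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  drug_sensitivity(tab[[1]], tab[[2]], scale = match.arg(scale))
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited, fields name, description,
#' then member genes.  A line with fewer than 3 fields is a hard error
#' reported with its line number.
#'
#' @param path GMT path.
#' @param universe optional explicit background gene universe.
#' @return named list of character vectors with attribute `"universe"`.
#' @export
read_gene_sets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .assert(length(f) >= 3, "%s line %d: GMT line has %d fields (need >= 3)",
            path, i, length(f))
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets, universe = universe)
}

#' Construct a gene-set collection
#' @param sets named list of non-empty character vectors.
#' @param universe optional explicit background gene universe.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  .assert(length(sets) > 0 && !is.null(names(sets)) &&
            all(nzchar(names(sets))), "gene sets must be named")
  .assert(!anyDuplicated(names(sets)), "duplicate gene set names")
  .assert(all(lengths(sets) > 0), "empty gene set")
  sets <- lapply(sets, as.character)
  attr(sets, "universe") <- if (is.null(universe)) NULL
                            else unique(as.character(universe))
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection as GMT
#' @param sets gene-set collection.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an undirected protein-protein interaction network
#'
#' Self-loops are dropped with a warning; duplicate edges (in either
#' orientation) are collapsed.
#'
#' @param from,to character vectors of interacting gene ids.
#' @return object of class `ppi_network` with elements `edges` (two-column
#'   character matrix in canonical order) and `nodes`.
#' @export
ppi_network <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  .assert(length(from) == length(to), "edge columns differ in length")
  self <- from == to
  if (any(self)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(self)))
    from <- from[!self]; to <- to[!self]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(a = a[keep], b = b[keep])
  structure(list(edges = edges, nodes = sort(unique(c(a, b)))),
            class = "ppi_network")
}

#' Read a PPI edge list (two-column TSV or SIF)
#'
#' A SIF file (`node relation node`) is detected by a 3+ column layout, in
#' which case columns 1 and 3 are used.
#'
#' @param path edge-list path (no header).
#' @export
read_ppi <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(tab) >= 2, "%s: need at least two columns", path)
  if (ncol(tab) >= 3) ppi_network(tab[[1]], tab[[3]])
  else ppi_network(tab[[1]], tab[[2]])
}

#' Write a PPI network as a two-column TSV edge list
#' @param net `ppi_network` object.
#' @param path output path.
#' @export
write_ppi <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundle multi-omics profiles aligned on a master sample list
#'
#' @param cna gene-or-region x sample integer matrix of discrete copy-number
#'   calls in \{-2, -1, 0, 1, 2\} (GISTIC-style), or NULL.
#' @param mutation gene x sample binary somatic-mutation matrix, or NULL.
#' @param methylation gene x sample promoter methylation beta matrix in
#'   \[0, 1\], or NULL.
#' @param msi named character vector of MSI categories
#'   (`MSI-High`/`MSI-Low`/`MSS`), or NULL.
#' @param samples optional declared master sample list; every component's
#'   sample ids must be a subset of it.
#' @param region_map optional named list mapping region ids to gene id sets.
#' @return object of class `omics_bundle`.
#' @export
omics_bundle <- function(cna = NULL, mutation = NULL, methylation = NULL,
                         msi = NULL, samples = NULL, region_map = NULL) {
  if (!is.null(cna)) {
    .assert(all(is.na(cna) | cna %in% (-2:2)),
            "CNA calls must be integers in -2..2")
  }
  if (!is.null(mutation))
    .assert(all(is.na(mutation) | mutation %in% c(0, 1)),
            "mutation matrix must be binary")
  if (!is.null(methylation))
    .assert(all(is.na(methylation) |
                  (methylation >= 0 & methylation <= 1)),
            "methylation beta values must be in [0, 1]")
  if (!is.null(msi)) {
    .assert(!is.null(names(msi)), "msi must be a named vector")
    bad <- setdiff(unique(stats::na.omit(msi)),
                   c("MSI-High", "MSI-Low", "MSS"))
    .assert(length(bad) == 0, "invalid MSI categories: %s",
            paste(bad, collapse = ", "))
  }
  if (!is.null(samples)) {
    samples <- as.character(samples)
    for (comp in list(cna = cna, mutation = mutation,
                      methylation = methylation)) {
      if (!is.null(comp))
        .assert(all(colnames(comp) %in% samples),
                "omics sample ids outside the declared master list")
    }
    if (!is.null(msi))
      .assert(all(names(msi) %in% samples),
              "MSI sample ids outside the declared master list")
  }
  structure(list(cna = cna, mutation = mutation, methylation = methylation,
                 msi = msi, samples = samples, region_map = region_map),
            class = "omics_bundle")
}

#' Read multi-omics matrices into an [omics_bundle()]
#'
#' @param cna,mutation,methylation optional TSV matrix paths (features in
#'   rows, samples in columns).
#' @param msi optional two-column TSV path (sample id, MSI category).
#' @param samples optional declared master sample list.
#' @export
read_omics <- function(cna = NULL, mutation = NULL, methylation = NULL,
                       msi = NULL, samples = NULL) {
  rd <- function(p) if (is.null(p)) NULL else .read_matrix_tsv(p)
  msiv <- NULL
  if (!is.null(msi)) {
    tab <- read.delim(msi, header = TRUE, stringsAsFactors = FALSE)
    msiv <- setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  omics_bundle(cna = rd(cna), mutation = rd(mutation),
               methylation = rd(methylation), msi = msiv, samples = samples)
}

#' Summarize CpG-level methylation to gene-level promoter betas
#'
#' Optional pre-step for methylation analyses: the gene-level beta is the
#' arithmetic mean of the gene's mapped promoter CpG betas.
#'
#' @param cpg CpG-site x sample beta matrix (values in \[0, 1\]).
#' @param map named list: gene id -> character vector of CpG ids.
#' @return gene x sample beta matrix; genes with no mapped CpG present in
#'   the matrix are dropped with a log note.
#' @export
summarize_methylation <- function(cpg, map) {
  .assert(all(is.na(cpg) | (cpg >= 0 & cpg <= 1)),
          "beta values must be in [0, 1]")
  .assert(is.list(map) && !is.null(names(map)), "map must be a named list")
  rows <- lapply(names(map), function(g) {
    sites <- intersect(map[[g]], rownames(cpg))
    if (length(sites) == 0) return(NULL)
    colMeans(cpg[sites, , drop = FALSE], na.rm = TRUE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    reo_log("methylation summary: %d gene(s) without mapped CpGs dropped",
            sum(!keep))
  .assert(any(keep), "no genes with mapped CpG sites")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(map)[keep]
  out
}
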