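#' Construct a gene-pair signature
#'
#' A signature is an ordered set of REO rules.  Each rule compares two
#' genes within a sample; `direction = "a_gt_b_risky"` means the ordering
#' gene_a > gene_b votes for high risk (the case when the rule's Cox
#' coefficient beta is positive), `"a_gt_b_protective"` the reverse.  A
#' sample is called high risk when at least half of its non-abstaining
#' rules vote high (ties go to high risk).
#'
#' @param rules data.frame with columns `gene_a`, `gene_b`, `beta`,
#'   `p_value`, `fdr`, `c_index`, `direction`.
#' @param vote_threshold voting rule; only `"at-least-half"` is defined.
#' @param provenance free-text provenance note.
#' @return object of class `gene_pair_signature`.
#' @export
gene_pair_signature <- function(rules, vote_threshold = "at-least-half",
                                provenance = "") {
  .assert(is.data.frame(rules) && nrow(rules) >= 1,
          "a signature needs at least one rule")
  needed <- c("gene_a", "gene_b", "beta", "p_value", "fdr", "c_index",
              "direction")
  .assert(all(needed %in% names(rules)), "rules must have columns: %s",
          paste(needed, collapse = ", "))
  rules <- rules[needed]
  rules$gene_a <- as.character(rules$gene_a)
  rules$gene_b <- as.character(rules$gene_b)
  .assert(all(rules$gene_a != rules$gene_b),
          "a rule cannot pair a gene with itself")
  key <- paste(pmin(rules$gene_a, rules$gene_b),
               pmax(rules$gene_a, rules$gene_b))
  .assert(!anyDuplicated(key), "duplicated unordered gene pair in signature")
  .assert(all(rules$direction %in% c("a_gt_b_risky", "a_gt_b_protective")),
          "invalid direction token; use 'a_gt_b_risky' or 'a_gt_b_protective'")
  sgn <- ifelse(rules$direction == "a_gt_b_risky", 1, -1)
  okb <- is.finite(rules$beta)
  .assert(all(sign(rules$beta[okb]) == sgn[okb]),
          "direction must match the sign of beta (beta > 0 <=> risky)")
  .assert(identical(vote_threshold, "at-least-half"),
          "unsupported vote threshold '%s'", vote_threshold)
  rownames(rules) <- NULL
  structure(list(rules = rules, vote_threshold = vote_threshold,
                 provenance = provenance), class = "gene_pair_signature")
}

#' @export
print.gene_pair_signature <- function(x, ...) {
  cat(sprintf("Gene-pair REO signature: %d rule(s), %d distinct genes\n",
              nrow(x$rules),
              length(unique(c(x$rules$gene_a, x$rules$gene_b)))))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  df <- x$rules
  df$rule <- ifelse(df$direction == "a_gt_b_risky",
                    paste0(df$gene_a, " > ", df$gene_b, "  (risky)"),
                    paste0(df$gene_a, " > ", df$gene_b, "  (protective)"))
  print(df[c("rule", "beta", "p_value", "fdr", "c_index")], digits = 3)
  cat("vote rule: high risk iff >= half of the non-abstaining rules vote high\n")
  invisible(x)
}

#' The bundled six-gene-pair colorectal 5-FU signature
#'
#' The published six REO rules (11 distinct genes) for stratifying stage
#' II-III colorectal cancer patients treated with 5-FU-based adjuvant
#' chemotherapy into high- and low-recurrence-risk groups.  All six rules
#' are risky orderings (beta > 0): a sample with at least three of the six
#' orderings present is called high risk.
#'
#' @return a [gene_pair_signature()] with six rules.
#' @examples
#' six_gps()
#' @export
six_gps <- function() {
  rules <- data.frame(
    gene_a = c("CHTOP", "MRPL4", "SLC19A1", "PUS1", "MCM2", "SLC19A1"),
    gene_b = c("CAPN2", "AXL", "NREP", "LTBP2", "IFRD2", "WWC2"),
    beta = c(1.22, 0.98, 1.09, 0.61, 0.66, 1.20),
    p_value = c(6.37e-05, 4.12e-05, 2.19e-03, 8.74e-03, 1.18e-02, 9.92e-05),
    fdr = c(1.89e-03, 1.70e-03, 1.43e-02, 3.39e-02, 3.89e-02, 2.41e-03),
    c_index = c(0.63, 0.60, 0.59, 0.57, 0.57, 0.56),
    direction = "a_gt_b_risky",
    stringsAsFactors = FALSE)
  gene_pair_signature(rules,
                      provenance = "bundled 6-GPS (colorectal, 5-FU-based therapy)")
}

.SIG_HEADER <- "#reosig-signature v1"

#' Write a gene-pair signature to a self-describing TSV file
#'
#' The file starts with the schema line `#reosig-signature v1`, an
#' optional `#provenance:` comment, then a tab-delimited rule table.
#' Numeric fields are written at full precision so the round trip through
#' [read_signature()] is lossless.
#'
#' @param sig a [gene_pair_signature()].
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  .assert(inherits(sig, "gene_pair_signature"), "not a gene_pair_signature")
  df <- sig$rules
  for (nm in c("beta", "p_value", "fdr", "c_index"))
    df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.SIG_HEADER, con)
  if (nzchar(sig$provenance))
    writeLines(paste0("#provenance: ", sig$provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-pair signature written by [write_signature()]
#' @param path signature file path.
#' @return a [gene_pair_signature()].
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) >= 2 && identical(lines[1], .SIG_HEADER),
          "%s: unknown signature schema (expected '%s')", path, .SIG_HEADER)
  prov <- ""
  body <- lines[-1]
  is_prov <- startsWith(body, "#provenance: ")
  if (any(is_prov)) prov <- sub("^#provenance: ", "", body[which(is_prov)[1]])
  body <- body[!startsWith(body, "#")]
  .assert(length(body) >= 2, "%s: signature must have at least one rule", path)
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE)
  gene_pair_signature(df, provenance = prov)
}
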