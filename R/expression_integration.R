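#' Remove genes expressed below background in both groups
#'
#' A gene is removed only when its median TPM is below `tpm_min` in both the
#' metastatic and the non-metastatic group (a conjunction: expression above
#' background in either group keeps the gene).
#'
#' @param records data frame with columns `median_tpm_met`,
#'   `median_tpm_nomet`.
#' @param tpm_min background TPM threshold (default 2).
#' @return the kept rows.
#' @export
filter_low_expression <- function(records, tpm_min = 2) {
  drop <- records$median_tpm_met < tpm_min & records$median_tpm_nomet < tpm_min
  records[!drop, , drop = FALSE]
}

#' Select differentially expressed mRNAs
#'
#' Strict thresholds: kept iff adjusted p-value < `adj_p_max` and
#' |log2 fold change| > `abs_log2_fc_min`.
#'
#' @param records data frame with columns `adj_p`, `log2_fc`.
#' @param adj_p_max adjusted p-value cutoff (default 0.05, strict).
#' @param abs_log2_fc_min |log2FC| cutoff (default 1, strict).
#' @param inclusive use inclusive comparisons instead (harmonises with the
#'   miRNA rule); default `FALSE`.
#' @return the kept rows.
#' @export
select_de_mrna <- function(records, adj_p_max = 0.05, abs_log2_fc_min = 1,
                           inclusive = FALSE) {
  keep <- if (inclusive)
    records$adj_p <= adj_p_max & abs(records$log2_fc) >= abs_log2_fc_min
  else
    records$adj_p < adj_p_max & abs(records$log2_fc) > abs_log2_fc_min
  records[keep, , drop = FALSE]
}

#' Remove miRNAs expressed below background
#'
#' The background rule inspects four medians per miRNA: raw and normalised
#' read-count medians in each of the two groups. Under the default
#' `"all_four"` reading a miRNA is removed only when all four are below
#' `count_min` — the most conservative removal rule. `"raw_only"` and
#' `"normalised_only"` consider only that pair of group medians.
#'
#' @param records data frame with columns `median_raw_met`,
#'   `median_raw_nomet`, `median_norm_met`, `median_norm_nomet`.
#' @param count_min read-count threshold (default 45).
#' @param rule which medians must all be below threshold for removal.
#' @return the kept rows.
#' @export
filter_mirna_background <- function(records, count_min = 45,
                                    rule = c("all_four", "raw_only",
                                             "normalised_only")) {
  rule <- match.arg(rule)
  below <- switch(rule,
    all_four = records$median_raw_met < count_min &
      records$median_raw_nomet < count_min &
      records$median_norm_met < count_min &
      records$median_norm_nomet < count_min,
    raw_only = records$median_raw_met < count_min &
      records$median_raw_nomet < count_min,
    normalised_only = records$median_norm_met < count_min &
      records$median_norm_nomet < count_min)
  records[!below, , drop = FALSE]
}

#' Select differentially expressed miRNAs
#'
#' Inclusive thresholds (deliberately different from the strict mRNA rule):
#' kept iff q-value <= `q_max` and |log2 fold change| >= `abs_log2_fc_min`.
#'
#' @param records data frame with columns `q_value`, `log2_fc`.
#' @param q_max q-value cutoff (default 0.05, inclusive).
#' @param abs_log2_fc_min |log2FC| cutoff (default 1, inclusive).
#' @return the kept rows.
#' @export
select_de_mirna <- function(records, q_max = 0.05, abs_log2_fc_min = 1) {
  keep <- records$q_value <= q_max & abs(records$log2_fc) >= abs_log2_fc_min
  records[keep, , drop = FALSE]
}

#' Pair differentially expressed miRNAs with oppositely regulated targets
#'
#' Emits a (miRNA, gene) pair iff the pair appears in the interaction table
#' at an allowed confidence level, both members are differentially
#' expressed, and their log2 fold changes have strictly opposite signs
#' (a zero fold change pairs with nothing).
#'
#' @param de_mirnas data frame with columns `mirna`, `log2_fc`.
#' @param de_mrnas data frame with columns `gene`, `log2_fc`.
#' @param interactions data frame with columns `mirna`, `gene`,
#'   `confidence`.
#' @param allowed_confidence confidence levels admitted (default
#'   experimentally observed and highly predicted).
#' @return data frame with columns `mirna`, `gene`, `mirna_log2_fc`,
#'   `gene_log2_fc`, one row per pair, ordered by (mirna, gene).
#' @export
pair_mirna_targets <- function(de_mirnas, de_mrnas, interactions,
                               allowed_confidence = c("experimentally_observed",
                                                      "highly_predicted")) {
  ix <- interactions[interactions$confidence %in% allowed_confidence,
                     c("mirna", "gene"), drop = FALSE]
  ix <- unique(ix)
  m <- de_mirnas[!duplicated(de_mirnas$mirna), c("mirna", "log2_fc")]
  g <- de_mrnas[!duplicated(de_mrnas$gene), c("gene", "log2_fc")]
  names(m)[2] <- "mirna_log2_fc"
  names(g)[2] <- "gene_log2_fc"
  out <- merge(merge(ix, m, by = "mirna"), g, by = "gene")
  out <- out[sign(out$mirna_log2_fc) * sign(out$gene_log2_fc) < 0,
             c("mirna", "gene", "mirna_log2_fc", "gene_log2_fc"),
             drop = FALSE]
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
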