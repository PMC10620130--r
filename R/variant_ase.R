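#' Filter somatic variants by sequencing-evidence thresholds
#'
#' Keeps a variant iff tumour depth, control depth, tumour mutant allele
#' frequency and tumour alt-supporting read count all reach their thresholds
#' (all inclusive). Input order is preserved.
#'
#' @param variants data frame with columns `tumour_depth`, `control_depth`,
#'   `tumour_maf`, `tumour_alt_reads` (other columns pass through).
#' @param tumour_depth_min minimum tumour coverage (default 50).
#' @param control_depth_min minimum control coverage (default 30).
#' @param maf_min minimum tumour mutant allele frequency (default 0.03).
#' @param alt_reads_min minimum alt-supporting reads in tumour (default 5).
#' @return the kept rows.
#' @export
filter_somatic <- function(variants, tumour_depth_min = 50,
                           control_depth_min = 30, maf_min = 0.03,
                           alt_reads_min = 5) {
  req <- c("tumour_depth", "control_depth", "tumour_maf", "tumour_alt_reads")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  keep <- variants$tumour_depth >= tumour_depth_min &
    variants$control_depth >= control_depth_min &
    variants$tumour_maf >= maf_min &
    variants$tumour_alt_reads >= alt_reads_min
  variants[keep, , drop = FALSE]
}

#' Tumour mutational burden
#'
#' @param n_protein_coding_mutations mutation count.
#' @param target_size_mb size of the sequenced coding target in Mb (> 0);
#'   required — no hidden exome-size constant is assumed.
#' @param low_threshold mutations/Mb below which TMB is "low" (default 5,
#'   strict: a TMB of exactly 5 is not low).
#' @return list with `tmb` (mutations per Mb) and logical `low_tmb`.
#' @export
compute_tmb <- function(n_protein_coding_mutations, target_size_mb,
                        low_threshold = 5) {
  if (!is.finite(target_size_mb) || target_size_mb <= 0)
    stop("target_size_mb must be positive")
  tmb <- n_protein_coding_mutations / target_size_mb
  list(tmb = tmb, low_tmb = tmb < low_threshold)
}

#' Classify allele-specific expression of somatic mutations
#'
#' Applies the rule set joining a somatic mutation to its RNA evidence:
#' \itemize{
#'   \item `NOT_COVERED` — no RNA reads overlap the locus
#'     (`rna_ref_count + rna_alt_count == 0`);
#'   \item `GENE_NOT_EXPRESSED` — gene TPM below `tpm_min`;
#'   \item `MUTATED_EXPRESSED` — gene TPM at or above `tpm_min` and RNA VAF
#'     strictly above `vaf_min`;
#'   \item `MUTATED_NOT_EXPRESSED` — gene expressed but RNA VAF at or below
#'     `vaf_min` (only the wild-type allele is expressed).
#' }
#' The TPM comparison is inclusive for "expressed" (TPM >= 2) and the VAF
#' comparison strict for "expressed" (VAF > 0.03), matching the asymmetry of
#' the rule as stated.
#'
#' @param observations data frame with columns `gene_tpm`, `rna_ref_count`,
#'   `rna_alt_count`.
#' @param tpm_min TPM threshold for gene expression (default 2).
#' @param vaf_min RNA VAF threshold for mutant-allele expression
#'   (default 0.03).
#' @return character vector of classes, one per row.
#' @export
classify_ase <- function(observations, tpm_min = 2, vaf_min = 0.03) {
  req <- c("gene_tpm", "rna_ref_count", "rna_alt_count")
  miss <- setdiff(req, names(observations))
  if (length(miss)) stop("ASE table missing column(s): ",
                         paste(miss, collapse = ", "))
  depth <- observations$rna_ref_count + observations$rna_alt_count
  vaf <- ifelse(depth > 0, observations$rna_alt_count / depth, NA_real_)
  ifelse(depth == 0, "NOT_COVERED",
         ifelse(observations$gene_tpm < tpm_min, "GENE_NOT_EXPRESSED",
                ifelse(vaf > vaf_min, "MUTATED_EXPRESSED",
                       "MUTATED_NOT_EXPRESSED")))
}

#' @rdname classify_ase
#' @export
ase_classes <- function() c("MUTATED_EXPRESSED", "MUTATED_NOT_EXPRESSED",
                            "GENE_NOT_EXPRESSED", "NOT_COVERED")

#' Per-sample ASE class proportions
#'
#' Proportions of `MUTATED_EXPRESSED`, `MUTATED_NOT_EXPRESSED` and
#' `GENE_NOT_EXPRESSED` among a sample's mutations; `NOT_COVERED`
#' observations are excluded from the denominator (loci absent from the
#' covered RNA data carry no expression evidence) but their count is
#' reported.
#'
#' @param observations data frame with a `sample_id` column and either a
#'   precomputed `ase_class` column or the columns needed by
#'   [classify_ase()].
#' @param tpm_min,vaf_min passed to [classify_ase()] when classes are not
#'   precomputed.
#' @return data frame with one row per sample: `sample_id`, `n_classified`,
#'   `n_not_covered`, `prop_mutated_expressed`, `prop_mutated_not_expressed`,
#'   `prop_gene_not_expressed` (the three proportions sum to 1).
#' @export
ase_sample_summary <- function(observations, tpm_min = 2, vaf_min = 0.03) {
  if (!"sample_id" %in% names(observations))
    stop("ASE table must have a 'sample_id' column")
  cls <- if ("ase_class" %in% names(observations)) observations$ase_class
  else classify_ase(observations, tpm_min, vaf_min)
  by_sample <- split(cls, observations$sample_id)
  rows <- lapply(names(by_sample), function(sid) {
    x <- by_sample[[sid]]
    covered <- x[x != "NOT_COVERED"]
    if (length(covered) == 0)
      stop("sample '", sid, "': all observations NOT_COVERED; no denominator")
    data.frame(n_classified = length(covered),
               n_not_covered = sum(x == "NOT_COVERED"),
               prop_mutated_expressed = mean(covered == "MUTATED_EXPRESSED"),
               prop_mutated_not_expressed = mean(covered == "MUTATED_NOT_EXPRESSED"),
               prop_gene_not_expressed = mean(covered == "GENE_NOT_EXPRESSED"))
  })
  out <- cbind(data.frame(sample_id = names(by_sample), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Pooled ASE class proportions across a cohort
#'
#' Pools all covered observations (rather than averaging per-sample
#' proportions) and reports one proportion per class.
#'
#' @inheritParams ase_sample_summary
#' @return named numeric vector of three proportions plus `n_classified`
#'   and `n_not_covered` counts as attributes-free list.
#' @export
ase_pooled_summary <- function(observations, tpm_min = 2, vaf_min = 0.03) {
  cls <- if ("ase_class" %in% names(observations)) observations$ase_class
  else classify_ase(observations, tpm_min, vaf_min)
  covered <- cls[cls != "NOT_COVERED"]
  if (length(covered) == 0) stop("all observations NOT_COVERED")
  list(n_classified = length(covered),
       n_not_covered = sum(cls == "NOT_COVERED"),
       prop_mutated_expressed = mean(covered == "MUTATED_EXPRESSED"),
       prop_mutated_not_expressed = mean(covered == "MUTATED_NOT_EXPRESSED"),
       prop_gene_not_expressed = mean(covered == "GENE_NOT_EXPRESSED"))
}
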