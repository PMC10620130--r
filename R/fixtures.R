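#' Bundled reference cohort summaries
#'
#' The package ships the chromosome-level CIN overview and the
#' chromothripsis pattern table of a published cohort of 21 resectable,
#' gastric, high-risk GISTs (10 patients later metastatic, 11 without
#' relapse) as plain-text fixtures. `gist_cohort_cin()` returns one row per
#' sample: the counts of chromosomes affected by CNV only, copy-neutral LOH
#' only, and both, the total, the Simple/Complex label at the 10-chromosome
#' threshold, tumour ploidy and mitotic count.
#' `gist_cohort_chromothripsis()` returns one row per reported
#' (sample, chromosome): the maximal number of copy-number switches within
#' 50 Mb.
#'
#' @return data frame.
#' @export
gist_cohort_cin <- function() {
  utils::read.delim(system.file("extdata", "gist_cohort_cin.tsv",
                                package = "gistcin"),
                    stringsAsFactors = FALSE)
}

#' @rdname gist_cohort_cin
#' @export
gist_cohort_chromothripsis <- function() {
  tab <- utils::read.delim(system.file("extdata",
                                       "gist_cohort_chromothripsis.tsv",
                                       package = "gistcin"),
                           stringsAsFactors = FALSE)
  tab$chrom <- normalize_chrom(tab$chrom)
  tab
}

#' Profile specs reproducing the reference cohort's CIN table
#'
#' Encodes each reference-cohort sample as a [profile_spec()] planting that
#' sample's CNV-only / cnLOH-only / both-affected chromosome counts, so that
#' [simulate_cohort()] followed by [cohort_cin_table()] reproduces the
#' bundled table's counts, totals and Simple/Complex labels exactly.
#'
#' @param table a cohort CIN table; defaults to [gist_cohort_cin()].
#' @return list of `profile_spec`.
#' @export
gist_cohort_specs <- function(table = gist_cohort_cin()) {
  lapply(seq_len(nrow(table)), function(i)
    profile_spec(sample_id = table$sample[i],
                 group = table$group[i],
                 ploidy = table$ploidy[i],
                 n_cnv_only = table$n_chr_cnv[i],
                 n_loh_only = table$n_chr_loh[i],
                 n_both = table$n_chr_both[i]))
}
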