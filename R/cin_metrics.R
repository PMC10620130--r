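#' CIN scoring configuration
#'
#' Parameters governing per-chromosome aberration calling and the
#' simple/complex karyotype classification.
#'
#' The affected-chromosome CIN score counts chromosomes carrying copy-number
#' variation (any segment whose total copy number differs from the baseline)
#' and/or copy-neutral loss of heterozygosity (a segment at baseline total
#' copy number with zero minor-allele copies). Samples with
#' `complexity_threshold` or more affected chromosomes are labelled
#' `Complex`, the rest `Simple`.
#'
#' @param baseline_cn baseline total copy number against which gain/loss is
#'   judged in `"diploid"` mode (default 2).
#' @param baseline_mode `"diploid"` uses `baseline_cn`;
#'   `"nearest_integer_ploidy"` uses `round(ploidy)` of the sample.
#' @param min_aberrant_len_bp minimum segment length for a segment to count
#'   as aberrant (default 0: any segment counts).
#' @param complexity_threshold affected-chromosome count at or above which a
#'   sample is `Complex` (default 10).
#' @param log_ratio_threshold |log-ratio| above which a segment counts as a
#'   copy-number abnormality for the comparator metrics (default 0.2).
#' @param count_x_for_cnloh whether chromosome X is eligible for cnLOH
#'   counting. Default `NA`: decided per sample — excluded when the sample's
#'   sex is male (a hemizygous X is not LOH), included otherwise.
#' @param tai_masked when `TRUE`, the total aberration index averages
#'   |log-ratio| only over segments passing `log_ratio_threshold`; default
#'   `FALSE` averages over all segments.
#' @return list of class `cin_config`.
#' @export
cin_config <- function(baseline_cn = 2L,
                       baseline_mode = c("diploid", "nearest_integer_ploidy"),
                       min_aberrant_len_bp = 0,
                       complexity_threshold = 10L,
                       log_ratio_threshold = 0.2,
                       count_x_for_cnloh = NA,
                       tai_masked = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(baseline_cn >= 0, min_aberrant_len_bp >= 0,
            complexity_threshold >= 0, log_ratio_threshold >= 0)
  structure(list(baseline_cn = as.integer(baseline_cn),
                 baseline_mode = baseline_mode,
                 min_aberrant_len_bp = min_aberrant_len_bp,
                 complexity_threshold = as.integer(complexity_threshold),
                 log_ratio_threshold = log_ratio_threshold,
                 count_x_for_cnloh = count_x_for_cnloh,
                 tai_masked = tai_masked),
            class = "cin_config")
}

baseline_for <- function(config, ploidy) {
  if (config$baseline_mode == "diploid") config$baseline_cn
  else max(1L, as.integer(round(ploidy)))
}

cnloh_eligible <- function(config, chrom, sex) {
  if (chrom != "X") return(TRUE)
  if (!is.na(config$count_x_for_cnloh)) return(isTRUE(config$count_x_for_cnloh))
  !(identical(tolower(as.character(sex)), "male"))
}

#' Aberration status of one chromosome
#'
#' A chromosome is CNV-affected when some sufficiently long segment has a
#' total copy number different from the baseline, and cnLOH-affected when
#' some sufficiently long segment sits at baseline total copy number with
#' zero minor-allele copies (heterozygosity lost without net copy change).
#'
#' @param segments segment rows on a single chromosome (internal
#'   coordinates).
#' @param config a [cin_config()].
#' @param ploidy sample ploidy, used only in `nearest_integer_ploidy` mode.
#' @param sex sample sex, used only for X-chromosome cnLOH eligibility.
#' @return list with logical `cnv_affected` and `cnloh_affected`.
#' @export
chromosome_status <- function(segments, config = cin_config(), ploidy = 2,
                              sex = NA_character_) {
  chroms <- unique(segments$chrom)
  if (length(chroms) > 1)
    stop("chromosome_status expects segments of a single chromosome, got: ",
         paste(chroms, collapse = ", "))
  if (nrow(segments) == 0)
    return(list(cnv_affected = FALSE, cnloh_affected = FALSE))
  base <- baseline_for(config, ploidy)
  len_ok <- (segments$end - segments$start) >= config$min_aberrant_len_bp
  cnv <- any(len_ok & segments$total_cn != base)
  loh <- any(len_ok & segments$total_cn == base & segments$minor_cn == 0) &&
    cnloh_eligible(config, chroms, sex)
  list(cnv_affected = cnv, cnloh_affected = loh)
}

#' Simple/complex classification from the affected-chromosome count
#'
#' @param n_chr_total number of affected chromosomes (>= 0).
#' @param threshold count at or above which the sample is `Complex`
#'   (default 10).
#' @return character vector, `"Complex"` where `n_chr_total >= threshold`,
#'   else `"Simple"`.
#' @export
classify_complexity <- function(n_chr_total, threshold = 10L) {
  stopifnot(all(n_chr_total >= 0))
  ifelse(n_chr_total >= threshold, "Complex", "Simple")
}

#' Per-sample CIN summary: affected chromosome counts
#'
#' Partitions the affected chromosomes of a profile into CNV-only,
#' cnLOH-only and both-affected counts, totals them, and labels the sample
#' `Simple` or `Complex` by the configured threshold.
#'
#' @param profile a [segmented_profile()].
#' @param config a [cin_config()].
#' @return one-row data frame with columns `sample_id`, `n_chr_cnv_only`,
#'   `n_chr_loh_only`, `n_chr_both`, `n_chr_total`, `complexity`.
#' @export
summarize_cin <- function(profile, config = cin_config()) {
  chroms <- unique(profile$segments$chrom)
  cnv_only <- loh_only <- both <- 0L
  for (chr in chroms) {
    st <- chromosome_status(profile_chrom_segments(profile, chr), config,
                            ploidy = profile$ploidy, sex = profile$sex)
    if (st$cnv_affected && st$cnloh_affected) both <- both + 1L
    else if (st$cnv_affected) cnv_only <- cnv_only + 1L
    else if (st$cnloh_affected) loh_only <- loh_only + 1L
  }
  total <- cnv_only + loh_only + both
  data.frame(sample_id = profile$sample_id,
             n_chr_cnv_only = cnv_only, n_chr_loh_only = loh_only,
             n_chr_both = both, n_chr_total = total,
             complexity = classify_complexity(total, config$complexity_threshold),
             stringsAsFactors = FALSE)
}

# log-ratio per segment: input column when present, else derived from total
# copy number against a diploid reference (0.5 floor avoids log2(0))
segment_log_ratio <- function(segments) {
  lr <- segments$log_ratio
  derived <- log2(pmax(segments$total_cn, 0.5) / 2)
  ifelse(is.na(lr), derived, lr)
}

#' Comparator CIN metrics: CNA count, breakpoints, FGA, TAI
#'
#' Computes the segment-level CIN scores commonly used alongside the
#' affected-chromosome score: the number of copy-number abnormalities
#' (segments with |log-ratio| above threshold), the number of breakpoints
#' (adjacent same-chromosome segment pairs whose total copy number differs),
#' the fraction of the genome altered (aberrant length over total build
#' length) and the total aberration index (length-weighted mean
#' |log-ratio|).
#'
#' Segments lacking a log-ratio get one derived as
#' `log2(max(total_cn, 0.5) / 2)`.
#'
#' @param profile a [segmented_profile()].
#' @param build a [genome_build()]; its total length is the FGA denominator.
#' @param config a [cin_config()].
#' @return one-row data frame with `sample_id`, `cna_segment_count`,
#'   `breakpoint_count`, `fga`, `tai`.
#' @export
cin_metric_scores <- function(profile, build = genome_b37(),
                              config = cin_config()) {
  s <- profile$segments
  if (nrow(s) == 0) {
    warning("profile '", profile$sample_id, "' has no segments; all scores 0")
    return(data.frame(sample_id = profile$sample_id, cna_segment_count = 0L,
                      breakpoint_count = 0L, fga = 0, tai = 0,
                      stringsAsFactors = FALSE))
  }
  lr <- segment_log_ratio(s)
  len <- s$end - s$start
  aberrant <- abs(lr) > config$log_ratio_threshold
  breaks <- 0L
  for (chr in unique(s$chrom)) {
    tc <- s$total_cn[s$chrom == chr]
    if (length(tc) > 1) breaks <- breaks + sum(diff(tc) != 0)
  }
  tai_idx <- if (config$tai_masked) aberrant else rep(TRUE, nrow(s))
  tai <- if (any(tai_idx)) sum(len[tai_idx] * abs(lr[tai_idx])) / sum(len[tai_idx]) else 0
  data.frame(sample_id = profile$sample_id,
             cna_segment_count = sum(aberrant),
             breakpoint_count = breaks,
             fga = sum(len[aberrant]) / sum(build$length),
             tai = tai,
             stringsAsFactors = FALSE)
}

#' Cohort CIN table
#'
#' One row per sample: group, ploidy, the affected-chromosome CIN summary and
#' the comparator metric scores, ordered by sample id.
#'
#' @param profiles list of [segmented_profile()].
#' @param config a [cin_config()].
#' @param build a [genome_build()].
#' @return data frame with one row per sample.
#' @export
cohort_cin_table <- function(profiles, config = cin_config(),
                             build = genome_b37()) {
  if (length(profiles) == 0) {
    return(data.frame(sample_id = character(), group = character(),
                      ploidy = numeric(), n_chr_cnv_only = integer(),
                      n_chr_loh_only = integer(), n_chr_both = integer(),
                      n_chr_total = integer(), complexity = character(),
                      cna_segment_count = integer(), breakpoint_count = integer(),
                      fga = numeric(), tai = numeric(), stringsAsFactors = FALSE))
  }
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(profiles, function(p) {
    cs <- summarize_cin(p, config)
    cbind(cs[1],
          data.frame(group = p$group, ploidy = p$ploidy, stringsAsFactors = FALSE),
          cs[-1],
          cin_metric_scores(p, build, config)[-1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), ]
  rownames(out) <- NULL
  out
}
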