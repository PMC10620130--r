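#' Run the CIN analysis pipeline on a cohort
#'
#' Ties the stages together for a cohort of segmented profiles: the
#' per-sample affected-chromosome CIN table with comparator metrics, the
#' per-chromosome chromothripsis calls, and the exact Mann-Whitney
#' comparison of affected-chromosome totals between metastatic and
#' non-metastatic samples (when both groups are present). When `out_dir` is
#' given, each table is also written as TSV; writes are atomic
#' (temp-then-rename) and nothing is written if any stage fails.
#'
#' @param profiles named list of [segmented_profile()], or a path to a
#'   segment TSV readable by [read_segment_table()].
#' @param meta optional metadata table or path (see [read_segment_table()]);
#'   used only when `profiles` is a path.
#' @param build a [genome_build()].
#' @param cin a [cin_config()].
#' @param ct a [chromothripsis_config()].
#' @param out_dir optional output directory for `cin_table.tsv`,
#'   `chromothripsis.tsv` and `group_comparison.tsv`.
#' @return list with `cin_table`, `chromothripsis` and `comparison` (a
#'   `group_comparison` or `NULL` when a group is absent).
#' @export
run_cin_pipeline <- function(profiles, meta = NULL, build = genome_b37(),
                             cin = cin_config(), ct = chromothripsis_config(),
                             out_dir = NULL) {
  if (is.character(profiles))
    profiles <- read_segment_table(profiles, build = build, meta = meta)
  if (length(profiles) == 0) stop("no profiles to analyse")
  for (p in profiles) {
    v <- validate_profile(p, build)
    if (length(v)) stop("invalid profile '", p$sample_id, "': ",
                        paste(v, collapse = "; "))
  }
  cin_table <- cohort_cin_table(profiles, cin, build)
  ct_table <- cohort_chromothripsis_table(profiles, ct)
  comparison <- NULL
  if (all(c("metastatic", "non_metastatic") %in% cin_table$group))
    comparison <- compare_groups(cin_table, "n_chr_total")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv_atomic(cin_table, file.path(out_dir, "cin_table.tsv"))
    write_tsv_atomic(ct_table, file.path(out_dir, "chromothripsis.tsv"))
    if (!is.null(comparison)) {
      comp_df <- data.frame(
        column = "n_chr_total", group_a = "metastatic",
        group_b = "non_metastatic", n_a = comparison$n_a,
        n_b = comparison$n_b, u_statistic = comparison$u_statistic,
        p_two_sided = comparison$p_two_sided, method = comparison$method,
        median_a = comparison$median_a, median_b = comparison$median_b,
        stringsAsFactors = FALSE)
      write_tsv_atomic(comp_df, file.path(out_dir, "group_comparison.tsv"))
    }
  }
  list(cin_table = cin_table, chromothripsis = ct_table,
       comparison = comparison)
}

# atomic TSV write: temp file in the target directory, then rename
write_tsv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
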