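#' Segmented allele-specific copy-number profiles
#'
#' A `segmented_profile` holds one sample's allele-specific copy-number state:
#' a segment table with columns `chrom`, `start`, `end` (internal 0-based,
#' half-open coordinates), `total_cn`, `minor_cn` and `log_ratio` (NA when
#' unknown), sorted by chromosome then start, pairwise non-overlapping within
#' a chromosome. Segments need not tile the chromosome; gaps carry no state.
#'
#' @param sample_id sample identifier.
#' @param segments data frame with at least `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`; optional `log_ratio`. Coordinates are taken as
#'   internal (0-based half-open) — use [read_segment_table()] for files.
#' @param group one of `"metastatic"`, `"non_metastatic"`, `"unknown"`.
#' @param ploidy tumour ploidy (> 0).
#' @param sex `"male"`, `"female"` or `NA`; used only to decide whether the
#'   X chromosome is eligible for copy-neutral LOH counting.
#' @param validate check invariants and stop on violation.
#' @return object of class `segmented_profile`.
#' @export
segmented_profile <- function(sample_id, segments,
                              group = c("unknown", "metastatic", "non_metastatic"),
                              ploidy = 2, sex = NA_character_, validate = TRUE) {
  group <- match.arg(group)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table missing column(s): ", paste(miss, collapse = ", "))
  if (!"log_ratio" %in% names(segments)) segments$log_ratio <- NA_real_
  segments$chrom <- normalize_chrom(segments$chrom)
  segments <- segments[order(match(segments$chrom, unique(segments$chrom)), segments$start),
                       c(req, "log_ratio")]
  rownames(segments) <- NULL
  prof <- structure(list(sample_id = as.character(sample_id), group = group,
                         ploidy = as.numeric(ploidy), sex = sex,
                         segments = segments),
                    class = "segmented_profile")
  if (validate) {
    v <- validate_profile(prof)
    if (length(v)) stop("invalid profile '", sample_id, "': ",
                        paste(v, collapse = "; "))
  }
  prof
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("segmented_profile '%s' (%s, ploidy %.2f): %d segments on %d chromosome(s)\n",
              x$sample_id, x$group, x$ploidy, nrow(x$segments),
              length(unique(x$segments$chrom))))
  invisible(x)
}

#' Validate a segmented profile
#'
#' Checks the type invariants (start < end, non-negative integer copy
#' numbers, minor allele really the lesser allele, sorted non-overlapping
#' segments per chromosome, ploidy > 0) and, when a build is supplied, that
#' every segment lies within its chromosome.
#'
#' @param profile a [segmented_profile()].
#' @param build optional [genome_build()]; when given, unknown chromosomes
#'   and out-of-bounds segments are reported.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_profile <- function(profile, build = NULL) {
  v <- character()
  s <- profile$segments
  if (!is.numeric(profile$ploidy) || !is.finite(profile$ploidy) || profile$ploidy <= 0)
    v <- c(v, "ploidy must be a positive number")
  if (nrow(s) == 0) return(v)
  bad <- which(s$start >= s$end)
  if (length(bad)) v <- c(v, sprintf("segment row %d: start >= end", bad))
  bad <- which(s$total_cn < 0 | s$minor_cn < 0 |
                 s$total_cn != floor(s$total_cn) | s$minor_cn != floor(s$minor_cn))
  if (length(bad)) v <- c(v, sprintf("segment row %d: copy numbers must be non-negative integers", bad))
  bad <- which(s$minor_cn > s$total_cn - s$minor_cn)
  if (length(bad))
    v <- c(v, sprintf("segment row %d: minor_cn (%d) exceeds total_cn - minor_cn",
                      bad, s$minor_cn[bad]))
  for (chr in unique(s$chrom)) {
    i <- which(s$chrom == chr)
    if (is.unsorted(s$start[i]))
      v <- c(v, sprintf("chromosome %s: segments not sorted by start", chr))
    if (length(i) > 1) {
      o <- order(s$start[i]); i <- i[o]
      ov <- which(s$start[i][-1] < s$end[i][-length(i)])
      if (length(ov))
        v <- c(v, sprintf("chromosome %s: rows %d and %d overlap", chr, i[ov], i[ov + 1]))
    }
  }
  if (!is.null(build)) {
    unk <- setdiff(unique(s$chrom), build$chrom)
    if (length(unk)) v <- c(v, sprintf("unknown chromosome '%s' for build %s",
                                       unk, attr(build, "name")))
    known <- s$chrom %in% build$chrom
    over <- which(known & s$end > chrom_length(build, s$chrom))
    if (length(over))
      v <- c(v, sprintf("segment row %d: end %d beyond chromosome %s length",
                        over, s$end[over], s$chrom[over]))
  }
  v
}

#' Read allele-specific segment tables
#'
#' Reads a FACETS-style tab-delimited segment table covering one or more
#' samples and returns one validated [segmented_profile()] per sample. File
#' coordinates are 1-based inclusive by default (SEG convention) and are
#' converted to the internal 0-based half-open representation; pass
#' `dialect = "bed"` for files that are already 0-based half-open.
#'
#' @param path tab-delimited file with header columns `sample`, `chrom`,
#'   `start`, `end`, `total_cn`, `minor_cn` and optionally `log_ratio`.
#' @param build [genome_build()] used to reject unknown chromosomes and
#'   out-of-bounds segments.
#' @param dialect `"seg"` (1-based inclusive, default) or `"bed"`
#'   (0-based half-open).
#' @param meta optional metadata table (or path to one) with columns
#'   `sample`, `group`, `ploidy` and optionally `sex`, `mitotic_count`.
#' @return named list of `segmented_profile`, one per distinct sample, in
#'   order of first appearance.
#' @export
read_segment_table <- function(path, build = genome_b37(),
                               dialect = c("seg", "bed"), meta = NULL) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("segment file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("segment file '", path, "' contains a header but no rows")
    return(list())
  }
  if (dialect == "seg") tab$start <- tab$start - 1L
  if (!is.null(meta) && !is.data.frame(meta)) meta <- read_profile_meta(meta)
  profiles <- list()
  for (sid in unique(tab$sample)) {
    rows <- tab[tab$sample == sid, ]
    grp <- "unknown"; pl <- 2; sex <- NA_character_
    if (!is.null(meta)) {
      m <- meta[meta$sample == sid, ]
      if (nrow(m) == 1) {
        if ("group" %in% names(m)) grp <- as.character(m$group)
        if ("ploidy" %in% names(m)) pl <- m$ploidy
        if ("sex" %in% names(m)) sex <- as.character(m$sex)
      }
    }
    prof <- segmented_profile(sid, rows[setdiff(names(rows), "sample")],
                              group = grp, ploidy = pl, sex = sex,
                              validate = FALSE)
    v <- validate_profile(prof, build)
    if (length(v)) stop("invalid segments for sample '", sid, "': ",
                        paste(v, collapse = "; "))
    profiles[[sid]] <- prof
  }
  profiles
}

#' Write profiles back to a segment TSV
#'
#' Inverse of [read_segment_table()]: internal 0-based half-open coordinates
#' are converted back to the requested on-disk dialect, so write-then-read
#' round-trips any valid profile exactly.
#'
#' @param profiles a `segmented_profile` or list of them.
#' @param path output path.
#' @param dialect `"seg"` (1-based inclusive) or `"bed"`.
#' @export
write_segment_table <- function(profiles, path, dialect = c("seg", "bed")) {
  dialect <- match.arg(dialect)
  if (inherits(profiles, "segmented_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    cbind(sample = p$sample_id, p$segments, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(sample = character(), chrom = character(),
                       start = integer(), end = integer(),
                       total_cn = integer(), minor_cn = integer(),
                       log_ratio = numeric())
  if (dialect == "seg") rows$start <- rows$start + 1L
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile metadata table
#'
#' @param path TSV with columns `sample`, `group`, `ploidy` and optionally
#'   `sex`, `mitotic_count`.
#' @return data frame.
#' @export
read_profile_meta <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(m)) stop("metadata file must have a 'sample' column")
  m
}

# segments of one profile restricted to one chromosome
profile_chrom_segments <- function(profile, chrom) {
  s <- profile$segments
  s[s$chrom == chrom, , drop = FALSE]
}
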