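#' Chromothripsis detection configuration
#'
#' A chromosome is called chromothripsis-positive with high confidence when
#' it carries `switch_threshold` or more copy-number state switches within a
#' `window_bp` interval (defaults: 10 switches within 50 Mb).
#'
#' @param switch_threshold minimum switches within the window (default 10).
#' @param window_bp window size in bp (default 50,000,000).
#' @param state_mode `"total_cn"` compares adjacent segments by total copy
#'   number only (default); `"allele_specific"` compares the pair
#'   (total_cn, minor_cn), so transitions into copy-neutral LOH also count
#'   as switches.
#' @return list of class `chromothripsis_config`.
#' @export
chromothripsis_config <- function(switch_threshold = 10L,
                                  window_bp = 50e6,
                                  state_mode = c("total_cn", "allele_specific")) {
  state_mode <- match.arg(state_mode)
  stopifnot(switch_threshold >= 1, window_bp >= 1)
  structure(list(switch_threshold = as.integer(switch_threshold),
                 window_bp = window_bp, state_mode = state_mode),
            class = "chromothripsis_config")
}

#' Copy-number state switch positions along one chromosome
#'
#' Adjacent segments (in sorted order, including across gaps) whose states
#' differ contribute one switch; its coordinate is the end of the left
#' segment.
#'
#' @param segments sorted, non-overlapping segment rows on one chromosome.
#' @param state_mode see [chromothripsis_config()].
#' @return sorted numeric vector of breakpoint positions (bp).
#' @export
switch_breakpoints <- function(segments, state_mode = c("total_cn", "allele_specific")) {
  state_mode <- match.arg(state_mode)
  if (length(unique(segments$chrom)) > 1)
    stop("switch_breakpoints expects segments of a single chromosome")
  n <- nrow(segments)
  if (n < 2) return(numeric())
  if (is.unsorted(segments$start))
    stop("segments must be sorted by start")
  if (any(segments$start[-1] < segments$end[-n]))
    stop("segments must be non-overlapping")
  differs <- if (state_mode == "total_cn") {
    diff(segments$total_cn) != 0
  } else {
    diff(segments$total_cn) != 0 | diff(segments$minor_cn) != 0
  }
  segments$end[-n][differs]
}

#' Maximum number of switches in any fixed-width window
#'
#' Exact maximum, over all half-open windows `[x, x + window_bp)`, of the
#' number of breakpoint positions inside. Since the count as a function of
#' `x` only increases when `x` lands on a position, it suffices to anchor
#' windows at each position.
#'
#' @param positions sorted numeric vector of breakpoint positions.
#' @param window_bp window width in bp.
#' @return integer maximum count.
#' @export
max_switches_in_window <- function(positions, window_bp = 50e6) {
  if (length(positions) == 0) return(0L)
  if (is.unsorted(positions)) stop("positions must be sorted")
  # two-pointer scan: for each anchor i, count positions in [p_i, p_i + window)
  n <- length(positions)
  best <- 0L
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && positions[j + 1L] < positions[i] + window_bp) j <- j + 1L
    best <- max(best, j - i + 1L)
  }
  as.integer(best)
}

#' Call chromothripsis-like oscillation per chromosome
#'
#' For each chromosome of a profile, counts copy-number state switches,
#' maximises the count over sliding windows, and flags high confidence when
#' the windowed maximum reaches the threshold.
#'
#' @param profile a [segmented_profile()].
#' @param config a [chromothripsis_config()].
#' @param include_all when `FALSE` (default) chromosomes with zero switches
#'   are omitted from the output.
#' @return data frame with columns `sample_id`, `chrom`, `n_switches_total`,
#'   `max_switches_in_window`, `high_confidence`.
#' @export
call_chromothripsis <- function(profile, config = chromothripsis_config(),
                                include_all = FALSE) {
  chroms <- unique(profile$segments$chrom)
  rows <- lapply(chroms, function(chr) {
    bp <- switch_breakpoints(profile_chrom_segments(profile, chr),
                             config$state_mode)
    data.frame(sample_id = profile$sample_id, chrom = chr,
               n_switches_total = length(bp),
               max_switches_in_window = max_switches_in_window(bp, config$window_bp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      n_switches_total = integer(),
                      max_switches_in_window = integer(),
                      stringsAsFactors = FALSE)
  out$high_confidence <- out$max_switches_in_window >= config$switch_threshold
  if (!include_all) out <- out[out$n_switches_total > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromothripsis calls for a cohort
#'
#' @param profiles list of [segmented_profile()].
#' @param config a [chromothripsis_config()].
#' @param include_all passed to [call_chromothripsis()].
#' @return row-bound data frame of per-chromosome calls.
#' @export
cohort_chromothripsis_table <- function(profiles,
                                        config = chromothripsis_config(),
                                        include_all = FALSE) {
  out <- do.call(rbind, lapply(profiles, call_chromothripsis,
                               config = config, include_all = include_all))
  if (is.null(out))
    out <- call_chromothripsis(segmented_profile(
      "empty", data.frame(chrom = character(), start = integer(),
                          end = integer(), total_cn = integer(),
                          minor_cn = integer())), config)
  rownames(out) <- NULL
  out
}
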