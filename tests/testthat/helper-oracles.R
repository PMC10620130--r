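# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, kept separate from the package code
# paths they check.

# per-segment scan over a profile: classify each chromosome by looping over
# individual segment rows
oracle_cin_counts <- function(profile, baseline = 2) {
  s <- profile$segments
  cnv_only <- loh_only <- both <- 0
  for (chr in unique(s$chrom)) {
    cnv <- FALSE; loh <- FALSE
    for (i in which(s$chrom == chr)) {
      if (s$total_cn[i] != baseline) cnv <- TRUE
      if (s$total_cn[i] == baseline && s$minor_cn[i] == 0) loh <- TRUE
    }
    if (chr == "X" && identical(tolower(as.character(profile$sex)), "male"))
      loh <- FALSE
    if (cnv && loh) both <- both + 1
    else if (cnv) cnv_only <- cnv_only + 1
    else if (loh) loh_only <- loh_only + 1
  }
  c(cnv_only = cnv_only, loh_only = loh_only, both = both,
    total = cnv_only + loh_only + both)
}

# exhaustive window scan anchored at every integer position between the
# extremes (valid for small coordinates)
oracle_max_window <- function(positions, window) {
  if (length(positions) == 0) return(0L)
  best <- 0L
  for (x in seq(min(positions) - window, max(positions))) {
    best <- max(best, sum(positions >= x & positions < x + window))
  }
  as.integer(best)
}

# direct per-anchor count at the positions themselves (naive quadratic form)
oracle_max_window_at_positions <- function(positions, window) {
  if (length(positions) == 0) return(0L)
  as.integer(max(vapply(positions, function(p)
    sum(positions >= p & positions < p + window), numeric(1))))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(a, b) {
  n_a <- length(a); pooled <- c(a, b); n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  us <- apply(utils::combn(n, n_a), 2, u_of)
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# a small random valid profile on a toy build (few chromosomes, integer
# coordinates), used by the CIN and chromothripsis property suites
random_small_profile <- function(n_chroms = 3, max_segs = 6, chrom_len = 1000) {
  chroms <- as.character(seq_len(n_chroms))
  segs <- do.call(rbind, lapply(chroms, function(chr) {
    k <- sample(1:max_segs, 1)
    cuts <- sort(sample(1:(chrom_len - 1), k - 1))
    bounds <- c(0, cuts, chrom_len)
    total <- sample(0:4, k, replace = TRUE)
    pick1 <- function(x) x[sample.int(length(x), 1)]   # sample() misreads length-1 vectors
    minor <- vapply(total, function(t) pick1(0:(t %/% 2)), integer(1))
    data.frame(chrom = chr, start = bounds[-length(bounds)], end = bounds[-1],
               total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
  }))
  segmented_profile(paste0("R", sample.int(1e6, 1)), segs)
}

toy_build <- function(n_chroms = 3, chrom_len = 1000) {
  genome_build("toy", data.frame(chrom = as.character(seq_len(n_chroms)),
                                 length = chrom_len))
}
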