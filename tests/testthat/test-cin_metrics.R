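seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]],
               total_cn = r[[4]], minor_cn = r[[5]], stringsAsFactors = FALSE)))
}

test_that("chromosome_status distinguishes CNV, cnLOH and unaffected", {
  cfg <- cin_config()
  # heterozygous diploid throughout
  s <- seg_df(list("1", 0, 100, 2, 1), list("1", 100, 300, 2, 1))
  expect_equal(chromosome_status(s, cfg),
               list(cnv_affected = FALSE, cnloh_affected = FALSE))
  # a single-copy loss among diploid segments is CNV
  s <- seg_df(list("1", 0, 100, 2, 1), list("1", 100, 200, 1, 0))
  expect_equal(chromosome_status(s, cfg),
               list(cnv_affected = TRUE, cnloh_affected = FALSE))
  # copy-neutral LOH: baseline total, zero minor allele
  s <- seg_df(list("1", 0, 100, 2, 0))
  expect_equal(chromosome_status(s, cfg),
               list(cnv_affected = FALSE, cnloh_affected = TRUE))
  # mixed chromosomes rejected
  s <- seg_df(list("1", 0, 100, 2, 1), list("2", 0, 100, 2, 1))
  expect_error(chromosome_status(s, cfg), "single chromosome")
})

test_that("min_aberrant_len_bp, ploidy baseline and male-X rules apply", {
  # short aberration ignored under a length filter
  s <- seg_df(list("1", 0, 50, 1, 0), list("1", 50, 1000, 2, 1))
  expect_false(chromosome_status(s, cin_config(min_aberrant_len_bp = 100))$cnv_affected)
  expect_true(chromosome_status(s, cin_config())$cnv_affected)
  # near-tetraploid sample: total 4 is baseline in ploidy mode
  s <- seg_df(list("1", 0, 100, 4, 2))
  expect_true(chromosome_status(s, cin_config(), ploidy = 3.9)$cnv_affected)
  cfg_p <- cin_config(baseline_mode = "nearest_integer_ploidy")
  expect_false(chromosome_status(s, cfg_p, ploidy = 3.9)$cnv_affected)
  # hemizygous-looking X is not cnLOH in a male sample
  s <- seg_df(list("X", 0, 100, 2, 0))
  expect_false(chromosome_status(s, cin_config(), sex = "male")$cnloh_affected)
  expect_true(chromosome_status(s, cin_config(), sex = "female")$cnloh_affected)
})

test_that("complexity threshold is >= 10, exactly", {
  expect_equal(classify_complexity(9), "Simple")
  expect_equal(classify_complexity(10), "Complex")
  expect_equal(classify_complexity(0), "Simple")
  expect_equal(classify_complexity(c(1, 10, 22)),
               c("Simple", "Complex", "Complex"))
})

test_that("summarize_cin recovers planted counts and labels", {
  sim <- simulate_profile(profile_spec("P1", n_cnv_only = 8, n_both = 5),
                          seed = 2)
  cs <- summarize_cin(sim$profile)
  expect_equal(cs$n_chr_cnv_only, 8)
  expect_equal(cs$n_chr_loh_only, 0)
  expect_equal(cs$n_chr_both, 5)
  expect_equal(cs$n_chr_total, 13)
  expect_equal(cs$complexity, "Complex")

  cs7 <- summarize_cin(simulate_profile(profile_spec("P2", n_cnv_only = 7),
                                        seed = 3)$profile)
  expect_equal(unname(unlist(cs7[2:5])), c(7, 0, 0, 7))
  expect_equal(cs7$complexity, "Simple")

  cs0 <- summarize_cin(simulate_profile(profile_spec("P3"), seed = 4)$profile)
  expect_equal(unname(unlist(cs0[2:5])), c(0, 0, 0, 0))
  expect_equal(cs0$complexity, "Simple")
})

test_that("summarize_cin matches a brute-force per-segment scan on random profiles", {
  set.seed(42)
  for (i in 1:60) {
    p <- random_small_profile(n_chroms = sample(1:5, 1),
                              max_segs = sample(1:10, 1))
    cs <- summarize_cin(p)
    oracle <- oracle_cin_counts(p)
    expect_equal(unname(unlist(cs[2:5])), unname(oracle),
                 info = paste("profile", i))
    # partition property: total equals the number of flagged chromosomes
    expect_equal(cs$n_chr_total,
                 cs$n_chr_cnv_only + cs$n_chr_loh_only + cs$n_chr_both)
  }
})

test_that("adding an aberrant segment to an unaffected chromosome never lowers the total", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_small_profile(n_chroms = 3)
    before <- summarize_cin(p)
    extra <- data.frame(chrom = "99", start = 0, end = 500,
                        total_cn = 1, minor_cn = 0, log_ratio = NA_real_)
    p2 <- segmented_profile(p$sample_id, rbind(p$segments, extra))
    after <- summarize_cin(p2)
    expect_gte(after$n_chr_total, before$n_chr_total)
    expect_false(before$complexity == "Complex" && after$complexity == "Simple")
  }
})

test_that("cin_metric_scores evaluates the stated formulas", {
  build <- genome_build("one", data.frame(chrom = "1", length = 100e6))
  segs <- data.frame(chrom = "1", start = c(0, 50e6), end = c(50e6, 100e6),
                     total_cn = c(4, 2), minor_cn = c(2, 1),
                     log_ratio = c(1, 0))
  p <- segmented_profile("M", segs)
  sc <- cin_metric_scores(p, build)
  expect_equal(sc$cna_segment_count, 1)
  expect_equal(sc$breakpoint_count, 1)
  expect_equal(sc$fga, 0.5)
  expect_equal(sc$tai, 0.5)

  # no aberrant segments -> all zero
  neutral <- segmented_profile("N", data.frame(
    chrom = "1", start = 0, end = 100e6, total_cn = 2, minor_cn = 1,
    log_ratio = 0))
  sc0 <- cin_metric_scores(neutral, build)
  expect_equal(unname(unlist(sc0[2:5])), c(0, 0, 0, 0))

  # fully aberrant genome -> fga exactly 1
  full <- segmented_profile("F", data.frame(
    chrom = "1", start = 0, end = 100e6, total_cn = 4, minor_cn = 2,
    log_ratio = 1))
  expect_equal(cin_metric_scores(full, build)$fga, 1)

  # empty profile warns and zeroes
  empty <- segmented_profile("E", segs[0, ])
  expect_warning(sce <- cin_metric_scores(empty, build), "no segments")
  expect_equal(sce$fga, 0)
})

test_that("fga and tai are invariant under equal-state splits; breakpoints too", {
  build <- toy_build(3)
  set.seed(13)
  for (i in 1:20) {
    p <- random_small_profile(3)
    p$segments$log_ratio <- NULL
    p <- segmented_profile(p$sample_id, p$segments)
    p2 <- split_segments_noise(p, n_splits = 8, seed = i)
    a <- cin_metric_scores(p, build)
    b <- cin_metric_scores(p2, build)
    expect_equal(b$fga, a$fga)
    expect_equal(b$tai, a$tai)
    expect_equal(b$breakpoint_count, a$breakpoint_count)
  }
})

test_that("cohort_cin_table is one row per sample and rejects duplicates", {
  specs <- lapply(1:4, function(i) profile_spec(paste0("S", i), n_cnv_only = i))
  sim <- simulate_cohort(specs, seed = 5)
  tab <- cohort_cin_table(sim$profiles)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$sample_id, sort(tab$sample_id))

  expect_equal(nrow(cohort_cin_table(list())), 0)
  dup <- sim$profiles[c(1, 1)]
  expect_error(cohort_cin_table(dup), "duplicate")
})
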