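ct_segs <- function(totals, bounds, chrom = "1") {
  data.frame(chrom = chrom, start = bounds[-length(bounds)], end = bounds[-1],
             total_cn = totals, minor_cn = pmin(1, totals),
             stringsAsFactors = FALSE)
}

test_that("switch_breakpoints counts state changes between adjacent segments", {
  # uniform state: no switches
  s <- ct_segs(rep(2, 5), seq(0, 500, by = 100))
  expect_equal(switch_breakpoints(s), numeric())
  # totals 2,3,2: two switches at the internal boundaries
  s <- ct_segs(c(2, 3, 2), c(0, 100, 200, 300))
  expect_equal(switch_breakpoints(s), c(100, 200))
  # equal-state adjacency is not a switch
  s <- ct_segs(c(2, 2, 3), c(0, 100, 200, 300))
  expect_equal(switch_breakpoints(s), 200)
  # allele-specific mode sees cnLOH transitions that total-only mode misses
  s <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200),
                  total_cn = c(2, 2), minor_cn = c(1, 0))
  expect_equal(switch_breakpoints(s, "total_cn"), numeric())
  expect_equal(switch_breakpoints(s, "allele_specific"), 100)
  # unsorted input is a contract error
  s <- ct_segs(c(2, 3), c(0, 100, 200))[2:1, ]
  expect_error(switch_breakpoints(s), "sorted")
})

test_that("max_switches_in_window is exact on the derived examples", {
  expect_equal(max_switches_in_window(numeric(), 50e6), 0L)
  # 12 positions inside a 40 Mb span, 50 Mb window: all in one window
  pos <- sort(seq(5e6, 45e6, length.out = 12))
  expect_equal(max_switches_in_window(pos, 50e6), 12L)
  # positions at 0,10,...,90 Mb, half-open 50 Mb window holds five
  pos <- seq(0, 90e6, by = 10e6)
  expect_equal(max_switches_in_window(pos, 50e6), 5L)
})

test_that("windowed maximisation matches an exhaustive anchor scan", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(0:40, 1)
    pos <- sort(sample(0:800, n))
    w <- sample(10:300, 1)
    expect_equal(max_switches_in_window(pos, w), oracle_max_window(pos, w),
                 info = sprintf("case %d (n=%d, w=%d)", i, n, w))
  }
})

test_that("window and threshold monotonicity hold", {
  set.seed(3)
  for (i in 1:30) {
    pos <- sort(sample(0:1000, sample(1:30, 1)))
    w1 <- sample(10:200, 1); w2 <- w1 + sample(1:200, 1)
    expect_lte(max_switches_in_window(pos, w1), max_switches_in_window(pos, w2))
  }
})

test_that("planted oscillations are called at the 10-switch/50 Mb rule", {
  # 26 switches inside 30 Mb: high confidence
  sim <- simulate_profile(
    profile_spec("G7", chromothriptic = list(list(chrom = "1", n_switches = 26,
                                                  span_bp = 30e6))), seed = 5)
  call <- call_chromothripsis(sim$profile)
  expect_equal(nrow(call), 1)
  expect_equal(call$chrom, "1")
  expect_equal(call$n_switches_total, 26)
  expect_true(call$high_confidence)
  # 9 switches inside 50 Mb: below threshold
  sim9 <- simulate_profile(
    profile_spec("S", chromothriptic = list(list(chrom = "2", n_switches = 9,
                                                 span_bp = 50e6))), seed = 6)
  expect_false(call_chromothripsis(sim9$profile)$high_confidence)
  # fully diploid profile emits no call, but include_all lists chromosomes
  flat <- simulate_profile(profile_spec("F"), seed = 7)$profile
  expect_equal(nrow(call_chromothripsis(flat)), 0)
  expect_gt(nrow(call_chromothripsis(flat, include_all = TRUE)), 0)
})

test_that("max window count never exceeds the switch total and obeys the invariant", {
  sim <- simulate_profile(
    profile_spec("W", chromothriptic = list(list(chrom = "4", n_switches = 20,
                                                 span_bp = 120e6))), seed = 8)
  call <- call_chromothripsis(sim$profile)
  expect_lte(call$max_switches_in_window, call$n_switches_total)
  expect_equal(call$high_confidence, call$max_switches_in_window >= 10)
})

test_that("equal-state splits and merges never change a call", {
  sim <- simulate_profile(
    profile_spec("M", n_cnv_only = 2,
                 chromothriptic = list(list(chrom = "3", n_switches = 12,
                                            span_bp = 40e6))), seed = 9)
  base <- call_chromothripsis(sim$profile)
  split <- call_chromothripsis(split_segments_noise(sim$profile, 40, seed = 10))
  expect_equal(split[c("chrom", "n_switches_total", "max_switches_in_window",
                       "high_confidence")],
               base[c("chrom", "n_switches_total", "max_switches_in_window",
                      "high_confidence")])
})
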