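#' Specification of one synthetic segmented profile
#'
#' Describes the ground truth to plant in a simulated sample: how many
#' chromosomes carry CNV only, copy-neutral LOH only, or both, and which
#' chromosomes receive a chromothriptic oscillation pattern.
#'
#' @param sample_id sample identifier.
#' @param group `"metastatic"`, `"non_metastatic"` or `"unknown"`.
#' @param ploidy tumour ploidy recorded on the profile (cosmetic; planted
#'   states are relative to a diploid baseline).
#' @param n_cnv_only,n_loh_only,n_both numbers of chromosomes to affect with
#'   CNV only, cnLOH only, and both.
#' @param chromothriptic list of `list(chrom =, n_switches =, span_bp =)`
#'   entries; each named chromosome receives `n_switches + 1` alternating
#'   copy-number segments whose `n_switches` breakpoints are evenly spaced
#'   within `span_bp`.
#' @param sex optional sample sex.
#' @return list of class `profile_spec`.
#' @export
profile_spec <- function(sample_id, group = "unknown", ploidy = 2,
                         n_cnv_only = 0, n_loh_only = 0, n_both = 0,
                         chromothriptic = list(), sex = NA_character_) {
  stopifnot(n_cnv_only >= 0, n_loh_only >= 0, n_both >= 0)
  ct_chroms <- vapply(chromothriptic, function(x) normalize_chrom(x$chrom),
                      character(1))
  if (anyDuplicated(ct_chroms))
    stop("duplicate chromothriptic chromosome in spec")
  structure(list(sample_id = as.character(sample_id), group = group,
                 ploidy = ploidy, n_cnv_only = as.integer(n_cnv_only),
                 n_loh_only = as.integer(n_loh_only),
                 n_both = as.integer(n_both),
                 chromothriptic = chromothriptic, sex = sex),
            class = "profile_spec")
}

# random interior interval of a chromosome of length L
random_interval <- function(L) {
  start <- floor(stats::runif(1, 0.15 * L, 0.45 * L))
  len <- floor(stats::runif(1, 0.10 * L, 0.30 * L))
  c(start, min(start + len, L - 1))
}

seg_row <- function(chrom, start, end, total, minor) {
  data.frame(chrom = chrom, start = start, end = end,
             total_cn = total, minor_cn = minor,
             log_ratio = log2(pmax(total, 0.5) / 2),
             stringsAsFactors = FALSE)
}

# segments for one chromosome given its planted role
simulate_chrom_segments <- function(chrom, L, role) {
  neutral <- function(s, e) seg_row(chrom, s, e, 2, 1)
  if (role == "neutral") return(neutral(0, L))
  if (role == "cnv") {
    iv <- random_interval(L)
    total <- sample(c(1L, 3L), 1)
    rbind(neutral(0, iv[1]),
          seg_row(chrom, iv[1], iv[2], total, if (total == 1) 0 else 1),
          neutral(iv[2], L))
  } else if (role == "loh") {
    iv <- random_interval(L)
    rbind(neutral(0, iv[1]),
          seg_row(chrom, iv[1], iv[2], 2, 0),
          neutral(iv[2], L))
  } else if (role == "both") {
    mid <- floor(L / 2)
    iv1 <- random_interval(mid)
    iv2 <- mid + random_interval(L - mid - 1)
    total <- sample(c(1L, 3L), 1)
    rbind(neutral(0, iv1[1]),
          seg_row(chrom, iv1[1], iv1[2], total, if (total == 1) 0 else 1),
          neutral(iv1[2], iv2[1]),
          seg_row(chrom, iv2[1], iv2[2], 2, 0),
          neutral(iv2[2], L))
  } else stop("unknown role: ", role)
}

# alternating 2<->3 run with n_switches breakpoints evenly spaced in span_bp
simulate_chromothriptic_segments <- function(chrom, L, n_switches, span_bp) {
  if (span_bp > L) stop("span_bp exceeds chromosome ", chrom, " length")
  off <- floor(stats::runif(1, 0, L - span_bp))
  k <- as.integer(n_switches)
  if (k == 0) return(list(segments = seg_row(chrom, off, off + span_bp, 2, 1),
                          breakpoints = numeric()))
  bounds <- off + round(seq(0, span_bp, length.out = k + 2))
  bounds <- unique(bounds)
  if (length(bounds) < k + 2)
    stop("span_bp too small to hold ", k, " distinct switch positions")
  totals <- rep(c(2L, 3L), length.out = k + 1)
  segs <- do.call(rbind, lapply(seq_len(k + 1), function(i)
    seg_row(chrom, bounds[i], bounds[i + 1], totals[i], 1)))
  list(segments = segs, breakpoints = bounds[2:(k + 1)])
}

#' Simulate one segmented profile with planted ground truth
#'
#' Chromosomes of the build are assigned disjoint roles: the spec's
#' chromothriptic chromosomes first, then (in build order) `n_cnv_only`
#' CNV-only, `n_loh_only` cnLOH-only and `n_both` both-affected chromosomes;
#' every other chromosome is heterozygous diploid throughout. A
#' chromothriptic chromosome oscillates between total copy numbers 2 and 3,
#' so it also counts as CNV-affected in the ground-truth CIN summary.
#'
#' @param spec a [profile_spec()].
#' @param build a [genome_build()].
#' @param seed integer seed; the output is deterministic given
#'   (spec, build, seed).
#' @return list with elements `profile` (a [segmented_profile()]), `cin`
#'   (ground-truth one-row CIN summary data frame, complexity at the default
#'   threshold of 10) and `chromothripsis` (data frame of planted
#'   chromosomes: `chrom`, `n_switches`, `span_bp`, plus a list-column
#'   `breakpoints` of planted switch positions).
#' @export
simulate_profile <- function(spec, build = genome_b37(), seed = 1L) {
  ct_chroms <- vapply(spec$chromothriptic,
                      function(x) normalize_chrom(x$chrom), character(1))
  unknown <- setdiff(ct_chroms, build$chrom)
  if (length(unknown)) stop("chromothriptic chromosome not in build: ",
                            paste(unknown, collapse = ", "))
  free <- setdiff(build$chrom, ct_chroms)
  n_roles <- spec$n_cnv_only + spec$n_loh_only + spec$n_both
  if (n_roles > length(free))
    stop("spec claims ", n_roles, " role chromosomes but only ",
         length(free), " are free (role collision with chromothriptic ",
         "chromosomes or too few chromosomes in build)")
  roles <- stats::setNames(rep("neutral", nrow(build)), build$chrom)
  roles[free[seq_len(spec$n_cnv_only)]] <- "cnv"
  roles[free[spec$n_cnv_only + seq_len(spec$n_loh_only)]] <- "loh"
  roles[free[spec$n_cnv_only + spec$n_loh_only + seq_len(spec$n_both)]] <- "both"

  withr::with_seed(seed, {
    seg_list <- list()
    ct_truth <- list()
    for (i in seq_len(nrow(build))) {
      chr <- build$chrom[i]; L <- build$length[i]
      if (chr %in% ct_chroms) {
        ct <- spec$chromothriptic[[match(chr, ct_chroms)]]
        sim <- simulate_chromothriptic_segments(chr, L, ct$n_switches, ct$span_bp)
        seg_list[[chr]] <- sim$segments
        ct_truth[[chr]] <- data.frame(chrom = chr,
                                      n_switches = as.integer(ct$n_switches),
                                      span_bp = ct$span_bp,
                                      stringsAsFactors = FALSE)
        ct_truth[[chr]]$breakpoints <- list(sim$breakpoints)
      } else {
        seg_list[[chr]] <- simulate_chrom_segments(chr, L, roles[[chr]])
      }
    }
    profile <- segmented_profile(spec$sample_id, do.call(rbind, seg_list),
                                 group = spec$group, ploidy = spec$ploidy,
                                 sex = spec$sex)
  })

  n_ct_cnv <- sum(vapply(spec$chromothriptic,
                         function(x) x$n_switches >= 1, logical(1)))
  total <- spec$n_cnv_only + n_ct_cnv + spec$n_loh_only + spec$n_both
  truth_cin <- data.frame(
    sample_id = spec$sample_id,
    n_chr_cnv_only = spec$n_cnv_only + n_ct_cnv,
    n_chr_loh_only = spec$n_loh_only,
    n_chr_both = spec$n_both,
    n_chr_total = total,
    complexity = classify_complexity(total),
    stringsAsFactors = FALSE)
  ct_df <- do.call(rbind, ct_truth)
  if (is.null(ct_df))
    ct_df <- data.frame(chrom = character(), n_switches = integer(),
                        span_bp = numeric(), stringsAsFactors = FALSE)
  list(profile = profile, cin = truth_cin, chromothripsis = ct_df)
}

#' Simulate a cohort of profiles
#'
#' @param specs list of [profile_spec()] with unique sample ids.
#' @param build a [genome_build()].
#' @param seed integer master seed; sample `i` is generated with
#'   `seed + i - 1`, so the cohort is deterministic given (specs, seed).
#' @return list with `profiles` (named list of [segmented_profile()]),
#'   `truth_cin` (row-bound ground-truth CIN summaries) and
#'   `truth_chromothripsis` (row-bound planted chromothripsis table with a
#'   `sample_id` column).
#' @export
simulate_cohort <- function(specs, build = genome_b37(), seed = 1L) {
  ids <- vapply(specs, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  profiles <- list(); cin <- list(); ct <- list()
  for (i in seq_along(specs)) {
    sim <- simulate_profile(specs[[i]], build, seed = seed + i - 1L)
    profiles[[ids[i]]] <- sim$profile
    cin[[i]] <- sim$cin
    if (nrow(sim$chromothripsis))
      ct[[i]] <- cbind(sample_id = ids[i], sim$chromothripsis,
                       stringsAsFactors = FALSE)
  }
  truth_ct <- do.call(rbind, ct)
  if (is.null(truth_ct))
    truth_ct <- data.frame(sample_id = character(), chrom = character(),
                           n_switches = integer(), span_bp = numeric(),
                           stringsAsFactors = FALSE)
  list(profiles = profiles,
       truth_cin = do.call(rbind, cin),
       truth_chromothripsis = truth_ct)
}

#' Split segments into equal-state pieces (noise mode)
#'
#' Randomly splits segments of a profile at interior points, preserving the
#' copy-number state of both halves. CIN summaries and chromothripsis calls
#' are invariant under such splits.
#'
#' @param profile a [segmented_profile()].
#' @param n_splits number of split operations to apply.
#' @param seed integer seed.
#' @return a new `segmented_profile`.
#' @export
split_segments_noise <- function(profile, n_splits = 10, seed = 1L) {
  withr::with_seed(seed, {
    s <- profile$segments
    for (i in seq_len(n_splits)) {
      wide <- which(s$end - s$start >= 2)
      if (!length(wide)) break
      j <- if (length(wide) == 1) wide else sample(wide, 1)
      cut <- floor(stats::runif(1, s$start[j] + 1, s$end[j]))
      left <- s[j, ]; right <- s[j, ]
      left$end <- cut; right$start <- cut
      s <- rbind(s[seq_len(j - 1), , drop = FALSE], left, right,
                 s[seq_len(nrow(s)) > j, , drop = FALSE])
    }
  })
  segmented_profile(profile$sample_id, s, group = profile$group,
                    ploidy = profile$ploidy, sex = profile$sex)
}

#' Simulate ASE observations with known classes
#'
#' Generates one observation per planted class with (TPM, RNA allele count)
#' values satisfying the class's defining inequalities with a margin away
#' from the thresholds, so a correct classifier reproduces the planted
#' labels exactly.
#'
#' @param n_per_class named integer vector over the classes of
#'   [ase_classes()]; missing names default to 0.
#' @param seed integer seed.
#' @param sample_id sample id assigned to all observations.
#' @param boundary_cases when `TRUE`, appends three threshold-sitting
#'   observations: TPM exactly 2 with clearly expressed mutant allele
#'   (planted `MUTATED_EXPRESSED` — the TPM rule is inclusive), RNA VAF
#'   exactly 0.03 on an expressed gene (planted `MUTATED_NOT_EXPRESSED` —
#'   the VAF rule is strict), and TPM just below 2 (planted
#'   `GENE_NOT_EXPRESSED`).
#' @return data frame with columns `sample_id`, `gene`, `gene_tpm`,
#'   `rna_ref_count`, `rna_alt_count`, `true_class`, in random order.
#' @export
simulate_ase_table <- function(n_per_class, seed = 1L, sample_id = "S1",
                               boundary_cases = FALSE) {
  n <- stats::setNames(rep(0L, 4), ase_classes())
  n[names(n_per_class)] <- as.integer(n_per_class)
  bad <- setdiff(names(n_per_class), ase_classes())
  if (length(bad)) stop("unknown ASE class: ", paste(bad, collapse = ", "))
  withr::with_seed(seed, {
    rows <- list()
    gen <- function(k, cls, tpm, ref, alt) {
      if (k == 0) return(NULL)
      data.frame(sample_id = sample_id,
                 gene = paste0("G_", cls, "_", seq_len(k)),
                 gene_tpm = tpm, rna_ref_count = ref, rna_alt_count = alt,
                 true_class = cls, stringsAsFactors = FALSE)
    }
    k <- n[["MUTATED_EXPRESSED"]]
    if (k) {
      depth <- sample(50:200, k, replace = TRUE)
      vaf <- stats::runif(k, 0.10, 0.60)
      alt <- pmax(ceiling(depth * vaf), ceiling(depth * 0.06))
      rows$exp <- gen(k, "MUTATED_EXPRESSED", stats::runif(k, 5, 100),
                      depth - alt, alt)
    }
    k <- n[["MUTATED_NOT_EXPRESSED"]]
    if (k) {
      depth <- sample(100:300, k, replace = TRUE)
      alt <- sample(0:1, k, replace = TRUE)
      rows$nexp <- gen(k, "MUTATED_NOT_EXPRESSED", stats::runif(k, 5, 100),
                       depth - alt, alt)
    }
    k <- n[["GENE_NOT_EXPRESSED"]]
    if (k) {
      depth <- sample(10:100, k, replace = TRUE)
      alt <- pmin(depth, sample(0:20, k, replace = TRUE))
      rows$gne <- gen(k, "GENE_NOT_EXPRESSED", stats::runif(k, 0, 1.5),
                      depth - alt, alt)
    }
    k <- n[["NOT_COVERED"]]
    if (k) rows$nc <- gen(k, "NOT_COVERED", stats::runif(k, 0, 50), 0L, 0L)
    out <- do.call(rbind, rows)
    if (boundary_cases) {
      out <- rbind(out, data.frame(
        sample_id = sample_id,
        gene = c("G_boundary_tpm2", "G_boundary_vaf3pct", "G_boundary_tpm_below"),
        gene_tpm = c(2, 10, 1.999),
        rna_ref_count = c(75L, 97L, 50L),
        rna_alt_count = c(25L, 3L, 10L),
        true_class = c("MUTATED_EXPRESSED", "MUTATED_NOT_EXPRESSED",
                       "GENE_NOT_EXPRESSED"),
        stringsAsFactors = FALSE))
    }
    if (!is.null(out) && nrow(out) > 1) out <- out[sample(nrow(out)), ]
  })
  if (is.null(out))
    out <- data.frame(sample_id = character(), gene = character(),
                      gene_tpm = numeric(), rna_ref_count = integer(),
                      rna_alt_count = integer(), true_class = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate mRNA/miRNA DE tables with planted anti-correlated pairs
#'
#' Builds differential-expression statistic tables in which a known set of
#' miRNA-mRNA pairs is differentially expressed with opposite-sign fold
#' changes and connected through the interaction table at an allowed
#' confidence level. Decoys are planted alongside: a same-sign interacting
#' DE pair, a low-confidence opposite-sign interacting DE pair, and
#' interactions between non-DE entities — none of which a correct pairing
#' stage may emit.
#'
#' @param n_genes,n_mirnas table sizes.
#' @param n_de_genes,n_de_mirnas numbers of differentially expressed
#'   entities (must allow `n_planted_pairs` plus two decoy genes).
#' @param n_planted_pairs number of true opposite-sign interacting pairs.
#' @param seed integer seed.
#' @return list with `mrna`, `mirna`, `interactions` data frames and
#'   `planted_pairs` (data frame `mirna`, `gene`).
#' @export
simulate_de_tables <- function(n_genes = 200, n_de_genes = 30,
                               n_mirnas = 60, n_de_mirnas = 12,
                               n_planted_pairs = 5, seed = 1L) {
  stopifnot(n_de_genes <= n_genes, n_de_mirnas <= n_mirnas,
            n_planted_pairs <= n_de_mirnas,
            n_de_genes >= n_planted_pairs + 2, n_de_mirnas >= 2 || n_planted_pairs == 0)
  withr::with_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    mirnas <- sprintf("miR-%03d", seq_len(n_mirnas))
    de_g <- seq_len(n_de_genes); de_m <- seq_len(n_de_mirnas)

    g_lfc <- stats::runif(n_genes, -0.8, 0.8)
    g_lfc[de_g] <- sample(c(-1, 1), n_de_genes, replace = TRUE) *
      stats::runif(n_de_genes, 1.2, 4)
    g_p <- stats::runif(n_genes, 0.10, 0.95)
    g_p[de_g] <- stats::runif(n_de_genes, 1e-6, 0.04)
    mrna <- data.frame(gene = genes,
                       median_tpm_met = stats::runif(n_genes, 5, 100),
                       median_tpm_nomet = stats::runif(n_genes, 5, 100),
                       log2_fc = g_lfc, adj_p = g_p, stringsAsFactors = FALSE)

    m_lfc <- stats::runif(n_mirnas, -0.8, 0.8)
    m_lfc[de_m] <- sample(c(-1, 1), n_de_mirnas, replace = TRUE) *
      stats::runif(n_de_mirnas, 1.1, 4)
    m_q <- stats::runif(n_mirnas, 0.10, 0.95)
    m_q[de_m] <- stats::runif(n_de_mirnas, 1e-6, 0.049)
    mirna <- data.frame(mirna = mirnas,
                        median_raw_met = stats::runif(n_mirnas, 60, 600),
                        median_raw_nomet = stats::runif(n_mirnas, 60, 600),
                        median_norm_met = stats::runif(n_mirnas, 60, 600),
                        median_norm_nomet = stats::runif(n_mirnas, 60, 600),
                        log2_fc = m_lfc, q_value = m_q, stringsAsFactors = FALSE)

    ix <- list(); planted <- NULL
    if (n_planted_pairs > 0) {
      # true pairs: miRNA down, target gene up
      mirna$log2_fc[seq_len(n_planted_pairs)] <-
        -abs(mirna$log2_fc[seq_len(n_planted_pairs)])
      mrna$log2_fc[seq_len(n_planted_pairs)] <-
        abs(mrna$log2_fc[seq_len(n_planted_pairs)])
      planted <- data.frame(mirna = mirnas[seq_len(n_planted_pairs)],
                            gene = genes[seq_len(n_planted_pairs)],
                            stringsAsFactors = FALSE)
      ix$true <- data.frame(planted,
                            confidence = sample(c("experimentally_observed",
                                                  "highly_predicted"),
                                                n_planted_pairs, replace = TRUE),
                            stringsAsFactors = FALSE)
      # decoy 1: same-sign interacting DE pair (both down)
      mrna$log2_fc[n_planted_pairs + 1] <- -abs(mrna$log2_fc[n_planted_pairs + 1])
      ix$same_sign <- data.frame(mirna = mirnas[1],
                                 gene = genes[n_planted_pairs + 1],
                                 confidence = "experimentally_observed",
                                 stringsAsFactors = FALSE)
      # decoy 2: opposite-sign interacting DE pair at disallowed confidence
      mrna$log2_fc[n_planted_pairs + 2] <- abs(mrna$log2_fc[n_planted_pairs + 2])
      ix$low_conf <- data.frame(mirna = mirnas[2],
                                gene = genes[n_planted_pairs + 2],
                                confidence = "other",
                                stringsAsFactors = FALSE)
    }
    # decoy 3: interaction between non-DE entities
    if (n_de_mirnas < n_mirnas && n_de_genes < n_genes)
      ix$non_de <- data.frame(mirna = mirnas[n_mirnas],
                              gene = genes[n_genes],
                              confidence = "highly_predicted",
                              stringsAsFactors = FALSE)
    interactions <- do.call(rbind, ix)
    if (is.null(interactions))
      interactions <- data.frame(mirna = character(), gene = character(),
                                 confidence = character(),
                                 stringsAsFactors = FALSE)
    if (is.null(planted))
      planted <- data.frame(mirna = character(), gene = character(),
                            stringsAsFactors = FALSE)
  })
  rownames(interactions) <- rownames(planted) <- NULL
  list(mrna = mrna, mirna = mirna, interactions = interactions,
       planted_pairs = planted)
}
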