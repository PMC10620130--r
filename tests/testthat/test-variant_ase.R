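variant_row <- function(td = 50, cd = 30, maf = 0.03, alt = 5) {
  data.frame(tumour_depth = td, control_depth = cd, tumour_maf = maf,
             tumour_alt_reads = alt)
}

test_that("somatic filter applies all four thresholds inclusively", {
  expect_equal(nrow(filter_somatic(variant_row())), 1)          # all at boundary
  expect_equal(nrow(filter_somatic(variant_row(td = 49))), 0)
  expect_equal(nrow(filter_somatic(variant_row(cd = 29))), 0)
  expect_equal(nrow(filter_somatic(variant_row(maf = 0.029))), 0)
  expect_equal(nrow(filter_somatic(variant_row(alt = 4))), 0)
})

test_that("somatic filter is idempotent and monotone in each threshold", {
  set.seed(21)
  v <- data.frame(tumour_depth = sample(30:120, 50, TRUE),
                  control_depth = sample(10:60, 50, TRUE),
                  tumour_maf = runif(50, 0, 0.2),
                  tumour_alt_reads = sample(0:20, 50, TRUE))
  kept <- filter_somatic(v)
  expect_equal(filter_somatic(kept), kept)
  stricter <- filter_somatic(v, tumour_depth_min = 80, maf_min = 0.1)
  expect_true(all(rownames(stricter) %in% rownames(kept)))
})

test_that("TMB is mutations per Mb with a strict low cutoff", {
  expect_equal(compute_tmb(100, 50), list(tmb = 2, low_tmb = TRUE))
  expect_equal(compute_tmb(250, 50), list(tmb = 5, low_tmb = FALSE))
  expect_equal(compute_tmb(0, 50)$tmb, 0)
  expect_true(compute_tmb(0, 50)$low_tmb)
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("ASE classification follows the TPM/VAF rule sentences exactly", {
  obs <- function(tpm, ref, alt)
    data.frame(gene_tpm = tpm, rna_ref_count = ref, rna_alt_count = alt)
  # TPM below 2: gene not expressed regardless of RNA counts
  expect_equal(classify_ase(obs(1.9, 10, 90)), "GENE_NOT_EXPRESSED")
  # expressed gene, clear mutant-allele signal
  expect_equal(classify_ase(obs(10, 75, 25)), "MUTATED_EXPRESSED")
  # VAF exactly 3%: the expressed rule is strict, so not expressed
  expect_equal(classify_ase(obs(10, 97, 3)), "MUTATED_NOT_EXPRESSED")
  # TPM exactly 2: the expression rule is inclusive
  expect_equal(classify_ase(obs(2, 75, 25)), "MUTATED_EXPRESSED")
  # no RNA coverage
  expect_equal(classify_ase(obs(10, 0, 0)), "NOT_COVERED")
})

test_that("classifier is total, deterministic and order-invariant", {
  tab <- simulate_ase_table(c(MUTATED_EXPRESSED = 50, MUTATED_NOT_EXPRESSED = 50,
                              GENE_NOT_EXPRESSED = 50, NOT_COVERED = 20),
                            seed = 31)
  cls <- classify_ase(tab)
  expect_true(all(cls %in% ase_classes()))
  perm <- sample(nrow(tab))
  expect_equal(classify_ase(tab[perm, ]), cls[perm])
})

test_that("confusion matrix on noise-free synthetic observations is diagonal", {
  tab <- simulate_ase_table(c(MUTATED_EXPRESSED = 300, MUTATED_NOT_EXPRESSED = 300,
                              GENE_NOT_EXPRESSED = 300, NOT_COVERED = 100),
                            seed = 17)
  expect_equal(classify_ase(tab), tab$true_class)
})

test_that("per-sample proportions exclude NOT_COVERED and sum to one", {
  tab <- data.frame(sample_id = "S1",
                    gene_tpm = c(10, 10, 1, 5),
                    rna_ref_count = c(50, 99, 40, 0),
                    rna_alt_count = c(50, 1, 10, 0))
  s <- ase_sample_summary(tab)
  expect_equal(s$n_classified, 3)
  expect_equal(s$n_not_covered, 1)
  props <- unlist(s[grep("^prop_", names(s))])
  expect_equal(unname(props), c(1, 1, 1) / 3)
  expect_equal(sum(props), 1, tolerance = 1e-12)

  # proportions are invariant to duplicating the observation list
  s2 <- ase_sample_summary(rbind(tab, tab))
  expect_equal(unlist(s2[grep("^prop_", names(s2))]), props)

  # an all-NOT_COVERED sample has no denominator
  nc <- data.frame(sample_id = "S2", gene_tpm = 5,
                   rna_ref_count = 0, rna_alt_count = 0)
  expect_error(ase_sample_summary(nc), "S2")
})

test_that("planted class fractions are recovered to 1/n at n = 1000", {
  n <- c(MUTATED_EXPRESSED = 310, MUTATED_NOT_EXPRESSED = 320,
         GENE_NOT_EXPRESSED = 370)
  tab <- simulate_ase_table(n, seed = 23)
  s <- ase_sample_summary(tab)
  expect_equal(s$prop_mutated_expressed, 0.31, tolerance = 1e-3)
  expect_equal(s$prop_mutated_not_expressed, 0.32, tolerance = 1e-3)
  expect_equal(s$prop_gene_not_expressed, 0.37, tolerance = 1e-3)
  pooled <- ase_pooled_summary(tab)
  expect_equal(pooled$prop_gene_not_expressed, 0.37, tolerance = 1e-3)
})
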