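---
title: "Chromosome-level CIN scoring, chromothripsis calling and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-level CIN scoring, chromothripsis calling and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistcin)
```

## The problem

High-risk gastrointestinal stromal tumours (GIST) with similar clinical
risk profiles behave very differently: some metastasise, others never
relapse. A genomic feature that tracks this divergence is the extent of
chromosomal instability (CIN). `gistcin` implements a chromosome-counting
CIN score on allele-specific copy-number segment profiles, a windowed
chromothripsis caller, a rule-based classifier for the allele-specific
expression (ASE) of somatic mutations, threshold-based expression filters
with miRNA–mRNA anti-correlation pairing, and exact small-sample group
statistics. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Input model

The substrate of all copy-number computation is the allele-specific
segmented profile, as emitted by FACETS-style segmentation: per sample, a
set of genomic intervals each carrying a total copy number, a minor-allele
copy number, and optionally a log-ratio. Internally all intervals are
0-based half-open, which makes lengths `end - start` and adjacency tests
unambiguous; on disk the default dialect is 1-based inclusive (SEG
convention) with a `bed` flag for files already half-open. Chromosome names
are normalised by stripping a `chr` prefix and mapping `23` to `X`, since
segmentation tools commonly emit numeric codes. Segments need not tile a
chromosome: segmentation output has gaps (centromeres, low-coverage
regions), and gaps carry no copy-number state. The bundled genome model is
b37 (autosomes 1–22 plus X); interval arithmetic for a cohort must use one
consistent build, and b37 is the assembly against which the segment
profiles this package consumes are normally produced, even when companion
RNA data were aligned to a newer assembly upstream.

## The affected-chromosome CIN score

Per chromosome, two flags are computed over its segments:

* **CNV-affected** — some segment of length ≥ `min_aberrant_len_bp` has
  total copy number different from the baseline;
* **cnLOH-affected** — some such segment has total copy number equal to the
  baseline and minor-allele copy number 0 (copy-neutral loss of
  heterozygosity).

The per-sample summary partitions affected chromosomes into CNV-only,
cnLOH-only and both-affected counts; the total is their sum, and a sample
with `complexity_threshold` (default 10) or more affected chromosomes is
labelled **Complex**, with nine or fewer **Simple**. The threshold
comparison is `>=` on integers, so no rounding question arises.

Parameter choices that were genuinely open:

* **Baseline copy number** defaults to 2 (diploid) rather than the sample's
  ploidy. The reference cohort includes near-tetraploid samples (ploidy
  3.27, 3.47) whose affected-chromosome counts are high (17–18 CNV
  chromosomes), which is consistent with a diploid reference — against
  rounded ploidy those genomes would look largely unremarkable. A
  `nearest_integer_ploidy` mode is available for users who want
  ploidy-relative calls.
* **`min_aberrant_len_bp`** defaults to 0: any segment counts. No length
  filter is part of the score's definition; the knob exists for robustness
  against segmentation noise.
* **Chromosome X** counts for CNV in all samples, but is excluded from
  cnLOH counting when the sample is male: a hemizygous X has minor copy
  number 0 at total 1–2 without any loss event, so counting it as LOH would
  be a systematic false positive. `count_x_for_cnloh` overrides this.
* The CNV-only and cnLOH-only counts are disjoint by construction — a
  chromosome with both kinds of event is counted once, in the both-affected
  category. This is the only reading under which the reference cohort's
  per-sample counts are additive.

### Comparator metrics

Four segment-level CIN scores are computed alongside, for ranking samples
on alternative definitions: the number of segments with |log-ratio| above
`log_ratio_threshold` (default 0.2), the number of breakpoints (adjacent
same-chromosome segment pairs with different total copy number), the
fraction of the genome altered (FGA: aberrant segment length over total
build length, hence always in [0, 1]), and the total aberration index
(TAI: length-weighted mean |log-ratio| over all segments; a masked variant
restricted to threshold-passing segments is available behind `tai_masked`,
since both conventions circulate). When the input lacks a log-ratio column
it is derived as `log2(max(total_cn, 0.5) / 2)`; the 0.5 floor keeps
homozygous deletions finite.

## Chromothripsis calling

Chromothripsis leaves a signature of many oscillating copy-number states
clustered on one chromosome. The caller counts switches — adjacent segments
(in sorted order, including across gaps; segmentation output is gapped and
no maximum-gap rule is imposed) whose states differ — and maximises the
switch count over sliding windows of `window_bp` (default 50 Mb). A
chromosome with `switch_threshold` (default 10) or more switches within
some window is positive with high confidence. The default state is total
copy number; an `allele_specific` mode also counts transitions in the minor
allele (e.g. into cnLOH) as switches.

Numerical choices: the switch coordinate is the left segment's end (any
consistent convention yields identical window counts); windows are
half-open `[x, x + w)`; and the window maximum is computed exactly by
anchoring a window at each switch position — the count as a function of the
anchor only increases when the anchor lands on a position, so this scan is
equivalent to scanning every basepair. Chromosomes with zero switches are
omitted from the output by default (`include_all = FALSE` restores them),
matching how such tables are reported: sub-threshold chromosomes of a
positive sample may still be listed, with the high-confidence flag applied
strictly at the threshold.

## Somatic-variant filtering, TMB and ASE classification

Somatic variants are kept when all four evidence thresholds hold, each
inclusive: tumour coverage ≥ 50×, control coverage ≥ 30×, tumour mutant
allele frequency ≥ 0.03, and ≥ 5 supporting reads. TMB is mutations per Mb
of coding target — the target size is a required argument, not a hidden
constant — and is "low" strictly below 5/Mb.

Each mutation joined to RNA evidence (gene TPM, RNA reference/alternate
allele counts) is assigned exactly one class, evaluated in this order:

1. `NOT_COVERED` when no RNA reads overlap the locus. This is an explicit
   class rather than a silently dropped row, so the count is auditable;
   summaries exclude it from denominators.
2. `GENE_NOT_EXPRESSED` when TPM < 2.
3. `MUTATED_EXPRESSED` when TPM ≥ 2 and RNA VAF > 0.03.
4. `MUTATED_NOT_EXPRESSED` when TPM ≥ 2 and VAF ≤ 0.03.

The asymmetry is deliberate and kept exactly as the rule is stated: the TPM
comparison is inclusive at 2 for "expressed", the VAF comparison strict at
3%. "3%" is interpreted as an RNA-derived VAF of 0.03 on the same scale as
the DNA MAF. INDEL RNA counts obtained by manual curation enter through the
same observation type; no realignment is attempted. Per-sample summaries
report the three covered-class proportions (summing to 1); a pooled cohort
summary is provided separately, since averaging per-sample proportions and
pooling variants answer subtly different questions.

## Expression filtering and miRNA–mRNA pairing

mRNA background: a gene is removed only when its median TPM is below 2 in
*both* groups — expression above background in either group keeps it. DE
selection for mRNA is strict (adjusted p < 0.05 and |log2FC| > 1) while the
miRNA rule is inclusive (q ≤ 0.05 and |log2FC| ≥ 1); the two rules are kept
verbatim rather than harmonised, with an `inclusive` switch on the mRNA
selector for users who prefer symmetry.

The miRNA background sentence ("median read counts before and after
normalisation less than 45 in both groups") is ambiguous about how the four
medians combine. The adopted default removes a miRNA only when **all four**
medians (raw and normalised, in each group) are below 45 — the most
conservative removal rule; `raw_only` and `normalised_only` readings are
selectable.

Pairing emits (miRNA, gene) exactly when the pair appears in the
interaction table at an allowed confidence level (default: experimentally
observed and highly predicted), both members are differentially expressed,
and their fold changes have strictly opposite signs — a zero fold change
pairs with nothing. The fold-change sign convention throughout is
metastatic over non-metastatic. DE statistics are consumed, never computed:
the negative-binomial model fits that produce them are upstream of this
package, and no multiple-testing correction is applied internally (the
tables arrive adjusted; correcting again would be wrong).

## Exact group statistics

Cohorts of this size (10 vs 11) sit where the normal approximation to the
Mann–Whitney null is unreliable and ties in integer-valued scores are
common. `mann_whitney_exact()` computes U with midranks and an exact
two-sided p-value under the permutation null: the distribution of the rank
sum over all `choose(n, n_a)` group assignments is built by a subset-sum
recursion over doubled midranks (doubling makes midranks integers, so the
distribution is exact with ties), and the two-sided p doubles the smaller
tail, capped at 1. Above a pooled size of 25 the implementation falls back
to the tie-corrected normal approximation with continuity correction.
Doubling the smaller tail is one of several defensible two-sided
conventions; published p-values from unspecified implementations are
therefore best compared as bounds rather than equalities. Group medians use
the mean-of-central-order-statistics convention for even n.

## The synthetic-data generator

The generator exists because raw segment profiles, variant tables and
count matrices for such cohorts are typically not public. It plants ground
truth *constructively* — values satisfying each class's defining
inequalities with a margin away from the thresholds — rather than sampling
from fitted distributions, because no distributional parameters for the
real data are available to fit. Concretely:

* `simulate_profile()` assigns chromosomes disjoint roles: a CNV-only
  chromosome receives one non-diploid segment flanked by heterozygous
  diploid ones; a cnLOH-only chromosome one copy-neutral LOH segment; a
  both chromosome one of each; a chromothriptic chromosome an alternating
  2↔3 run whose `n_switches` breakpoints are evenly spaced within
  `span_bp`; all other chromosomes are heterozygous diploid throughout.
  Breakpoint placement within a chromosome is randomised under the given
  seed; all outputs are deterministic given (spec, seed). A chromothriptic
  chromosome is by construction also CNV-affected, and the generator's
  ground-truth CIN counts include it in the CNV-only tally.
* Note on planted oscillations wider than the calling window: a chromosome
  with many switches spread over, say, 120 Mb can still contain ≥ 10
  switches within some 50 Mb window — by the calling rule it *is* positive
  (for evenly spaced breakpoints this happens from roughly 21 switches
  up, and for 28 or more switches in 120 Mb it is unavoidable for any
  placement, since three 50 Mb windows partition the span). Ground truth
  for such chromosomes is therefore defined by the planted breakpoint
  geometry, not by the span alone.
* `simulate_ase_table()` draws TPM and allele counts inside each class's
  region with margins (e.g. expressed: TPM in [5, 100], VAF in
  [0.10, 0.60]); a `boundary_cases` flag appends observations sitting
  exactly on TPM = 2 and VAF = 0.03 with their documented expected classes.
* `simulate_de_tables()` plants opposite-sign interacting miRNA–mRNA pairs
  plus three kinds of decoy: a same-sign interacting DE pair, an
  opposite-sign interacting DE pair at a disallowed confidence level, and
  interactions between non-DE entities.
* The bundled reference cohort (21 gastric high-risk GISTs: per-sample
  affected-chromosome counts, Simple/Complex labels, ploidy, mitotic
  counts, and the per-chromosome 50 Mb switch counts of the five
  chromothripsis-positive samples) ships as plain TSVs;
  `gist_cohort_specs()` turns the count columns into profile specs so the
  whole scoring stage can be exercised end to end.

What the generator does **not** emulate: realistic segment-length and
log-ratio noise distributions, subclonal (non-integer) copy-number states,
purity/ploidy estimation error, gapped or missing chromosomes, and
correlated aberrations across chromosomes. Passing tests on synthetic data
therefore demonstrate that the rules are implemented exactly as specified
and are recovered under clean conditions — not that the scores are robust
to segmentation artefacts in real data; the `min_aberrant_len_bp` and
log-ratio thresholds are the knobs a user would turn for that.

## Problem sizes used in the test suite

The property suites run on deliberately small instances chosen to make
their oracles exhaustive and exact: CIN summaries are cross-checked against
a brute-force per-segment scan on 200 random profiles of up to 5
chromosomes and 10 segments each; the windowed switch maximisation against
an every-integer-anchor scan on 200 random instances with coordinates up to
~800; the exact Mann–Whitney p against full enumeration of all group
assignments for pooled sizes up to 12 (enumeration grows combinatorially;
the package's recursion handles the cohort sizes directly); the planted
chromothripsis grid covers 0–30 switches at spans of 10, 50 and 120 Mb; and
the ASE confusion matrix uses 1000 covered observations. These sizes are
the package's own testing choices and exercise every boundary the rules
define.

## Known limitations

* The affected-chromosome score treats a chromosome as one unit: a single
  small aberrant segment and a whole-arm event contribute equally.
* The chromothripsis caller implements only the oscillating-switch-count
  criterion; structural-variant-based criteria (breakpoint clustering,
  fragment joins, heterozygosity retention) are out of scope, so
  "high confidence" here is a copy-number-pattern statement.
* FGA/TAI depend on the provided or derived log-ratio; when derived from
  integer copy number they ignore purity dilution.
* The ASE classifier consumes pre-computed allele counts; reference-mapping
  bias in RNA is not modelled or corrected.
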