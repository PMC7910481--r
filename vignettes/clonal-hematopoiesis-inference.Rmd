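---
title: "Inferring clonal hematopoiesis from duplex and single-cell DNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal hematopoiesis from duplex and single-cell DNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

## The problem

Patients with inherited bone-marrow-failure syndromes such as
Shwachman-Diamond syndrome acquire multiple independent somatic blood-cell
clones early in life, most at very low abundance (median bulk variant allele
fraction around 0.5%). Distinguishing a benign, compensatory clone from a
pre-leukemic one requires (i) calling variants reliably down to 0.1% VAF in
bulk samples, (ii) resolving which mutations co-occur in the same cells,
(iii) detecting loss-of-heterozygosity progression of TP53-mutated clones,
and (iv) relating clonal genotypes to clinical status at cohort level.
`clonotrace` implements that computational chain from count-level inputs:
duplex-consensus read counts, single-cell depth/alt matrices, and exome-style
target and SNP counts. Raw-read processing (alignment, consensus building,
barcode handling) is out of scope; the pipeline starts where count tables
exist.

Because the motivating patient-level data are restricted-access, the package
ships a synthetic-data generator that reproduces the statistical structure of
each input with known ground truth. All tests and the acceptance script run
against it.

## Bulk duplex calling

A duplex-consensus molecule is counted only when both strand families ("ab"
and "ba") are present and each family has at most 5% N bases
(`collapse_families()`). Candidate variants then pass a fixed-order filter
chain (`filter_variants()`): on-target, at least 3 duplex alternate reads,
VAF at least 0.1%, no strand bias, no regional call clustering, not
synonymous, not a recurrent low-VAF homopolymer-adjacent indel, and absent
from the matched fibroblast comparator. The first failing rule is recorded
per call; sites without comparator coverage are `unclassified`, never
silently passed.

Three of these rules are only qualitative in the motivating study and are
operationalized here with exposed defaults (`filter_config()`):

* strand bias: two-sided binomial test of the alternate fwd/rev split against
  the site's depth split, fail at p < 1e-3;
* regional density: more than 3 surviving candidates within 50 bp fail
  together;
* homopolymer indels: indel with VAF < 1% flagged homopolymer-adjacent;
* germline subtraction: comparator alternate fraction >= 20%.

At duplex depth 20,000 the design floor works out as follows: a true 0.2%
variant yields ~40 alternate reads and passes with probability > 0.999, while
an error-only site at substitution rate 1e-4 yields ~2 and essentially never
clears both the 3-read and the 0.1% VAF rule.

## Single-cell genotyping and allelic dropout

Per-cell genotypes follow the panel criteria: depth >= 10 (else missing),
variant present iff alternate count >= 3 and alternate fraction >= 30%,
homozygous at fraction >= 90% (the hom boundary is a package default; the
assay reads heterozygotes near 0.5 and homozygotes near 1).

Allelic dropout (ADO) is quantified at informative germline heterozygous
SNPs as the ratio of homozygous-appearing (reference or variant) to
heterozygous-appearing cells (`estimate_ado()`), with a bootstrap over cells
for the confidence interval. Under independent per-allele dropout at rate
`d`, the expected ratio is `2d/(1-d)`; at the generator default `d = 0.05`
this is 0.105, matching the ~10% sample-level ADO typical of this assay
class. Doublet barcodes deflate the observed ratio slightly (a doublet at a
het SNP virtually always reads heterozygous); `ado_ratio_to_rate()` inverts
the ratio with the known doublet rate to recover `d` without bias.

Technical dropout (`technical_dropout()`) is the fraction of targeted
mutations — those passing the bulk filter and lying in designable
amplicons — genotyped in at least one cell; in simulation, as in practice,
failures concentrate in the lowest-VAF clones.

## Clone identification

Cells with complete genotypes at all somatic loci are grouped by exact
genotype vector; groups below 10 cells or 0.1% frequency are discarded
(clones at 0.1% abundance must remain detectable, which sets the floor).
Two artifact models are then applied, both algorithmic and deterministic
where the original analysis relied on manual review:

**Dropout spillover.** A true-het cell appears homozygous (or wild type) at
one locus when one allele drops out, so every clone sheds satellite groups
one zygosity-step away. A group differing from a larger group only by
het-to-wt or het-to-hom at one locus is tested by a one-sided binomial test
(level 0.01) of its size against the spillover expected at that site's
dropout rate (per-cell appearance probability `d(1-d) + d^2`); if not
rejected it is merged. Every plausible source is tried, largest first.

**Doublet images.** A barcode holding two cells reads mixed allele
fractions — most importantly a homozygous cell plus a wild-type cell reads
~0.5 and is called heterozygous. For each retained group we compute the
expected number of doublets whose mixture would be *called* exactly that
genotype vector (marginalizing the negative-binomial depth model over the
genotyping criteria) and flag groups consistent with that count plus
spillover as `putative_doublet`, keeping them in the output.

Parents are assigned by parsimony: the compatible ancestor with the largest
contained mutation set, then the fewest het-to-hom transitions, then the
larger clone (ties flagged `ambiguous_parent`). The result is a forest —
independent founding clones are the rule in this setting, not the exception.
A homozygous clone whose het parent exists is flagged `loh_subclone` when
its size rejects the same spillover null; this is the single-cell signature
of copy-neutral LOH progression, visible years before clinical
transformation in the motivating study.

Exact-recovery behaviour: at 10,000 cells, per-allele dropout 0.05, 2%
doublets and 3-6 clones with fractions >= 0.5%, the full truth hierarchy is
recovered exactly in >= 95% of seeded replicates. The residual failures are
almost entirely the spillover test's own 1% false-retention rate operating
2-4 times per replicate; they are inherent to the declared test level, not
to sample size.

## Copy number, phasing and cancer cell fraction

Total copy ratio per target is the sample's count fraction over the
panel-of-normals median fraction, median-re-centered (assumes a
majority-diploid profile); targets that are unstable within the panel
(mean ratio outside [0.25, 4] or CV > 0.3) are blacklisted. Segmentation is
recursive binary splitting on log2 tCR with a permutation stop (level 0.01,
100 permutations, minimum 5 targets per side) — an adaptation of circular
binary segmentation; in joint mode the split statistic is summed across a
patient's samples so shared breakpoints are favored and applied to all
samples.

Within each segment the allelic imbalance parameter (major-haplotype allele
fraction rho) is fitted by maximum likelihood under a mirrored binomial
model and tested against 0.5 by likelihood ratio (level 0.01). A two-state
hidden Markov model over ordered SNPs — state = which haplotype carries the
alternate allele, binomial emissions at rho, switch probability 0.005 —
is decoded by Viterbi to phase the SNPs. Classification combines imbalance
with mean log2 tCR: significant imbalance below -0.15 is a deletion, within
±0.15 copy-neutral LOH, above +0.15 a gain; balanced otherwise; fewer than
5 SNPs is indeterminate. Note that CN-LOH is by construction invisible to
the tCR track alone — the breakpoint information is carried entirely by the
SNP allele fractions — so chromosome-scale events (as at 17p in the
motivating setting) are the intended use.

The cancer cell fraction of a mutation with multiplicity `m` on local total
copy number `q` at sample purity `p` has expected alternate fraction
`f(c) = p*m*c / (p*q + 2*(1-p))`; `compute_ccf()` evaluates the binomial
likelihood on a 101-point grid with uniform prior and reports mode and 95%
central interval. Purity and multiplicity are inputs (truth in simulation;
user-supplied otherwise): the joint purity/ploidy inference of tools in the
ABSOLUTE family is deliberately out of scope, and this grid posterior is the
declared simplification.

## Cohort statistics

`fisher_exact_two_sided()` uses the probability-mass convention (sum of
hypergeometric probabilities not exceeding the observed table's, relative
tie tolerance 1e-7) with the tail-doubling p reported alongside; on the
published TP53-by-myeloid-neoplasm table (11/15 vs 33/83) it gives
p = 0.023. Prevalence by age, per-gene mutation burden, and the biallelic
TP53 mechanism classification (mutation+CN_LOH, mutation+deletion,
two_mutations when both CCF intervals cover 1, else monoallelic) complete
the cohort layer.

## The synthetic-data generator

`simulate_cells()`, `simulate_bulk_duplex()` and `simulate_exome_counts()`
emulate, respectively, the single-cell panel, serial duplex bulk sequencing,
and exome-style copy-number inputs. Design choices worth knowing:

* Dropout acts per allele, independently per cell and locus; loss of both
  alleles silences the locus (missing genotype), it does not fake a
  homozygote.
* Depth follows the amplicon read budget: amplification saturates, so a cell
  that lost one allele still reads at full depth from the surviving allele.
  Doublets are unions of two cells' allele sets with a doubled budget.
* Per-locus depth is negative-binomial (mean 120, size 25; cv about 0.2) —
  the per-cell depth distribution of such panels is not published, so this
  is an exposed assumption. The mean is set deep enough that the genotyping
  criteria essentially never misread a true heterozygote (at 120x the
  probability of a het cell reading below the 30% presence threshold is
  under 1e-4), which the generator's convergence to the 2d/(1-d) dropout
  ratio requires.
* Exome template counts are negative-binomial around a per-target capture
  efficiency shared with the emitted panel of normals (size 200, reflecting
  near-Poisson deduplicated counts); SNP allele counts follow the stated
  purity mixture with the truth haplotype recorded.
* Defaults mirror the study scale: 10,000 cells, per-allele dropout 0.05,
  2% doublets, duplex depth 20,000, background substitution rate 1e-4.

What the generator does **not** emulate: amplicon-specific biases that
correlate across cells, barcode collision structure beyond simple two-cell
doublets, mapping artifacts, GC waves in coverage, and germline SNP linkage
beyond segment-level haplotypes. Passing tests therefore demonstrate
correctness of the inference logic under the declared generative model, not
robustness to every artifact of real data.

## Numerical choices and problem sizes

Deterministic seeds flow from a single config value through a
state-preserving RNG scope, so fixed seeds give byte-identical outputs.
Grid resolutions: CCF grid 101 points; imbalance grid 0.5-0.995 step 0.005.
The test suite runs its heaviest check — 100 seeded replicates of full
single-cell inference at 10,000 cells — in about two minutes; the
acceptance script uses 40 replicates for the same quantity and finishes in
about three. Segmentation uses 100 permutations per split, which bounds the
attainable stop p-value at ~0.0099, just inside the 0.01 level.

## Known limitations

* Somatic-site dropout rates are taken from the sample-level SNP estimate;
  site-specific rates at somatic loci are not separately identifiable
  without clone truth.
* A true clone whose size matches its neighbour's dropout spillover is
  indistinguishable from that spillover by construction; the binomial test
  resolves this exactly as often as its level allows.
* The two-state phasing HMM ignores population haplotype panels; phase is
  resolved only up to a within-segment label swap.
* Multi-sample segmentation assumes shared target coordinates across
  samples of a patient.
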