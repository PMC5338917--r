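---
title: "Prioritizing regulatory SNPs in tissue-specific enhancers: methods and design"
author: "regSNPscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing regulatory SNPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regSNPscan)
```

## The problem and the model

Genome-wide association studies place most disease-associated variants in
non-coding sequence. The working model behind this package is mechanistic:
a functional non-coding SNP sits inside a cell-type-specific regulatory
element, its two alleles differ in how well a master transcription factor
(TF) binds its recognition motif, and the resulting difference in TF
occupancy shifts the expression of a nearby target gene, which may in turn
carry prognostic information. The pipeline operationalizes each link in
that chain as a testable filter or annotation:

* **regulatory element** — interval evidence: the SNP lies in a region
  that is open or enhancer-marked *and* bound by at least one master TF;
* **allelic binding difference** — allele-specific position-weight-matrix
  (PWM) scoring around the SNP;
* **expression shift** — a cis-eQTL one-way ANOVA of expression across
  genotype groups;
* **prognosis** — tumor-versus-normal differential expression and a
  Kaplan–Meier / log-rank analysis of recurrence-free survival after
  z-score stratification.

A *candidate* is the conjunction of the first three pieces of evidence;
the prognostic analyses annotate candidates rather than filter them, since
a regulatory variant can be real without its target being prognostic.

## Interval algebra

Peaks and regions follow BED conventions on disk (0-based half-open) and
live as 1-based closed `GRanges` in memory; `rtracklayer` performs the
conversion, and SNP manifests store 1-based positions, so a SNP at position
$p$ overlaps BED interval $[s, e)$ iff $s < p \le e$ in the in-memory
coordinates. Three choices deserve an explicit statement:

* **Abutting intervals merge.** The regulatory-region set is meant to be a
  non-redundant collection of maximal covered runs, so intervals that touch
  end-to-start become one region.
* **Support counts are per region, not per base.** After merging, a TF
  "supports" a region if any of its peaks overlaps it by at least 1 bp;
  `support_count` is the number of distinct TF sets doing so. The inclusion
  criterion is "bound by one or more TFs", which is a property of the
  region.
* **Chromosome names match exactly.** Mixing `chr1` with `1` across inputs
  silently empties every overlap, so `checkChromNaming()` turns mixed
  naming into an error instead of normalizing it away.

The open/active evidence layer is built as the *union* of the
open-chromatin and histone-mark peak sets before intersecting with the TF
union. The alternative — requiring both marks — is stricter; the union
reading matches the disjunctive phrasing of "open chromatin *or* active
enhancer" and is the implemented default. TF peaks are then intersected
with this active set, so the final regions are TF-bound base pairs lying in
open or enhancer-marked chromatin.

All three operations (merge, union with support, intersection) are checked
in the test suite against per-base brute-force oracles that mark every
covered base and reconstruct maximal runs, on random instances of ~1,000
intervals.

## cis-eQTL scan

For each SNP, genes whose transcription start site (TSS) lies within a
±25 kb window of the SNP position (boundary inclusive) are tested. The
window half-width is exposed as `window`; 25 kb is the default because
larger cis windows dilute true regulatory pairs with false positives while
most enhancer–promoter interactions are short-range.

Samples are grouped by observed genotype class (0/1/2 copies of allele B).
The grouping questions the data cannot answer are settled as follows:

* **Three groups when available.** Heterozygous and minor-homozygous
  classes are *not* pooled; the ANOVA generalizes over 2 or 3 groups
  naturally.
* **`minGroupSize = 3`.** Genotype classes with fewer than 3 samples are
  dropped before testing — a variance estimate from 1–2 samples makes F
  unstable. If fewer than 2 classes remain, the pair is flagged untestable
  rather than erroring.
* **Missing genotypes are excluded pairwise**, maximizing usable samples
  per SNP.
* **Significance is BH FDR ≤ 0.05 across all tested pairs** by default,
  with a raw-p override (`pCutoff`). An FDR rule is reproducible and
  scales sensibly with the number of pairs actually tested.
* Expression values are used as provided (they are assumed already
  normalized); a `log2Transform` flag exists but defaults to off.

The ANOVA itself is the classical one-way decomposition; the degenerate
case of zero within-group variance with unequal means is reported
explicitly as F = ∞, p = 0 rather than left to floating-point noise. The
test suite checks the implementation against an independent sums-of-squares
computation to 1e-10 relative error, verifies the nominal type-I error on
2,000 null simulations, and confirms ≥ 90% recovery of a planted additive
effect (β = 1 SD, MAF 0.3, n = 200) at FDR 0.05 over 100 replicates.

## Allele-specific motif scoring

Motif models are HOMER-style: per-position base probabilities plus a
log-odds detection threshold. A window of length $L$ scores
$\sum_i \log_2(\max(p_i[b_i], \varepsilon)/q[b_i])$ against the uniform
background $q = 0.25$. Numerical choices:

* **Log base 2** throughout, so scores and thresholds are in bits.
* **Probability floor $\varepsilon = 10^{-3}$** keeps scores finite when a
  matrix contains zeros; it is applied inside the log, never to the stored
  matrix.
* **`N` bases score as the worst case** (the minimum log-odds at that
  position), so ambiguous sequence can never fabricate a motif gain.
* **Reverse strand** is handled by scoring the reverse complement of the
  window with the unmodified PWM — the standard convention, stated to
  remove ambiguity.

For a SNP with flanking context ±20 bp (matching the motif-analysis window;
`flank` is configurable but must be at least $L - 1$), every placement of
the PWM covering the SNP is scored on both strands under each allele, and
the per-allele maxima are compared (ties broken by smallest offset, then
forward strand):

* `disrupt` — allele A reaches the detection threshold, allele B does not;
* `create` — the reverse;
* `none` — neither allele reaches threshold;
* both reach threshold — `neutral` unless the absolute score difference
  exceeds `deltaMin` (default **2 bits**, about the cost of a strong
  single-base mismatch), in which case the higher-scoring side labels the
  direction.

The exact rule by which threshold crossing and score differences combine is
not uniquely determined by the verbal description "disrupting a subsequence
with a good score or creating one with a better score"; the rule above is
the documented reading, and both the threshold and `deltaMin` are exposed.
The scorer is validated against an exhaustive (offset × strand) enumeration
oracle, a reverse-complement symmetry property, a monotonicity property,
and a planted-disruption experiment requiring ≥ 95% sensitivity over 200
constructions.

## Differential expression and recurrence risk

The DE call is deliberately simple, matching a threshold rule rather than a
count model: fold change is the ratio of class means on the linear scale
with offset 1 guarding zero means, and p comes from Welch's t-test on
log2(x+1) (Wilcoxon available via `test = "wilcoxon"`). A gene is called DE
when |log2 FC| > log2(1.5) and p < 0.01. Whether the original rule used
means or medians, linear or log space, is not recoverable; means on the
linear scale with the documented offset is the package's choice.

For recurrence risk, tumor expression is z-scored against the normal
reference, $z = (x - \mu)/\sigma$, with $\sigma$ the **sample (n−1)**
standard deviation of normals (stated to fix a silent convention); genes
with $\sigma = 0$ are excluded with a warning. Stratification keeps the
floor(0.75·n) most extreme tumors of each z-sign (minimum 1; z = 0 is
neither sign), excluding the tumors nearest zero as uninformative; `floor`
is the documented rounding rule and ties break by stable sample id, making
the assignment permutation-invariant. The strata are compared with the
standard two-group 1-df log-rank test (the universal default for
Kaplan–Meier group comparison), with tied event times handled by the
aggregated risk-set formulation; a comparison with no events at all is
flagged untestable. The reported `direction` is the sign of the high
group's observed-minus-expected event count; the package does not take a
position on which direction constitutes "risk" for any particular gene, it
reports the statistic and the sign.

The KM estimator and log-rank test are validated against a hand
product-limit example, a risk-set counting oracle, a power requirement
(hazard ratio 3, n = 75/group, 30% censoring: rejection in ≥ 90% of 100
replicates) and a calibration requirement (null hazard ratio: 5% ± 3%
rejections over 500 replicates).

## The synthetic study

`simulateRegSnpData()` generates every input the pipeline reads, with
planted ground truth. Its defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_tumor`, `n_normal` | 200, 52 | sample counts (genotyped tumors; normal reference) |
| `n_snps`, `n_planted` | 500, 5 | manifest size; planted regulatory SNPs |
| `n_genes` | 300 | annotated genes over two 1 Mb chromosomes |
| `maf_range`, `planted_maf` | 0.1–0.5, 0.3 | Hardy–Weinberg genotype draws |
| `eqtl_beta` | 1.0 | additive effect per allele copy, in units of the expression noise SD |
| `noise_sd` | 0.5 | log2-scale expression noise |
| `motif_info_bits`, `motif_length` | 20, 12 | planted PWM information content and length |
| `hazard_ratio`, `censor_rate` | 3, 0.3 | recurrence hazard of the high-expression tail; random censoring |
| `baseline_hazard`, `followup_cap` | log(2)/60 per month, 150 months | median 60-month time to recurrence; administrative cap |

The generator emulates the *processed* forms of a real cohort: peak BED
files per mark and TF, an array-style SNP manifest, Hardy–Weinberg
genotypes with 2% missingness (never on planted SNPs, so planted effects
keep their nominal n), RSEM-like positive expression values (generated on
the log2 scale and exponentiated), exponential recurrence times, and
HOMER-style motif files. Planted SNPs are constructed to satisfy every
stage at once: a DHS peak, a mark peak and one TF peak are forced over the
locus, the TF's consensus is written into the reference with the SNP at a
core motif position (allele A = consensus base, allele B = the
lowest-probability base), and the planted PWM threshold is set at 85% of
the consensus score so that a single worst-base substitution falls below
it. Decoy SNPs are placed both inside regulatory regions (away from any
planted motif) and, by rejection sampling, outside them.

Two structural decisions matter for interpretation. First, all randomness
flows from one seed through a fixed child-stream schedule (motifs, regions
and SNPs, genes, genotypes, expression, survival), so regenerating one
artifact never perturbs the others and two runs from the same configuration
are byte-identical. Second, the planted recurrence-risk gene is kept free
of the tumor-wide DE shift applied to the planted DE genes: a strongly DE
gene has almost all-positive z-scores versus normals, which leaves no
low-expression stratum to contrast — a real phenomenon the survival
annotation correctly reports as untestable, but one that would make the
planted risk signal unrecoverable by construction.

What the generator does *not* emulate is equally important when reading
test results: there is no linkage disequilibrium between SNPs, no
population structure or tumor-purity covariates, no correlation between
genes, no count-level sampling noise, and motif matches occur only where
planted (random background rarely crosses a 20-bit threshold). Passing the
planted-recovery tests therefore demonstrates that the pipeline's logic and
statistics are correct and calibrated under its own model assumptions — not
that the thresholds would achieve the same sensitivity and specificity on a
real cohort, where confounding and LD dominate the error budget.

## Problem sizes used in validation

The test suite and the acceptance script scale the experiments to desk
size: interval oracles run on 20 random instances of ~1,000 intervals over
two short chromosomes; ANOVA calibration uses 2,000 null simulations at
n = 60 and 100 planted-recovery replicates at n = 200; motif sensitivity
uses 200 planted constructions; log-rank power and calibration use 100 and
500 replicates at n = 75 per group; and the end-to-end run uses the default
500-SNP study. These sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerances (e.g. ±0.005 on a 5% rate at 2,000
replicates) while keeping the whole suite fast.

## Known limitations

* Trans effects, dosage (linear regression) eQTL models, covariate
  adjustment and LD pruning are out of scope; the eQTL scan is a grouped
  ANOVA by design.
* Motif scoring has no p-value calibration and assumes a 0-order uniform
  background; indels are not handled.
* The DE call is a threshold rule on normalized values, not a count model
  with dispersion shrinkage.
* Survival analysis is a two-group log-rank comparison; no Cox modeling,
  multivariable adjustment or competing risks.
* The candidate definition inherits the verbal ambiguities documented
  above (motif call rule, eQTL threshold); both are parameterized so a
  user can tighten or relax them.
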