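---
title: "Profiling fragment-length-dependent R2 error rates in paired-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling fragment-length-dependent R2 error rates in paired-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglenqc)
```

## The phenomenon and the measurement

Illumina paired-end sequencing reads both ends of a DNA fragment: R1 first,
then — after resynthesis on the flow cell — R2. In many public datasets a
subpopulation of R2 reads shows markedly lower base quality than the
corresponding R1 reads, and the size of that subpopulation varies strongly
between libraries sequenced in the same run. The driver is the fragment
(insert) length: fragments longer than about 500 nt yield R2 reads with
elevated substitution error rates, while R1 reads stay clean at all fragment
lengths. `fraglenqc` quantifies this effect from coordinate-level alignments.

Quality is measured from alignments, not from base-caller Phred scores: the
per-read **aligned-base mismatch rate**, i.e. the number of substituted bases
divided by the number of read bases under alignment-match CIGAR operations.
Working with intra-sample contrasts (R2 versus R1 of the same library) cancels
alignment artefacts and genotype differences between a sample and the
reference. A read is called **low quality (LQ)** when its mismatch rate is
strictly above 0.01; the alternative definition (mean Phred strictly below
30) is computed alongside, but all headline metrics use the mismatch
definition. A fragment is **long** when its alignment-derived length,
`|TLEN|`, is strictly greater than 500 nt.

## Filtering contract

Only records that are mapped, primary (neither secondary nor supplementary)
and properly paired enter the analysis; fragment length is only defined for
concordant pairs, and restricting to primary alignments avoids double
counting. Everything else is tallied in a per-class filter log so the
contract is auditable for every run. Pairs with `|TLEN|` outside [1, 1000]
carry no usable length and are excluded from numerator and denominator of
every fraction. Two upstream details are deliberately configurable because
common practice varies:

* **Duplicates** are kept by default (`keep_duplicates = TRUE`); duplicate
  removal before error profiling is a judgement call, and a flag flips it.
* **`N` read bases** are excluded from both the substitution count and the
  aligned-base denominator: a no-call is not a substitution.

## Substitution extraction and cycle coordinates

Substitution positions come from the MD tag walked jointly with the CIGAR
(insertions and soft clips consume read bases but are invisible to MD;
deletions consume reference only). When MD tags are absent a reference FASTA
can be supplied and MD is reconstructed with the same convention `samtools
calmd` uses. Because SAM stores reverse-strand reads reverse-complemented,
read-string positions are mapped to **sequencing cycles**
(`cycle = read_length - 1 - position` on the reverse strand) before any
positional aggregation; error mechanisms live in cycle space, not reference
space. The package carries two independent extraction routes — the MD walk
and a direct read-versus-reference comparison — and the test suite holds them
to exact agreement on thousands of randomized alignments with clips and
indels.

## Stratification and cross-sample testing

Valid pairs are binned into half-open fragment-length strata, by default
`[0,100), …, [900,1000)`. The exact bin width is a presentation choice, so
the edges are configurable. Two closed windows feed the positional profiles:
**short** fragments 200–400 bp and **long** fragments 600–1000 bp, leaving a
buffer around the 500-nt step so window membership is unambiguous. Cells
with fewer than 100 reads and profile cycles with fewer than 1000 aligned
bases are masked as too noisy to interpret; both minima are configurable.

Across samples, the analysis tests whether a library's long-fragment content
predicts its excess of low-quality R2 reads with Spearman rank correlation
(mid-ranks for ties, i.e. Pearson on average ranks). Three fixed comparisons
are run against the fraction of long fragments: the LQ fraction in R1, the
LQ fraction in R2, and their difference R2 − R1. Tests are two-sided; with
n ≤ 8 samples the p-value is the exact permutation probability over all `n!`
reorderings, otherwise the usual `t = rho * sqrt((n-2)/(1-rho^2))`
approximation with `n − 2` degrees of freedom. A perfect correlation is
reported at the permutation floor `2/n!` rather than 0. No multiple-testing
correction is applied across the three rows — they are three views of one
hypothesis, not a family of discoveries.

## The simulator: what it emulates and what it does not

The bundled generator produces multi-sample paired-end alignments with the
statistical structure the analysis assumes, so every stage can be validated
against known truth:

* **Fragment lengths** follow a two-component truncated normal mixture:
  a short mode (mean 300, SD 50) and a long mode (mean 700, SD 100), both
  truncated to [read_length, 1000]. Varying the long-component weight
  `p_long` across samples emulates libraries differing in long-fragment
  content. Draws use vectorized rejection sampling against the truncation.
* **Substitution errors**: R1 error depends on cycle only
  (`eps = 0.002 + 2e-5 * cycle`); R2 error adds a baseline offset
  (`0.003 + 3e-5 * cycle`) plus a fragment-length term — by default a step
  of 0.015 for fragments strictly above 500 nt, with a linear-in-length ramp
  available because stratified summaries of real libraries suggest a graded
  rise from 500–600 bp upward. Baselines sit near the error rates of healthy
  Illumina runs (about 1/500–1/300 per base); the 0.015 step is a package
  choice calibrated only to reproduce the qualitative ordering of the real
  phenomenon, which has no published quantitative effect size.
* **Geometry**: R1 reads the fragment's 5' end, R2 the reverse complement of
  its 3' end; the fragment sits on either reference strand with equal
  probability, so FLAG pairs 99/147 and 83/163 both occur and the
  strand-to-cycle conversion is exercised on both mates.
* **Phred scores** are set truthfully per base as `round(-10*log10(eps))`,
  capped to [2, 41]. A consequence worth knowing: with class-deterministic
  error rates the mean Phred of every read is a step function of mate and
  fragment class (an R1 baseline of 0.002 maps to Q27, below the Q30
  cutoff), so the Phred-based LQ fraction is degenerate on synthetic data.
  Real reads have per-read quality spread; only the mismatch-based
  definition is meaningful for simulator-driven validation, and it is the
  headline definition anyway.
* **Determinism**: a master seed derives one substream seed per sample via a
  fixed linear congruential map (all below 2^31), with Mersenne-Twister
  inside; identical configurations give byte-identical SAM and truth files.

Not emulated: sequence-context and GC effects, adapter read-through,
duplicates, indel sequencing errors (an indel/soft-clip generator exists
separately for parser validation), per-read quality dispersion, and any
mechanistic model of flow-cell chemistry. Passing tests on synthetic data
therefore demonstrate that the pipeline measures what it claims under the
assumed error structure — not that real libraries follow that structure.

## Numerical choices and degenerate inputs

* Per-base substitution probabilities are validated against a ceiling of
  0.75: a uniform draw over the three alternative bases cannot represent a
  probability above it, so an error probability of exactly 1 at a cycle is
  unrepresentable by design and the simulator rejects it.
* A read with zero aligned bases has an undefined mismatch rate; such
  records are dropped and counted, never silently scored 0.
* Empty samples (no valid pairs) and studies with fewer than 3 samples are
  hard errors, not empty outputs.
* MD/CIGAR inconsistencies are record-level parse errors: the record is
  skipped and tallied, the run continues.
* The positional profiles report raw per-cycle rates; a centered rolling
  mean (window 5) exists for display only and never feeds a statistic.

## Per-cycle comparisons need multiplicity control

A recurring validation idiom here compares two positional profiles cycle by
cycle. With a read length of 100 there are ~100 simultaneous comparisons, so
a per-cycle band of ±2 binomial standard errors has joint coverage of about
`0.95^100 ≈ 0.6%` — it will almost always flag a few cycles even when the
profiles are identical in expectation (simulation confirms 2–4 excursions
per run with none beyond 4 SE). The suite therefore checks the scientific
claim — no systematic R1 fragment-length effect — with a global 4-SE band,
whose joint coverage exceeds 99%. A literal per-cycle 2-SE check is retained
alongside it, documented as expected to fail for this statistical reason.

## Validation problem sizes

The shipped suite validates at sizes chosen to make binomial noise small
relative to the effects being recovered: one 5 × 10^4-pair sample at
simulator defaults for error-model recovery and positional profiles (the
long-minus-short R2 rate difference recovers the configured 0.015 step to
within a few tenths of a percent relative error); a 30-sample study at 5000
pairs per sample for the cross-sample correlation structure; twenty 30-sample
null-control studies at 500 pairs per sample (the null false-positive rate
does not depend on pairs per sample); 10^4 randomized alignments for parser
equivalence; and 1000 null replicates at n = 50 for the type-I error of the
Spearman test.

## Known limitations

* `positional_profile` derives per-cycle coverage exactly for fully aligned
  reads and re-walks CIGAR/MD for clipped or gapped records; on real data
  dominated by clipped alignments this is the slow path.
* The Phred-based LQ definition is reported for completeness but is only
  informative when base qualities vary within and between reads.
* Fragment lengths are alignment-derived (`|TLEN|`), so library-preparation
  lengths are observed only through the aligner's insert-size model, and
  pairs the aligner refused to pair concordantly are invisible.
* The simulator's effect-size default is a calibration choice, not an
  estimate of any particular instrument's behaviour.
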