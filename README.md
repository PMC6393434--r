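# fraglenqc

Fragment-length-stratified quality profiling of Illumina paired-end
alignments.

In paired-end sequencing, some libraries show a subpopulation of second
reads (R2) with much higher error rates than their first reads (R1), and
the size of that subpopulation varies widely between libraries — even
between multiplexed libraries of the same run. The driver is DNA fragment
length: fragments longer than ~500 nt produce R2 reads with elevated
substitution rates, while R1 reads stay clean at all lengths. `fraglenqc`
is for sequencing facilities and method developers who want to quantify
this effect in their own data, and for anyone building Illumina error
models that should include fragment length as a factor.

## What it computes

Quality is measured from alignments: for each read, the aligned-base
mismatch rate

```
r = (# substituted bases under M CIGAR ops) / (# aligned bases)
```

extracted from CIGAR + MD tags in sequencing-cycle coordinates
(reverse-strand positions flipped), over reads that are mapped, primary and
properly paired. A read is *low quality* (LQ) when `r > 0.01` (alternative
definition: mean Phred < 30); a fragment is *long* when `|TLEN| > 500`,
with valid inserts restricted to `1 ≤ |TLEN| ≤ 1000`. Per sample, the
package reports the LQ fraction per mate and per fragment-length stratum,
positional (per-cycle) mismatch profiles for short (200–400 bp) and long
(600–1000 bp) fragments, and across samples it tests

```
rho_k = Spearman( fraction of long fragments , y_k ),
y_1 = LQ fraction in R1,  y_2 = LQ fraction in R2,  y_3 = y_2 - y_1
```

two-sided, with exact permutation p-values for n ≤ 8 and the
`t = rho * sqrt((n-2)/(1-rho^2))` approximation otherwise. A seedable
simulator generates multi-sample paired-end SAM data with a
cycle-and-fragment-length-dependent substitution model (R1:
`eps = b1 + s1*c`; R2: `eps = b2 + s2*c + e(L)`, step or ramp in fragment
length `L`) plus a truth table, so the whole pipeline validates against
known error injection.

## Worked example

Simulate six libraries whose long-fragment content rises from 10% to 50%,
profile them from their SAM files, and test the association:

```r
library(fraglenqc)

sims <- simulate_study(p_long = seq(0.1, 0.5, length.out = 6),
                       config = sim_config(n_pairs = 2000), seed = 42)
dir <- tempfile()
for (s in sims) emit_sam(s, dir, write_reference = FALSE)

out <- tempfile()
res <- run_profile(list.files(dir, "\\.sam$", full.names = TRUE), out)
res$summaries
#> # A tibble: 6 × 6
#>   sample_id n_pairs frac_long frac_lq_r1 frac_lq_r2 lq_diff
#>   <chr>       <int>     <dbl>      <dbl>      <dbl>   <dbl>
#> 1 sample01     2000     0.095     0.032       0.126  0.0935
#> 2 sample02     2000     0.184     0.034       0.164  0.130
#> 3 sample03     2000     0.244     0.0355      0.209  0.174
#> 4 sample04     2000     0.335     0.037       0.253  0.216
#> 5 sample05     2000     0.406     0.037       0.281  0.244
#> 6 sample06     2000     0.484     0.0315      0.320  0.288

run_correlate(res$summaries)
#>                comparison       rho     p_value n significant
#> 1 frac_long vs frac_lq_r1 0.1159542 0.844444444 6       FALSE
#> 2 frac_long vs frac_lq_r2 1.0000000 0.002777778 6        TRUE
#> 3    frac_long vs lq_diff 1.0000000 0.002777778 6        TRUE
```

Reading the output: `frac_long` is the fraction of pairs with insert
> 500 nt; `frac_lq_r1` stays flat near 3% while `frac_lq_r2` climbs from
13% to 32% as long fragments accumulate, so the R2 − R1 excess (`lq_diff`)
tracks `frac_long` almost perfectly — significant for R2 and for the
difference, not for R1. `run_profile` also writes `summary.tsv`,
`strata.tsv` (per-stratum LQ fractions), `profiles.tsv` (per-cycle rates)
and a JSON manifest of thresholds and filter counts into `out`.

The same stages are available from the shell:

```sh
Rscript exec/fraglenqc simulate  --out sims --samples 6 --pairs 2000
Rscript exec/fraglenqc profile   --out prof sims/*.sam
Rscript exec/fraglenqc correlate --summary prof/summary.tsv --out prof/correlations.tsv
```

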