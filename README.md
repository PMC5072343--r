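# hornscan

Tools for the genetics of horn status in sheep around the candidate polled
mutation: a 1.78-kb insertion in the 3′-UTR of *RXFP2* on ovine chromosome 10.

Horn status in sheep is sex-influenced: the horned (ancestral, *anc*) allele
behaves as dominant in rams and recessive in ewes, so heterozygous males are
horned while heterozygous females are polled. The insertion (derived, *der*)
allele segregates almost perfectly with polledness in Central and Western
European breeds, but not in breeds with variable or sex-dependent horn
status. `hornscan` implements the computational analyses behind that kind of
study, for geneticists who want to run them on their own panels or on
simulated data:

- **Selection scan** — a case/control windowed F<sub>ST</sub> scan over a
  biallelic site-by-sample dosage matrix. Sites are filtered at MAF > 0.05
  (pooled sample); per site, the major allele among the polled cases is
  identified and its frequency tracked in cases and controls; frequencies
  are averaged in 20-kb sliding windows; per window a Nei-style G<sub>ST</sub>
  is computed from the two window-mean frequencies,
  F_ST = (H_T − H_S) / H_T with H_T = 2p̄(1−p̄) at the across-group mean and
  H_S the mean within-group heterozygosity; windows above
  mean + k·SD (k = 1) are merged into the called identity-by-descent (IBD)
  interval.
- **Segregation analysis** — the sex-influenced dominance rule
  (`predict_phenotype()`), genotype–phenotype concordance per breed
  (`concordance()`, with a configurable policy for scurred animals), genotype
  frequency tables and counting verbs over animal panels, plus packaged
  transcriptions of the study's published genotype tables
  (`horn_status_tables()`).
- **Linkage disequilibrium** — EM haplotype-frequency estimation from
  unphased two-locus genotype counts (`em_haplotypes()`), D, D′ and
  r² = D²/(p_A(1−p_A)p_B(1−p_B)) (`ld_stats()`), and per-group r² with group
  ratios (`grouped_r2()`).
- **In-silico genotyping** — exact-match primer site search, PCR product
  prediction, multiplex-PCR genotype calls for the insertion (fragments
  2286/389/676 bp with the insertion, 506 bp without), IUPAC restriction
  digestion (Hpy188I, TCN^GA) and RFLP fragment-pattern genotype calls.
- **Synthetic data** — generators for all of the above: a case/control SNP
  matrix with a fixed case haplotype in a known interval, allele template
  sequences realising the published amplicon geometry, restriction-assay
  amplicons, and breed panels under the dominance model. Everything is
  seed-deterministic, so the full pipeline is testable without sequencing
  data.

Functions take data frames first and return tibbles, so they chain with the
pipe; fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate the resequencing design — 12 polled cases and 12 horned controls
over a 246-kb region, with cases sharing a fixed haplotype between
29,436,000 and 29,476,000 bp — and scan it:

```r
library(hornscan)

sm   <- simulate_scan_data(seed = 1)
scan <- scan_selection(sm, region = c(29331000, 29577000))
scan
#> Windowed F_ST scan: 50 windows (50 with sites), threshold 0.2099 (mean + 1 SD)
#> Called IBD interval(s):
#> # A tibble: 1 × 2
#>      start      end
#>      <dbl>    <dbl>
#> 1 29431000 29481000
```

The called interval brackets the true shared segment to within one 5-kb
step on each side; `autoplot(scan)` draws the two frequency curves, the
F<sub>ST</sub> track and the threshold. In-silico genotyping of a
heterozygote recovers the published band pattern:

```r
fx <- synth_allele_sequences(seed = 1)
multiplex_genotype(fx$sequences[c("anc", "der")], fx$primers)
#> $fragments
#> [1]  389  506  676 2286
#> $genotype
#> [1] "anc/der"
```

The packaged genotype tables regenerate the headline aggregates of the
segregation analysis — e.g. 110 males homozygous G/G at the intron-11 SNP in
breeds whose males are uniformly horned, or 98.7 % of Rambouillet rams
carrying the genotype associated with polledness:

```r
run_report()$headline
#> # A tibble: 6 × 2
#>   statistic                            value
#>   <chr>                                <dbl>
#> 1 gg_males_sex_dependent_breeds       110
#> 2 ag_males_completely_polled_breeds    17
#> 3 ag_females_completely_horned_breeds   6
#> 4 ethiopian_menz_ag_freq                0.12
#> 5 tibetan_ag_freq                       0.11
#> 6 rambouillet_gg_male_pct              98.7
```

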