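---
title: "Methods: selection scans, segregation and in-silico genotyping for ovine horn status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, segregation and in-silico genotyping for ovine horn status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hornscan)
```

`hornscan` bundles four analyses used to interrogate the candidate polled
mutation in sheep — a 1.78-kb insertion in the 3′-UTR of *RXFP2* — together
with a synthetic-data module that generates inputs with the structural
properties each analysis assumes. This vignette is the package's account of
the underlying models, the tunable parameters, the numerical choices, and
what the tests do and do not establish.

## The sex-influenced dominance model

The inheritance model is deliberately minimal: one autosomal biallelic locus
whose horned allele (*anc*, the ancestral state without the insertion) acts
dominant in males and recessive in females. `predict_phenotype()` therefore
maps

| genotype   | male   | female |
|------------|--------|--------|
| anc/anc    | horned | horned |
| anc/der    | horned | polled |
| der/der    | polled | polled |

Homozygotes are mapped identically in both sexes, which is why panels may
carry animals of unrecorded sex (`sex = "unknown"`, as in breed surveys
reported as genotype counts): their prediction is defined unless they are
heterozygous, in which case it is flagged undefined rather than guessed.

Scurs, knobs and horn rudiments are genuinely intermediate phenotypes, and
the literature disagrees on whether to count them as horned or polled.
`concordance()` therefore defaults to a separate `intermediate` class
(`scur_policy = "intermediate"`), with explicit switches to fold them into
either side. Historical multi-allele models (three alleles at one locus, or
linked modifier loci) are documented here for context but not implemented:
the two-allele sex-influenced rule is the hypothesis the analyses test.

The packaged tables (`horn_status_tables()`) are per-stratum transcriptions
of the published genotype counts for three sample sets (fixed-status breeds;
crosses; variable-status breeds) and an international SNP survey. Cells
whose genotype-column placement could not be established unambiguously from
the source rendering carry `uncertain = TRUE`; no headline statistic
computed by `run_report()` or asserted in the test suite depends on an
uncertain cell. Checksums (row-count totals per table and per breed
category) are verified on every load, so a corrupted fixture fails loudly.

## The windowed F_ST selection scan

The scan takes a biallelic site-by-sample dosage matrix with case
(= polled) and control (= horned) labels and proceeds in four steps.

1. **Informativeness filter.** Sites with pooled-sample minor allele
   frequency strictly above `maf_min` (default 0.05) are retained; sites
   with call rate below 0.8 are dropped first. Removal counts are emitted
   as structured messages, never silently.
2. **Case-major profile.** Per site, the major allele among the cases is
   the allele with case frequency ≥ 0.5; an exact tie resolves to the
   reference allele — a deterministic, documented tie-break. Both group
   frequencies then refer to that same allele.
3. **Window statistics.** Windows of `window_size` (default 20,000 bp, the
   published window) slide on a `step` grid (default 5,000 bp; the original
   description says "sliding" without a step, so the step is configurable
   and `step = window_size` gives non-overlapping windows). Within a
   window the two group frequencies are averaged over sites, and
   F_ST is a Nei-style G_ST on those window means: with
   p̄ the across-group mean, H_T = 2p̄(1−p̄), H_S the mean of the two
   within-group heterozygosities, F_ST = (H_T − H_S)/H_T, defined as 0 when
   H_T = 0. The estimator is frequency-level rather than genotype-level
   because the procedure being modelled explicitly averages frequencies
   over windows before estimating F_ST; no sample-size correction is
   applied, and group weights are equal.
4. **IBD calling.** The threshold is mean + `k_sd`·SD of F_ST over
   non-empty windows, with the population (n-divisor) SD — the published
   account does not disambiguate the divisor, and the choice is recorded
   here; with ~50 windows the difference is below 1 %. Windows strictly
   above threshold are merged (overlapping or touching spans) into maximal
   intervals. Coordinates are 1-based half-open internally; BED exports are
   0-based half-open.

Two properties of this estimator deserve note. First, the mean + 1·SD
threshold is self-calibrating: a genuine shared-haplotype signal inflates
the SD and pushes the threshold well above the background, which is why
partially overlapping windows at the segment edges fall back below it and
the called boundaries land within about one step of the truth. Second,
label-swap symmetry (cases ↔ controls) is exact at the *site* level — the
case-major allele is re-derived and G_ST is invariant under jointly swapping
and complementing the two frequencies — but only approximate at the window
level, because the per-site allele polarity enters the window means. The
tests assert the exact site-level invariance.

## Two-locus linkage disequilibrium

`em_haplotypes()` estimates the four haplotype frequencies from a 3×3 table
of unphased two-locus genotype counts. The allele frequencies are fixed by
the genotype margins, so the likelihood has a single free parameter (the
frequency of the haplotype carrying both second alleles); the only
phase-ambiguous class is the double heterozygote, which the E-step splits in
proportion to the current haplotype-frequency products.

Initialisation matters more than it first appears. Linkage equilibrium —
the spec-level natural start — is an *exact fixed point* of the EM map
whenever the unambiguous genotype classes happen to sit at equilibrium, and
the profile likelihood can be bimodal, so a single LE start can converge to
a saddle or a minor mode. The fit therefore runs from three starts (LE and
the two near-boundary phase configurations) and returns the run with the
highest final log-likelihood. Convergence is declared when the largest
absolute frequency change falls below `tol` (default 1e-10, effectively
machine-level for these problem sizes); within a run the log-likelihood is
non-decreasing, which the tests assert.

`ld_stats()` reports D = p₂₂ − p_A·p_B, D′ = D/D_max with the standard
sign-dependent D_max, and r² = D²/(p_A(1−p_A)p_B(1−p_B)). LD is undefined
(an error, not an NA) at a monomorphic locus. `grouped_r2()` applies the
fit per group of a panel, skips monomorphic groups with a warning, and
reports group r² ratios rounded to two decimals with the denominator floored
at 1e-12, as published group comparisons do. Whether the original analysis
used EM-based composite LD or known phase is not stated; EM over unphased
counts matches the estimator family of the named software and is the
implemented choice.

## In-silico genotyping

Primer matching is exact (plus strand and reverse complement), with no
mismatch tolerance or thermodynamics. This is not a simplification of
convenience: the amplification-created restriction site (ACRS) assay being
modelled *deliberately* embeds a primer–template mismatch, so templates
generated from the primers reproduce the assay exactly under literal
matching, whereas a mismatch model would need melting-temperature
parameters the analysis never uses. `pcr()` reports every forward-site ×
downstream-reverse-site product up to `max_len` (default 10,000 bp),
mirroring what a gel shows.

`digest()` cuts at every IUPAC match of the recognition pattern on either
strand: plus-strand matches at the enzyme's cut offset, minus-strand
matches at the mirrored offset, and coincident spans (the Hpy188I site
TCNGA is its own reverse complement at the IUPAC level) cut once. Fragment
lengths always partition the template — a conservation property the tests
check on random sequences. Enzymes are user-definable records
(`restriction_enzyme("Hpy188I", "TCNGA", 3)` or the `"TCNGA:3"` shorthand),
not a bundled database.

Genotype calls are fragment-pattern matches. For the multiplex insertion
assay: insertion-dependent products (389 and 676 bp) without the 506-bp
ancestral product → `der/der`; the ancestral product without insertion
products → `anc/anc`; both → `anc/der`; anything else → `uncallable`.
For RFLP calls, a heterozygote is the union of the two allele band sets,
and an optional detection floor (`min_fragment`, default off, 20 bp typical)
masks bands that would run off a gel.

## What the synthetic data emulate — and what they do not

`simulate_scan_data()` emulates the *structure* of the case/control
resequencing comparison: 12 + 12 samples (the study design), a 246-kb region
(29,331,000–29,577,000), ~2 SNPs/kb, per-site population allele frequencies
drawn from Beta(0.8, 0.8), and an identity-by-descent interval
(29,436,000–29,476,000, the ~40-kb published segment) inside which every
case is homozygous for the same allele. The Beta(0.8, 0.8) background is a
fixture choice: a folded-U frequency spectrum that keeps a tail of sites
below the 5 % MAF filter so the filter path is genuinely exercised. Sites
are independent given their frequency — there is **no background LD decay
model** and no read-level error — so passing the recovery tests shows the
estimator finds a clean shared segment under sampling noise, not that it is
robust to autocorrelated backgrounds or genotyping error in real capture
data. The published threshold value itself (0.3159) depends on the raw
sequencing data and is not a target of the simulation.

`synth_allele_sequences()` encodes the published assay geometry as defaults
(506-bp ancestral F1/R1 span; 1,780-bp insertion; 389- and 676-bp
insertion-dependent products, hence a 2,286-bp derived F1/R1 product) around
generated 20-mer primers, since the study's primer sequences live in
supplementary material. The targets therefore validate the *engine* and the
geometry, not the literal oligonucleotides. The insertion point within the
amplicon is placed mid-feasible-range given the product-size constraints.
The derived haplotype's ancillary 83-bp absence (plus 13 substitutions and a
1-bp deletion) is available behind `include_83bp_deletion`, default off: the
published account leaves ambiguous whether it falls inside the F1/R1
amplicon (the printed sizes are only consistent with it falling outside),
so when enabled it is placed downstream of the R1 site where it cannot
perturb the printed product sizes.

`synth_breed_panel()` draws insertion genotypes per breed category
(derived-allele frequency 0.97 in completely polled breeds — matching the
small heterozygote fraction seen in fixed-status surveys — 0 in completely
horned, 0.5 in sex-dependent and variable breeds, Hardy–Weinberg within
category), assigns the model-predicted phenotype, and flips a
`discordance_rate` fraction. It emulates marker–phenotype discordance as
independent random flips; real discordance is breed-structured.

All generators are seed-deterministic; every stochastic test and the
acceptance script fix seeds explicitly.

## Numerical and reporting choices

- Printed frequencies and percentages round half-up (`0.115 → 0.12`),
  matching how published tables are rounded; base R's banker's rounding is
  deliberately not used for reported values.
- Coordinates are 1-based inclusive throughout, half-open for windows and
  intervals; only BED output converts to 0-based.
- Genotype strings are order-insensitive on input (`der/anc ≡ anc/der`) and
  canonicalised on parse; unparseable genotypes become missing with a
  logged count, empty cells silently missing.
- Degenerate inputs fail loudly where the quantity is undefined (LD at a
  monomorphic locus, IBD calling with fewer than two non-empty windows,
  empty panels) and degrade gracefully where it is defined (empty window →
  `n_sites = 0`, excluded from threshold statistics; all sites filtered →
  empty result with a warning).
- Problem sizes in the test suite are chosen for tightness of the oracles,
  not realism: brute-force window recomputation on ≤ 50-site matrices,
  grid-search ML on tables of n ≤ 30, 20 simulation seeds for interval
  recovery. At these sizes the whole suite runs in well under a minute.

## Known limitations

- The F_ST estimator is the frequency-level G_ST described above; per-site
  or genotype-level estimators (Weir–Cockerham and relatives) are out of
  scope, and no significance is attached to the mean + k·SD threshold.
- Exact primer matching cannot model degenerate or mismatched binding
  beyond what is embedded in the template.
- The segregation model is the two-allele sex-influenced rule; penetrance
  estimation, likelihood-based segregation ratios and pedigrees are not
  implemented.
- The packaged tables are transcriptions; cells flagged `uncertain` should
  not be used as ground truth for per-cell analyses.
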