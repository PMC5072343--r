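# Synthetic inputs with the structural properties the analyses assume:
# a case/control SNP matrix with a fixed case haplotype, allele template
# sequences with the published amplicon geometry, restriction-assay
# amplicons, and breed panels under the sex-influenced dominance model.

#' Simulate a case/control genotype matrix with a shared case haplotype
#'
#' Emulates the data structure of a capture-resequencing comparison between
#' polled cases and horned controls: biallelic SNPs scattered over a genomic
#' region, per-site population allele frequencies drawn from a (U-shaped)
#' Beta distribution, and an identity-by-descent interval inside which every
#' case is fixed homozygous for the same allele while controls keep following
#' the background frequencies. Sites are independent given their frequency
#' (no background LD model).
#'
#' @param n_case,n_control Number of case (polled) and control (horned)
#'   samples; defaults mirror the 12 + 12 resequencing design.
#' @param region Length-2 integer vector, 1-based inclusive bounds of the
#'   simulated region (default the 246-kb window around RXFP2).
#' @param snp_density Expected SNPs per kb.
#' @param ibd_interval Length-2 vector, the interval where cases share a fixed
#'   homozygous haplotype (default the ~40-kb segment 29,436,000-29,476,000),
#'   or `NULL` for no shared segment.
#' @param beta_shape1,beta_shape2 Beta parameters of the per-site population
#'   alternate-allele frequency (default 0.8/0.8: folded-U spectrum that keeps
#'   a tail of sites below a 5 % MAF filter).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [site_matrix()] with samples `case_01`... and `ctrl_01`....
#' @export
simulate_scan_data <- function(n_case = 12, n_control = 12,
                               region = c(29331000L, 29577000L),
                               snp_density = 2,
                               ibd_interval = c(29436000L, 29476000L),
                               beta_shape1 = 0.8, beta_shape2 = 0.8,
                               seed = NULL) {
  if (n_case < 2 || n_control < 2) abort("Need at least 2 cases and 2 controls.")
  if (length(region) != 2 || region[2] <= region[1]) abort("Invalid `region`.")
  if (!is.null(ibd_interval)) {
    if (length(ibd_interval) != 2 || ibd_interval[2] < ibd_interval[1]) {
      abort("Invalid `ibd_interval`.")
    }
    if (ibd_interval[1] < region[1] || ibd_interval[2] > region[2]) {
      abort("`ibd_interval` must lie inside `region`.")
    }
  }
  with_opt_seed(seed, {
    width <- region[2] - region[1] + 1
    n_sites <- max(2L, as.integer(round(width / 1000 * snp_density)))
    pos <- sort(sample.int(width, n_sites)) + region[1] - 1L
    p <- rbeta(n_sites, beta_shape1, beta_shape2)
    ref_alt <- t(vapply(
      seq_len(n_sites),
      function(i) sample(c("A", "C", "G", "T"), 2),
      character(2)
    ))
    in_ibd <- if (is.null(ibd_interval)) {
      rep(FALSE, n_sites)
    } else {
      pos >= ibd_interval[1] & pos <= ibd_interval[2]
    }
    sites <- tibble(
      contig = "OAR10", pos = pos,
      ref = ref_alt[, 1], alt = ref_alt[, 2]
    )
    case_names <- sprintf("case_%02d", seq_len(n_case))
    ctrl_names <- sprintf("ctrl_%02d", seq_len(n_control))
    for (s in case_names) {
      d <- rbinom(n_sites, 2L, p)
      d[in_ibd] <- 2L # every case homozygous for the alternate allele
      sites[[s]] <- as.integer(d)
    }
    for (s in ctrl_names) {
      sites[[s]] <- as.integer(rbinom(n_sites, 2L, p))
    }
    site_matrix(sites, case = case_names, control = ctrl_names)
  })
}

# Count exact plus-strand occurrences of `what` in `sequence`.
n_occurrences <- function(sequence, what) length(iupac_match_starts(sequence, what))

# Verify a primer binds exactly `fwd`/`rev` times on each strand of a template.
primer_sites_ok <- function(template, primer, fwd, rev) {
  n_occurrences(template, primer) == fwd &&
    n_occurrences(template, revcomp(primer)) == rev
}

#' Generate ancestral/derived allele templates for the multiplex PCR assay
#'
#' Builds a pair of DNA templates that realise the published multiplex-PCR
#' geometry around the insertion site: on the ancestral template the flanking
#' primers F1/R1 span `anc_amplicon_f1r1` bp; the derived template carries an
#' `insertion_length`-bp insertion placed so that F1 with the
#' insertion-internal reverse primer R2 spans `f1r2_product` bp and the
#' insertion-internal forward primer F2 with R1 spans `f2r1_product` bp.
#' Primer sequences are generated 20-mers (the published primers live in
#' supplementary material); each binds exactly once per template and
#' orientation, and F2/R2 sites lie wholly inside the insertion, so the
#' fragment-pattern logic of the assay is fully exercised.
#'
#' @param insertion_length Insertion size in bp (default 1780).
#' @param anc_amplicon_f1r1 F1..R1 span on the ancestral allele (default 506).
#' @param f1r2_product,f2r1_product Derived-allele product sizes (defaults 389
#'   and 676), measured primer start to primer end inclusive.
#' @param flank Extra sequence outside the F1/R1 footprint, bp per side.
#' @param include_83bp_deletion If `TRUE`, additionally remove 83 bp from the
#'   derived template downstream of the R1 site (outside all amplicons; the
#'   placement of this ancillary deletion relative to the amplicon is not
#'   resolvable, so product sizes are unaffected). Default `FALSE`.
#' @param primer_length Primer length in bp.
#' @param seed Integer seed.
#' @return A list with elements `sequences` (named character vector `anc`,
#'   `der`), `primers` (named vector `F1`, `F2`, `R1`, `R2`) and
#'   `insertion_after` (ancestral coordinate after which the insertion sits).
#' @export
synth_allele_sequences <- function(insertion_length = 1780,
                                   anc_amplicon_f1r1 = 506,
                                   f1r2_product = 389,
                                   f2r1_product = 676,
                                   flank = 120,
                                   include_83bp_deletion = FALSE,
                                   primer_length = 20,
                                   seed = NULL) {
  pl <- primer_length
  A <- anc_amplicon_f1r1
  L <- insertion_length
  if (A < 2 * pl + 2) abort("`anc_amplicon_f1r1` too small for two primers.")
  f1s <- flank + 1L

  if (L == 0) {
    return(with_opt_seed(seed, {
      for (i in 1:25) {
        primers <- c(
          F1 = random_dna(pl), F2 = random_dna(pl),
          R1 = random_dna(pl), R2 = random_dna(pl)
        )
        anc <- random_dna(flank + A + flank)
        anc <- plant_seq(anc, primers[["F1"]], f1s)
        anc <- plant_seq(anc, revcomp(primers[["R1"]]), f1s + A - pl)
        ok <- primer_sites_ok(anc, primers[["F1"]], 1, 0) &&
          primer_sites_ok(anc, primers[["R1"]], 0, 1) &&
          primer_sites_ok(anc, primers[["F2"]], 0, 0) &&
          primer_sites_ok(anc, primers[["R2"]], 0, 0)
        if (ok) {
          return(list(
            sequences = c(anc = anc, der = anc), primers = primers,
            insertion_after = NA_integer_
          ))
        }
      }
      abort("Could not realise unique primer sites; widen the flanks.")
    }))
  }

  if (L <= f1r2_product) abort("`insertion_length` must exceed `f1r2_product`.")
  # Feasible insertion points q (insertion sits after ancestral position q):
  # after F1, before the R1 footprint, R2 wholly inside the insertion, and
  # F2 wholly inside the insertion.
  lo <- max(f1s + pl, f1s + A - f2r1_product + pl - 1)
  hi <- min(f1s + f1r2_product - pl - 1, f1s + A - pl - 1)
  if (lo > hi) abort("Infeasible assay geometry: no valid insertion point.")
  q <- as.integer((lo + hi) %/% 2)
  rel_r2 <- f1s + f1r2_product - pl - q # R2 site start, insertion-relative
  rel_f2 <- f1s + A + L - f2r1_product - q # F2 start, insertion-relative
  if (rel_r2 < 1 || rel_f2 + pl - 1 > L || rel_f2 <= rel_r2 + pl - 1) {
    abort("Infeasible assay geometry: internal primers do not fit the insertion.")
  }

  with_opt_seed(seed, {
    for (i in 1:25) {
      primers <- c(
        F1 = random_dna(pl), F2 = random_dna(pl),
        R1 = random_dna(pl), R2 = random_dna(pl)
      )
      anc <- random_dna(flank + A + flank)
      anc <- plant_seq(anc, primers[["F1"]], f1s)
      anc <- plant_seq(anc, revcomp(primers[["R1"]]), f1s + A - pl)
      ins <- random_dna(L)
      ins <- plant_seq(ins, revcomp(primers[["R2"]]), rel_r2)
      ins <- plant_seq(ins, primers[["F2"]], rel_f2)
      der <- paste0(substr(anc, 1, q), ins, substr(anc, q + 1, nchar(anc)))
      if (include_83bp_deletion) {
        cut_at <- q + L + (f1s + A - q) + 10 # 10 bp past the R1 site on der
        if (cut_at + 83 > nchar(der)) abort("Flank too short for the 83-bp deletion.")
        der <- paste0(substr(der, 1, cut_at - 1), substr(der, cut_at + 83, nchar(der)))
      }
      ok <- primer_sites_ok(anc, primers[["F1"]], 1, 0) &&
        primer_sites_ok(anc, primers[["R1"]], 0, 1) &&
        primer_sites_ok(anc, primers[["F2"]], 0, 0) &&
        primer_sites_ok(anc, primers[["R2"]], 0, 0) &&
        primer_sites_ok(der, primers[["F1"]], 1, 0) &&
        primer_sites_ok(der, primers[["R1"]], 0, 1) &&
        primer_sites_ok(der, primers[["F2"]], 1, 0) &&
        primer_sites_ok(der, primers[["R2"]], 0, 1)
      if (ok) {
        return(list(
          sequences = c(anc = anc, der = der), primers = primers,
          insertion_after = q
        ))
      }
    }
    abort("Could not realise unique primer sites; widen the flanks.")
  })
}

# Remove every TCNGA-family motif from `sequence` by redrawing bases at the
# offending positions, leaving `protected` positions untouched.
scrub_motifs <- function(sequence, pattern, protected = integer(0)) {
  for (i in 1:200) {
    hits <- iupac_match_starts(sequence, pattern)
    hits <- hits[!vapply(
      hits,
      function(h) all(seq(h, h + nchar(pattern) - 1) %in% protected),
      logical(1)
    )]
    if (length(hits) == 0) return(sequence)
    h <- hits[[1]]
    span <- setdiff(seq(h, h + nchar(pattern) - 1), protected)
    for (j in span) {
      substr(sequence, j, j) <- sample(c("A", "C", "G", "T"), 1)
    }
  }
  abort("Could not scrub recognition motifs from the random fill.")
}

#' Generate the 754-bp exon-14 amplicon fixture for the Hpy188I RFLP assay
#'
#' Builds the amplicon whose Hpy188I (TCN^GA) digestion pattern distinguishes
#' the exon-14 SNP alleles: the A-allele template carries exactly one site,
#' yielding fragments of 726 and 28 bp; the G-allele template carries two,
#' yielding 429, 297 and 28 bp. The random fill is rejection-sampled so no
#' spurious TCNGA motif exists on either strand. With the same seed, the A
#' and G templates differ only at the allele-dependent site.
#'
#' @param allele `"A"` or `"G"`.
#' @param seed Integer seed.
#' @return A list with `sequence` (754 bp), `forward`, `reverse` (primer pair
#'   matching the template ends) and `allele`.
#' @export
synth_rflp_fixture <- function(allele = c("A", "G"), seed = NULL) {
  allele <- match.arg(allele)
  total <- 754L
  pattern <- "TCNGA"
  with_opt_seed(seed, {
    # Cuts after 726 (A and G) and additionally after 429 (G only); a TCN^GA
    # site cutting after position c starts at c - 2.
    sites <- c(724L, if (allele == "G") 427L)
    base <- random_dna(total)
    protected <- unlist(lapply(sites, function(s) seq(s, s + 4)))
    for (s in sites) {
      base <- plant_seq(base, paste0("TC", sample(c("A", "C", "G", "T"), 1), "GA"), s)
    }
    base <- scrub_motifs(base, pattern, protected = protected)
    list(
      sequence = base,
      forward = substr(base, 1, 20),
      reverse = revcomp(substr(base, total - 19, total)),
      allele = allele
    )
  })
}

#' Generate the 104-bp ACRS amplicon fixture for the 3'-UTR SNP assay
#'
#' The amplification-created restriction site assay: the published primer
#' pair brackets a 104-bp product in which the reverse primer's engineered
#' mismatch creates an Hpy188I site only when allele G is present, so
#' digestion yields 104 bp (allele A) or 82 + 22 bp (allele G).
#'
#' @param allele `"A"` or `"G"`.
#' @param seed Integer seed.
#' @return A list with `sequence`, `forward`, `reverse` and `allele`.
#' @export
synth_acrs_fixture <- function(allele = c("A", "G"), seed = NULL) {
  allele <- match.arg(allele)
  forward <- "CAAGCCAAAAAGGTGAATGG"
  reverse <- "GTGGAGCAGCAGCTTTGAAAT"
  rc_rev <- revcomp(reverse) # occupies positions 84..104
  with_opt_seed(seed, {
    base <- paste0(forward, random_dna(104 - nchar(forward) - nchar(rc_rev)), rc_rev)
    protected <- c(seq_len(nchar(forward)), seq(84, 104))
    if (allele == "G") {
      # Site at 80..84 (cut after 82 -> 82 + 22); last base is the leading A
      # of the reverse-primer footprint.
      base <- plant_seq(base, paste0("TC", sample(c("A", "C", "G", "T"), 1), "G"), 80)
      protected <- c(protected, seq(80, 84))
    }
    base <- scrub_motifs(base, "TCNGA", protected = protected)
    list(sequence = base, forward = forward, reverse = reverse, allele = allele)
  })
}

CATEGORY_DER_FREQ <- c(
  completely_polled = 0.97, completely_horned = 0,
  sex_dependent = 0.5, variable = 0.5
)

#' Simulate a breed panel under the sex-influenced dominance model
#'
#' Draws insertion-marker genotypes per breed category (polled breeds rich in
#' the derived allele, horned breeds fixed ancestral, sex-dependent and
#' variable breeds intermediate, Hardy-Weinberg within category), assigns the
#' phenotype the sex-influenced dominance rule predicts, then flips a
#' `discordance_rate` fraction of phenotypes (horned to polled and vice
#' versa) to emulate breeds where the marker does not segregate with horn
#' status.
#'
#' @param category Breed category, one of `completely_polled`,
#'   `completely_horned`, `sex_dependent`, `variable`.
#' @param n_male,n_female Animals per sex.
#' @param discordance_rate Fraction of animals whose phenotype is flipped.
#' @param breed Breed label (defaults to the category name).
#' @param seed Integer seed.
#' @return A panel tibble with columns `animal_id`, `breed`, `breed_category`,
#'   `sex`, `phenotype` and `RXFP2_ins`.
#' @export
synth_breed_panel <- function(category, n_male = 10, n_female = 10,
                              discordance_rate = 0, breed = category,
                              seed = NULL) {
  category <- match.arg(category, BREED_CATEGORIES)
  stopifnot(discordance_rate >= 0, discordance_rate <= 1)
  with_opt_seed(seed, {
    n <- n_male + n_female
    p_der <- CATEGORY_DER_FREQ[[category]]
    dosage <- rbinom(n, 2L, p_der)
    genotype <- c("anc/anc", "anc/der", "der/der")[dosage + 1L]
    sex <- c(rep("male", n_male), rep("female", n_female))
    predicted <- predict_phenotype(genotype, sex)
    flip <- runif(n) < discordance_rate
    phenotype <- ifelse(
      flip, ifelse(predicted == "horned", "polled", "horned"), predicted
    )
    tibble(
      animal_id = sprintf("%s_%03d", gsub("\\s+", "_", breed), seq_len(n)),
      breed = breed, breed_category = category,
      sex = sex, phenotype = phenotype, RXFP2_ins = genotype
    )
  })
}
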