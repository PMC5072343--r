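# In silico PCR (single and multiplex) and restriction digestion, with
# genotype calling from fragment-length patterns. Primer matching is exact:
# the assay this models embeds a deliberately mismatched primer into its own
# amplicon, so fixtures carry primer sequences as-is and no thermodynamic
# model is needed.

#' Find exact primer binding sites on a template
#'
#' Plus-strand sites are exact matches of the primer; minus-strand sites are
#' exact matches of its reverse complement (positions reported on the plus
#' strand, 1-based start of the matched span). No mismatches are tolerated.
#'
#' @param template A DNA string.
#' @param primer A primer sequence (5'->3').
#' @return A tibble with columns `position` and `strand` (`"+"`/`"-"`).
#' @export
find_sites <- function(template, primer) {
  if (nchar(primer) < 10) abort("Primer must be at least 10 bp.")
  template <- toupper(template)
  plus <- iupac_match_starts(template, toupper(primer))
  minus <- iupac_match_starts(template, revcomp(primer))
  tibble(
    position = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus)))
  ) |> dplyr::arrange(.data$position, .data$strand)
}

#' Predict PCR products from a primer pair
#'
#' One amplicon per pair of a plus-strand forward site and a downstream
#' minus-strand reverse site, up to `max_len`; product lengths include both
#' primer footprints. All qualifying products are reported, mirroring what a
#' gel would show.
#'
#' @param template A DNA string (or a named length-1 character vector; the
#'   name is carried into the output).
#' @param forward,reverse Primer sequences (5'->3').
#' @param max_len Longest product reported (default 10000).
#' @return A tibble with columns `template`, `start`, `end` (1-based
#'   inclusive) and `length`; zero rows if no product forms.
#' @export
pcr <- function(template, forward, reverse, max_len = 10000) {
  tname <- names(template) %||% "template"
  template <- unname(template)
  f_sites <- find_sites(template, forward)
  r_sites <- find_sites(template, reverse)
  f_pos <- f_sites$position[f_sites$strand == "+"]
  r_pos <- r_sites$position[r_sites$strand == "-"]
  out <- tidyr::expand_grid(f = f_pos, r = r_pos) |>
    dplyr::mutate(
      start = .data$f,
      end = .data$r + nchar(reverse) - 1L,
      length = .data$end - .data$start + 1L
    ) |>
    dplyr::filter(.data$r > .data$f + nchar(forward) - 1L, .data$length <= max_len)
  tibble(
    template = rep(tname, nrow(out)),
    start = as.integer(out$start), end = as.integer(out$end),
    length = as.integer(out$length)
  )
}

#' Multiplex-PCR genotype call for the insertion polymorphism
#'
#' Runs every forward/reverse primer combination of the multiplex set on the
#' template(s) of the two chromosomes, pools the product lengths, and calls
#' the genotype from the fragment pattern: insertion-internal products
#' present and the short ancestral product absent is `der/der`; the ancestral
#' product alone is `anc/anc`; both patterns together are `anc/der`; any
#' other pattern is `uncallable`.
#'
#' @param templates Character vector of one (homozygote) or two template
#'   sequences, one per chromosome.
#' @param primers Named character vector with elements `F1`, `F2`, `R1`, `R2`.
#' @param anc_product Expected ancestral-allele F1/R1 size (default 506).
#' @param ins_products Expected insertion-dependent sizes (default 389 and
#'   676, the F1/R2 and F2/R1 products).
#' @param max_len Passed to [pcr()].
#' @return A list with `fragments` (sorted unique product lengths) and
#'   `genotype` (`"anc/anc"`, `"anc/der"`, `"der/der"` or `"uncallable"`).
#' @export
multiplex_genotype <- function(templates, primers,
                               anc_product = 506, ins_products = c(389, 676),
                               max_len = 10000) {
  stopifnot(all(c("F1", "F2", "R1", "R2") %in% names(primers)))
  fragments <- sort(unique(unlist(lapply(templates, function(tmpl) {
    unlist(lapply(c("F1", "F2"), function(f) {
      unlist(lapply(c("R1", "R2"), function(r) {
        pcr(tmpl, primers[[f]], primers[[r]], max_len = max_len)$length
      }))
    }))
  }))))
  has_anc <- anc_product %in% fragments
  has_ins <- all(ins_products %in% fragments)
  genotype <- if (has_ins && !has_anc) {
    "der/der"
  } else if (has_anc && !any(ins_products %in% fragments)) {
    "anc/anc"
  } else if (has_anc && has_ins) {
    "anc/der"
  } else {
    "uncallable"
  }
  list(fragments = as.integer(fragments), genotype = genotype)
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param pattern IUPAC recognition pattern (e.g. Hpy188I: `"TCNGA"`).
#' @param cut_offset Top-strand cut position within the pattern: the enzyme
#'   cuts after `cut_offset` bases (Hpy188I: 3, i.e. TCN^GA).
#' @return A list of class `restriction_enzyme`.
#' @export
#' @examples
#' hpy188i <- restriction_enzyme("Hpy188I", "TCNGA", 3)
restriction_enzyme <- function(name, pattern, cut_offset) {
  pattern <- toupper(pattern)
  if (cut_offset < 0 || cut_offset > nchar(pattern)) {
    abort("`cut_offset` must lie within the pattern.")
  }
  structure(
    list(name = name, pattern = pattern, cut_offset = as.integer(cut_offset)),
    class = "restriction_enzyme"
  )
}

# Parse "TCNGA:3" shorthand.
as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1 && grepl(":", enzyme)) {
    parts <- strsplit(enzyme, ":", fixed = TRUE)[[1]]
    return(restriction_enzyme(parts[1], parts[1], as.integer(parts[2])))
  }
  abort("`enzyme` must be a restriction_enzyme or a 'PATTERN:offset' string.")
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Cuts at every match of the recognition pattern: plus-strand matches at the
#' enzyme's cut offset, minus-strand matches (spans where the plus strand
#' reads the pattern's reverse complement) at the mirrored offset. Matches
#' occupying the same span on both strands (as for the self-complementary
#' TCNGA) cut once. Fragment lengths always partition the template.
#'
#' @param sequence A DNA string.
#' @param enzyme A [restriction_enzyme()] or `"PATTERN:offset"` string.
#' @return Integer vector of fragment lengths, descending.
#' @export
#' @examples
#' digest("AAATCAGAAAA", "TCNGA:3")
digest <- function(sequence, enzyme) {
  enzyme <- as_enzyme(enzyme)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  plen <- nchar(enzyme$pattern)
  plus <- iupac_match_starts(sequence, enzyme$pattern)
  minus <- iupac_match_starts(sequence, revcomp(enzyme$pattern))
  cuts <- c(
    plus + enzyme$cut_offset - 1L,
    setdiff(minus, plus) + (plen - enzyme$cut_offset) - 1L
  )
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < len]))
  bounds <- c(0L, cuts, len)
  sort(as.integer(diff(bounds)), decreasing = TRUE)
}

#' Call a genotype from observed restriction-fragment lengths
#'
#' A homozygote matches one allele's expected fragment pattern; a
#' heterozygote matches the union of both alleles' band sets (a gel shows
#' the union of band positions); anything else is uncallable. Optionally,
#' fragments below a detection floor are masked from both the observation
#' and the expectations, mimicking small fragments running off the gel.
#'
#' @param fragments Integer vector of observed fragment lengths.
#' @param allele_patterns Named list of two expected fragment-length vectors,
#'   e.g. `list(A = c(726, 28), G = c(429, 297, 28))`.
#' @param min_fragment Detection floor in bp; `0` (default) disables masking,
#'   `20` mimics a typical agarose gel.
#' @return A genotype string (`"A/A"`, `"A/G"`, ... ) or `"uncallable"`.
#' @export
rflp_call <- function(fragments, allele_patterns, min_fragment = 0) {
  stopifnot(length(allele_patterns) == 2, !is.null(names(allele_patterns)))
  visible <- function(x) sort(unique(as.numeric(x[x >= min_fragment])))
  obs <- visible(fragments)
  alleles <- names(allele_patterns)
  pat <- lapply(allele_patterns, visible)
  hom <- lapply(alleles, function(a) pat[[a]])
  het <- sort(unique(c(pat[[1]], pat[[2]])))
  if (identical(obs, hom[[1]])) {
    paste(alleles[1], alleles[1], sep = "/")
  } else if (identical(obs, hom[[2]])) {
    paste(alleles[2], alleles[2], sep = "/")
  } else if (identical(obs, het)) {
    paste(sort(alleles), collapse = "/")
  } else {
    "uncallable"
  }
}
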