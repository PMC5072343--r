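#' Define a genetic marker
#'
#' A marker is a biallelic locus: either a SNP or a presence/absence
#' polymorphism such as the 1.78-kb insertion in the 3'-UTR of RXFP2. The
#' first allele is the reference-like one (for the insertion marker, the
#' ancestral allele `anc`, i.e. no insertion).
#'
#' @param name Marker name, e.g. `"rs421908034"`.
#' @param alleles Character vector of exactly two distinct allele names,
#'   reference-like first.
#' @param kind `"snp"` or `"presence_absence"`.
#' @param contig,pos Optional 1-based genomic coordinate of the marker.
#' @return A one-row tibble of class `marker_def`.
#' @export
#' @examples
#' marker_def("RXFP2_ins", c("anc", "der"), "presence_absence",
#'   contig = "NC_019467.2", pos = 29433060
#' )
marker_def <- function(name, alleles, kind = c("snp", "presence_absence"),
                       contig = NA_character_, pos = NA_integer_) {
  kind <- match.arg(kind)
  if (length(alleles) != 2L || anyDuplicated(alleles) > 0) {
    abort("`alleles` must be two distinct allele names.")
  }
  out <- tibble(
    name = name, allele1 = alleles[[1]], allele2 = alleles[[2]],
    kind = kind, contig = contig, pos = as.integer(pos)
  )
  class(out) <- c("marker_def", class(out))
  out
}

#' Markers analysed around ovine RXFP2
#'
#' The four markers used throughout: the 1.78-kb 3'-UTR insertion
#' (alleles `anc`/`der`), the 3'-UTR SNP rs421908034, the exon-14 SNP
#' rs414104606 and the intron-11 SNP OAR10_29511510.1.
#'
#' @return A tibble with one row per marker.
#' @export
default_markers <- function() {
  dplyr::bind_rows(
    marker_def("RXFP2_ins", c("anc", "der"), "presence_absence",
      contig = "NC_019467.2", pos = 29433060L
    ),
    marker_def("rs421908034", c("A", "G"), "snp",
      contig = "NC_019467.2", pos = 29432846L
    ),
    marker_def("rs414104606", c("A", "G"), "snp", contig = "NC_019467.2"),
    marker_def("OAR10_29511510.1", c("A", "G"), "snp", contig = "NC_019467.2")
  )
}

# Normalise "x/y" genotype strings: order-insensitive input, canonical output.
# `alleles` (optional, length 2) fixes the canonical order; otherwise
# alphabetical. Unparseable strings become NA; the count is returned as an
# attribute for the caller to log.
normalize_genotypes <- function(x, alleles = NULL) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  parts <- strsplit(trimws(x), "/", fixed = TRUE)
  n_bad <- 0L
  out <- vapply(parts, function(p) {
    if (length(p) == 1L && is.na(p)) return(NA_character_)
    p <- trimws(p)
    ok <- length(p) == 2L && all(nzchar(p)) &&
      (is.null(alleles) || all(p %in% alleles))
    if (!ok) {
      n_bad <<- n_bad + 1L
      return(NA_character_)
    }
    p <- if (is.null(alleles)) sort(p) else p[order(match(p, alleles))]
    paste(p, collapse = "/")
  }, character(1))
  out[vapply(parts, function(p) length(p) == 1L && is.na(p[1]), logical(1))] <- NA_character_
  attr(out, "n_unparseable") <- n_bad
  out
}

# Split canonical "x/y" genotypes into a two-column character matrix.
genotype_alleles <- function(g) {
  parts <- strsplit(as.character(g), "/", fixed = TRUE)
  a1 <- vapply(parts, function(p) if (length(p) == 2) p[[1]] else NA_character_, character(1))
  a2 <- vapply(parts, function(p) if (length(p) == 2) p[[2]] else NA_character_, character(1))
  cbind(a1, a2)
}

# Dosage of `allele` (0, 1, 2 or NA) in canonical genotype strings.
allele_dosage <- function(g, allele) {
  al <- genotype_alleles(g)
  out <- (al[, 1] == allele) + (al[, 2] == allele)
  as.integer(out)
}
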