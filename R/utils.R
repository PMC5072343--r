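# Internal helpers shared across modules.

# round() uses banker's rounding; printed tables in this field round half up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under `seed` when given, without disturbing the caller's RNG.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B"
)

#' Reverse complement of a DNA string
#'
#' Accepts IUPAC ambiguity codes; case is normalised to upper.
#'
#' @param x A single DNA string.
#' @return A single string, the reverse complement of `x`.
#' @export
#' @examples
#' revcomp("TCNGA")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(COMPLEMENT))
  if (length(bad) > 0) {
    abort(paste0("Non-IUPAC characters in sequence: ", paste(bad, collapse = ", ")))
  }
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

# Translate an IUPAC pattern into a plain regular expression.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    abort(paste0("Non-IUPAC characters in pattern: ", paste(bad, collapse = ", ")))
  }
  paste(unname(IUPAC_MAP[chars]), collapse = "")
}

# All (possibly overlapping) match start positions of an IUPAC pattern.
iupac_match_starts <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1L) integer(0) else as.integer(m)
}

# Random DNA string of length n (uniform base composition).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Replace a substring at 1-based [at, at + nchar(value) - 1].
plant_seq <- function(sequence, value, at) {
  stopifnot(at >= 1, at + nchar(value) - 1 <= nchar(sequence))
  paste0(
    substr(sequence, 1, at - 1), value,
    substr(sequence, at + nchar(value), nchar(sequence))
  )
}

# Structured filter log: a message the caller can silence, never a side door
# for data.
inform_filter <- function(what, n) {
  inform(sprintf("%s: %d removed", what, n), class = "hornscan_filter")
}

SEXES <- c("male", "female")
# Panels may carry animals whose sex was not recorded (e.g. breed surveys
# reporting genotype counts only); predictions for heterozygotes are then
# undefined.
PANEL_SEXES <- c("male", "female", "unknown")
PHENOTYPES <- c("horned", "polled", "scurred", "rudiments", "unknown")
BREED_CATEGORIES <- c(
  "completely_polled", "completely_horned", "sex_dependent", "variable"
)
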