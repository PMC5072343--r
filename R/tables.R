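# Packaged transcriptions of the published genotype tables: per-stratum
# counts, not per-animal rows, with an expander to pseudo-animal records.
# Cells whose genotype-column placement could not be established beyond doubt
# carry uncertain = TRUE and are excluded from any headline computation that
# depends on the placement.

TABLE_CHECKSUMS <- list(
  table1 = list(total = 292L, completely_polled = 208L, completely_horned = 84L),
  table2 = list(total = 18L),
  table3 = list(total = 179L),
  table4 = list(total = 767L)
)

#' Packaged horn-status genotype tables
#'
#' Loads the four packaged per-stratum count tables: sample set 1 (completely
#' polled and completely horned breeds, insertion genotypes), sample set 2
#' (crosses between polled and horned breeds), sample set 3 (breeds with
#' variable or sex-dependent horn status) and the intron-11 SNP survey of
#' international breeds with known breed-level horn status. Row-count
#' checksums are verified on load; a mismatch is an error, so silent fixture
#' corruption cannot propagate into reports.
#'
#' @param dir Directory holding `table1.csv` ... `table4.csv`; defaults to
#'   the copies installed with the package.
#' @return A named list of four tibbles with columns `breed_category`,
#'   `breed`, (`phenotype`,) `sex`, `genotype`, `n`, `uncertain`.
#' @export
horn_status_tables <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "hornscan")
  paths <- file.path(dir, sprintf("table%d.csv", 1:4))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Fixture file(s) not found: ", paste(missing, collapse = ", ")))
  }
  tabs <- lapply(paths, function(p) {
    readr::read_csv(p, col_types = readr::cols(
      n = readr::col_integer(), uncertain = readr::col_logical(),
      .default = readr::col_character()
    ), progress = FALSE)
  })
  names(tabs) <- sprintf("table%d", 1:4)
  check <- function(name, got, want) {
    if (got != want) {
      abort(sprintf(
        "Fixture integrity check failed for %s: count %d, expected %d.",
        name, got, want
      ))
    }
  }
  check("table1", sum(tabs$table1$n), TABLE_CHECKSUMS$table1$total)
  by_cat <- tapply(tabs$table1$n, tabs$table1$breed_category, sum)
  check(
    "table1/completely_polled", by_cat[["completely_polled"]],
    TABLE_CHECKSUMS$table1$completely_polled
  )
  check(
    "table1/completely_horned", by_cat[["completely_horned"]],
    TABLE_CHECKSUMS$table1$completely_horned
  )
  check("table2", sum(tabs$table2$n), TABLE_CHECKSUMS$table2$total)
  check("table3", sum(tabs$table3$n), TABLE_CHECKSUMS$table3$total)
  check("table4", sum(tabs$table4$n), TABLE_CHECKSUMS$table4$total)
  tabs
}

#' Expand a per-stratum count table into pseudo-animal records
#'
#' Each count row becomes `n` identical animal records with generated ids, so
#' the stratified published tables can flow through the same panel verbs
#' (concordance, frequency tables, counting) as per-animal data.
#'
#' @param counts A tibble with a `genotype` and an `n` column plus stratum
#'   columns (`breed`, `sex`, optionally `phenotype`, `breed_category`).
#' @param marker Name of the marker the `genotype` column refers to; becomes
#'   the genotype column name of the panel.
#' @param id_prefix Prefix for the generated `animal_id`s.
#' @return A panel tibble with one row per pseudo-animal.
#' @export
expand_counts <- function(counts, marker = "RXFP2_ins", id_prefix = "px") {
  stopifnot(all(c("genotype", "n") %in% names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$n)
  out <- counts[idx, , drop = FALSE]
  out$animal_id <- sprintf("%s_%04d", id_prefix, seq_along(idx))
  out[[marker]] <- out$genotype
  out$genotype <- NULL
  out$n <- NULL
  if (!"phenotype" %in% names(out)) out$phenotype <- "unknown"
  front <- c("animal_id", "breed", "sex", "phenotype")
  as_tibble(out[, c(front, setdiff(names(out), front))])
}
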