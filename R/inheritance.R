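# Sex-influenced dominance model of horn status and genotype-phenotype
# concordance over breed panels. The horned allele (ancestral, no insertion)
# acts dominant in males and recessive in females: heterozygous males are
# horned, heterozygous females polled.

#' Predict horn status from genotype and sex
#'
#' The sex-influenced dominance rule: a male is horned iff he carries at
#' least one copy of the horned allele; a female is horned iff she is
#' homozygous for it. Vectorised; missing genotypes yield `NA` with a
#' warning (flagged, never silent).
#'
#' @param genotype Character vector of `"x/y"` genotypes on a marker with a
#'   designated horned allele (the insertion marker: `anc`).
#' @param sex Character vector, `"male"`/`"female"` (recycled if length 1).
#'   `"unknown"` is accepted for survey data without recorded sex: the
#'   prediction is then defined only for homozygotes (which the rule maps the
#'   same way in both sexes) and `NA` for heterozygotes.
#' @param horned_allele The allele causing horns (default `"anc"`).
#' @return Character vector, `"horned"` or `"polled"` (`NA` where the
#'   genotype is missing or the sex is unknown for a heterozygote).
#' @export
#' @examples
#' predict_phenotype("anc/der", c("male", "female"))
predict_phenotype <- function(genotype, sex, horned_allele = "anc") {
  if (length(sex) == 1) sex <- rep(sex, length(genotype))
  if (length(genotype) == 1) genotype <- rep(genotype, length(sex))
  stopifnot(length(genotype) == length(sex))
  if (!all(sex %in% PANEL_SEXES)) {
    abort("`sex` must be 'male', 'female' or 'unknown'.")
  }
  dosage <- allele_dosage(genotype, horned_allele)
  out <- dplyr::case_when(
    dosage == 2 ~ "horned",
    dosage == 0 ~ "polled",
    sex == "male" ~ "horned",
    sex == "female" ~ "polled",
    TRUE ~ NA_character_ # heterozygote of unknown sex
  )
  n_undef <- sum(is.na(genotype)) + sum(!is.na(dosage) & dosage == 1 & sex == "unknown")
  if (n_undef > 0) {
    warn(sprintf(
      "%d prediction(s) undefined (missing genotype or unknown sex for a heterozygote).",
      n_undef
    ), class = "hornscan_missing")
  }
  out[is.na(genotype)] <- NA_character_
  out
}

# Classify one animal's observed phenotype against the model's prediction.
classify_concordance <- function(predicted, observed, scur_policy) {
  intermediate <- observed %in% c("scurred", "rudiments")
  observed_eff <- observed
  if (scur_policy != "intermediate") observed_eff[intermediate] <- scur_policy
  dplyr::case_when(
    is.na(predicted) | observed == "unknown" ~ "missing",
    scur_policy == "intermediate" & intermediate ~ "intermediate",
    predicted == observed_eff ~ "concordant",
    TRUE ~ "discordant"
  )
}

#' Genotype-phenotype concordance under the sex-influenced dominance model
#'
#' Compares each animal's observed horn status with the phenotype the model
#' predicts from its genotype and sex, per breed and pooled. Scurred animals
#' and animals with horn rudiments form a separate `intermediate` class by
#' default, since the literature disagrees on whether to count them as horned
#' or polled; `scur_policy` folds them into either class instead.
#'
#' @param panel A panel tibble (see [read_panel()]) containing `marker`.
#' @param marker Marker column holding the genotype (default `"RXFP2_ins"`).
#' @param scur_policy `"intermediate"` (default), `"horned"` or `"polled"`.
#' @param horned_allele Allele treated as horn-causing.
#' @return A tibble with one row per breed plus a pooled `"(all)"` row:
#'   `n`, `concordant`, `discordant`, `intermediate`, `missing`.
#' @export
concordance <- function(panel, marker = "RXFP2_ins",
                        scur_policy = c("intermediate", "horned", "polled"),
                        horned_allele = "anc") {
  scur_policy <- match.arg(scur_policy)
  if (nrow(panel) == 0) abort("Empty panel.")
  if (!marker %in% names(panel)) {
    abort(sprintf("Marker '%s' is not a column of the panel.", marker))
  }
  predicted <- withCallingHandlers(
    predict_phenotype(panel[[marker]], panel$sex, horned_allele = horned_allele),
    warning = function(w) {
      if (inherits(w, "hornscan_missing")) invokeRestart("muffleWarning")
    }
  )
  cls <- classify_concordance(predicted, panel$phenotype, scur_policy)
  tab <- panel |>
    dplyr::mutate(.class = cls) |>
    dplyr::count(.data$breed, .data$.class) |>
    tidyr::pivot_wider(
      names_from = ".class", values_from = "n", values_fill = 0L
    )
  for (col in c("concordant", "discordant", "intermediate", "missing")) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }
  tab <- tab[, c("breed", "concordant", "discordant", "intermediate", "missing")]
  pooled <- dplyr::summarise(tab, dplyr::across(-"breed", sum))
  out <- dplyr::bind_rows(tab, dplyr::mutate(pooled, breed = "(all)"))
  dplyr::mutate(out,
    n = .data$concordant + .data$discordant + .data$intermediate + .data$missing,
    .after = "breed"
  )
}

#' Genotype counts and frequencies per stratum
#'
#' Tabulates the three genotype classes of a biallelic marker per breed (or
#' breed-by-sex) stratum over non-missing calls, with frequencies rounded
#' half-up.
#'
#' @param panel A panel tibble.
#' @param marker Marker column name.
#' @param by `"breed"` or `"breed_sex"`.
#' @param decimals Decimal places for the reported frequency (default 2).
#' @return A tibble with the stratum columns, `genotype`, `n` and `freq`.
#' @export
genotype_frequency_table <- function(panel, marker, by = c("breed", "breed_sex"),
                                     decimals = 2) {
  by <- match.arg(by)
  if (!marker %in% names(panel)) {
    abort(sprintf("Marker '%s' is not a column of the panel.", marker))
  }
  keys <- if (by == "breed_sex") c("breed", "sex") else "breed"
  panel |>
    dplyr::filter(!is.na(.data[[marker]])) |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), genotype = .data[[marker]]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(freq = round_half_up(.data$n / sum(.data$n), decimals)) |>
    dplyr::ungroup()
}

#' Count panel animals matching arbitrary conditions
#'
#' A thin, pipe-friendly counting verb over panels: conditions are ordinary
#' expressions on the panel's columns (breed category, sex, genotype columns,
#' phenotype), as in `dplyr::filter()`. Rows where a referenced field is
#' missing do not match.
#'
#' @param panel A panel tibble.
#' @param ... Logical conditions.
#' @return An integer count.
#' @export
#' @examples
#' panel <- synth_breed_panel("completely_horned", seed = 1)
#' count_where(panel, sex == "male", RXFP2_ins == "anc/anc")
count_where <- function(panel, ...) {
  nrow(dplyr::filter(panel, ..., .preserve = FALSE))
}
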