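#' Regenerate the headline aggregates from the packaged tables
#'
#' One-call reporting surface over the packaged genotype tables: sample-set
#' checksums, genotype-phenotype concordance under the sex-influenced
#' dominance model for the insertion marker (sample sets 1-3), breed and
#' breed-by-sex genotype frequencies for the intron-11 SNP survey, and the
#' headline counts discussed in the segregation analysis (males homozygous
#' for the polled-associated SNP allele in sex-dependent breeds,
#' heterozygous males in completely polled breeds, heterozygous females in
#' completely horned breeds, and the per-breed heterozygote frequencies).
#'
#' @param scur_policy How scurred/rudiment animals enter the concordance
#'   tables (see [concordance()]).
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV together with a run manifest.
#' @param fixture_dir Passed to [horn_status_tables()].
#' @return A named list of tibbles: `sample_sets`, `concordance` (one
#'   element per sample set), `snp_frequencies_breed`,
#'   `snp_frequencies_breed_sex` and `headline`.
#' @export
run_report <- function(scur_policy = c("intermediate", "horned", "polled"),
                       out_dir = NULL, fixture_dir = NULL) {
  scur_policy <- match.arg(scur_policy)
  tabs <- horn_status_tables(dir = fixture_dir)

  panels <- list(
    set1 = expand_counts(tabs$table1, marker = "RXFP2_ins", id_prefix = "s1"),
    set2 = expand_counts(tabs$table2, marker = "RXFP2_ins", id_prefix = "s2"),
    set3 = expand_counts(tabs$table3, marker = "RXFP2_ins", id_prefix = "s3")
  )
  snp_panel <- expand_counts(tabs$table4, marker = "OAR10_29511510.1", id_prefix = "s4")

  sample_sets <- tibble(
    sample_set = c("set1", "set2", "set3", "snp_survey"),
    n = c(vapply(panels, nrow, integer(1)), nrow(snp_panel))
  )

  conc <- lapply(panels, function(p) {
    suppressWarnings(concordance(p, marker = "RXFP2_ins", scur_policy = scur_policy))
  })

  freq_breed <- genotype_frequency_table(snp_panel, "OAR10_29511510.1", by = "breed")
  freq_breed_sex <- genotype_frequency_table(snp_panel, "OAR10_29511510.1", by = "breed_sex")

  ag_freq <- function(breed) {
    row <- freq_breed[freq_breed$breed == breed & freq_breed$genotype == "A/G", ]
    if (nrow(row) == 0) 0 else row$freq
  }
  rb_males <- snp_panel[snp_panel$breed == "Rambouillet" & snp_panel$sex == "male", ]
  headline <- tibble(
    statistic = c(
      "gg_males_sex_dependent_breeds",
      "ag_males_completely_polled_breeds",
      "ag_females_completely_horned_breeds",
      "ethiopian_menz_ag_freq",
      "tibetan_ag_freq",
      "rambouillet_gg_male_pct"
    ),
    value = c(
      count_where(
        snp_panel, .data$breed_category == "sex_dependent",
        .data$sex == "male", .data$`OAR10_29511510.1` == "G/G"
      ),
      count_where(
        snp_panel, .data$breed_category == "completely_polled",
        .data$sex == "male", .data$`OAR10_29511510.1` == "A/G"
      ),
      count_where(
        snp_panel, .data$breed_category == "completely_horned",
        .data$sex == "female", .data$`OAR10_29511510.1` == "A/G"
      ),
      ag_freq("Ethiopian Menz"),
      ag_freq("Tibetan"),
      round_half_up(
        100 * mean(rb_males$`OAR10_29511510.1` == "G/G"), 1
      )
    )
  )

  out <- list(
    sample_sets = sample_sets,
    concordance = conc,
    snp_frequencies_breed = freq_breed,
    snp_frequencies_breed_sex = freq_breed_sex,
    headline = headline
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(sample_sets, file.path(out_dir, "sample_sets.tsv"), progress = FALSE)
    for (s in names(conc)) {
      readr::write_tsv(
        conc[[s]], file.path(out_dir, sprintf("concordance_%s.tsv", s)),
        progress = FALSE
      )
    }
    readr::write_tsv(freq_breed, file.path(out_dir, "snp_frequencies_breed.tsv"),
      progress = FALSE
    )
    readr::write_tsv(
      freq_breed_sex, file.path(out_dir, "snp_frequencies_breed_sex.tsv"),
      progress = FALSE
    )
    readr::write_tsv(headline, file.path(out_dir, "headline.tsv"), progress = FALSE)
    write_manifest(
      file.path(out_dir, "manifest.yaml"),
      inputs = list(fixtures = sprintf("table%d.csv", 1:4)),
      params = list(scur_policy = scur_policy)
    )
  }
  out
}
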