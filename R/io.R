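#' Read an animal panel from a delimited file
#'
#' A panel is a table with one genotyped/phenotyped sheep per row. The header
#' must declare `animal_id`, `breed`, `sex`, `phenotype`; every remaining
#' column is a marker whose cells hold slash-separated, order-insensitive
#' genotypes (e.g. `"anc/der"`, `"der/anc"`). Genotypes are normalised to a
#' canonical allele order; unparseable cells become missing with a logged
#' count; empty cells are missing without complaint.
#'
#' @param path Path to a CSV (default) or TSV file; the delimiter is inferred
#'   from the extension (`.tsv`/`.txt` read as tab-separated).
#' @param markers Optional marker table (as from [default_markers()]) used to
#'   validate alleles and fix canonical allele order per marker. Markers absent
#'   from the table fall back to alphabetical allele order.
#' @return A tibble with columns `animal_id`, `breed`, `sex`, `phenotype` and
#'   one character column per marker.
#' @export
read_panel <- function(path, markers = default_markers()) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("animal_id", "breed", "sex", "phenotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Panel is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  as_panel(raw, markers = markers)
}

# Validate and normalise an in-memory panel data frame.
as_panel <- function(df, markers = default_markers()) {
  df <- as_tibble(df)
  dup <- unique(df$animal_id[duplicated(df$animal_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated animal_id: ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(df$breed) | !nzchar(df$breed))) {
    abort("`breed` must be non-empty for every animal.")
  }
  bad_sex <- which(!df$sex %in% PANEL_SEXES)
  if (length(bad_sex) > 0) {
    abort(sprintf(
      "Unknown sex token '%s' in row %d (expected one of: %s).",
      df$sex[bad_sex[1]], bad_sex[1], paste(PANEL_SEXES, collapse = ", ")
    ))
  }
  bad_ph <- which(!df$phenotype %in% PHENOTYPES)
  if (length(bad_ph) > 0) {
    abort(sprintf(
      "Unknown phenotype token '%s' in row %d (expected one of: %s).",
      df$phenotype[bad_ph[1]], bad_ph[1], paste(PHENOTYPES, collapse = ", ")
    ))
  }
  marker_cols <- setdiff(names(df), c("animal_id", "breed", "sex", "phenotype", "breed_category"))
  n_bad <- 0L
  for (m in marker_cols) {
    al <- NULL
    if (!is.null(markers) && m %in% markers$name) {
      row <- markers[markers$name == m, ]
      al <- c(row$allele1, row$allele2)
    }
    g <- normalize_genotypes(df[[m]], alleles = al)
    n_bad <- n_bad + attr(g, "n_unparseable")
    attributes(g) <- NULL
    df[[m]] <- g
  }
  if (n_bad > 0) {
    warn(sprintf("%d unparseable genotype(s) set to missing.", n_bad),
      class = "hornscan_filter"
    )
  }
  df
}

#' Write an animal panel to CSV
#'
#' @param panel A panel tibble as returned by [read_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Construct a site-by-sample genotype matrix
#'
#' The central container of the selection scan: biallelic sites in rows,
#' allele dosages (0/1/2 copies of the alternate allele, NA = missing) in one
#' column per sample, plus case/control labels. Cases are the polled group.
#'
#' @param sites A data frame with columns `contig`, `pos` (1-based, strictly
#'   increasing), `ref`, `alt`, and one integer dosage column per sample.
#' @param case,control Character vectors naming the case and control sample
#'   columns.
#' @return A tibble of class `site_matrix` with attributes `case_samples` and
#'   `control_samples`.
#' @export
site_matrix <- function(sites, case, control) {
  sites <- as_tibble(sites)
  needed <- c("contig", "pos", "ref", "alt")
  if (!all(needed %in% names(sites))) {
    abort("`sites` needs columns contig, pos, ref, alt plus sample columns.")
  }
  samples <- c(case, control)
  if (length(case) < 1 || length(control) < 1) {
    abort("Need at least one case and one control sample.")
  }
  missing_s <- setdiff(samples, names(sites))
  if (length(missing_s) > 0) {
    abort(paste0("Sample column(s) not found: ", paste(missing_s, collapse = ", ")))
  }
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    abort("Site positions must be strictly increasing.")
  }
  for (s in samples) {
    v <- sites[[s]]
    if (!all(is.na(v) | v %in% 0:2)) {
      abort(sprintf("Sample '%s' has dosages outside {0, 1, 2, NA}.", s))
    }
    sites[[s]] <- as.integer(v)
  }
  out <- sites[, c(needed, samples)]
  attr(out, "case_samples") <- case
  attr(out, "control_samples") <- control
  class(out) <- c("site_matrix", class(out))
  out
}

case_samples <- function(sm) attr(sm, "case_samples")
control_samples <- function(sm) attr(sm, "control_samples")

# Rebuild site_matrix attributes after row-filtering operations.
rewrap_site_matrix <- function(sites, template) {
  site_matrix(as_tibble(as.data.frame(sites)),
    case = case_samples(template), control = control_samples(template)
  )
}

#' Read a site-by-sample genotype matrix
#'
#' Two plain-text layouts are supported: a TSV with columns
#' `contig`, `pos`, `ref`, `alt` followed by per-sample dosages (0/1/2, empty
#' or `NA` = missing), or a minimal VCF (CHROM/POS/REF/ALT plus GT fields;
#' `0/1`-style calls, phased or unphased). Multi-allelic sites are dropped
#' with a logged count.
#'
#' @param path Input file; files ending in `.vcf` are parsed as VCF.
#' @param case,control Sample names per group. For VCF input, defaults to no
#'   grouping being guessed: both must be given.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return A [site_matrix()].
#' @export
read_site_matrix <- function(path, case, control, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt)) || ncol(gt) == 0) abort("VCF contains no samples.")
    multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
    if (any(multi)) {
      inform_filter("multi-allelic sites", sum(multi))
      fix <- fix[!multi, , drop = FALSE]
      gt <- gt[!multi, , drop = FALSE]
    }
    dosage <- apply(gt, 2, function(col) {
      al <- strsplit(gsub("\\|", "/", col), "/", fixed = TRUE)
      vapply(al, function(a) {
        if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_integer_)
        sum(as.integer(a))
      }, integer(1))
    })
    dosage <- matrix(as.integer(dosage),
      nrow = nrow(fix),
      dimnames = list(NULL, colnames(gt))
    )
    sites <- tibble(
      contig = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    )
    sites <- dplyr::bind_cols(sites, as_tibble(dosage))
  } else {
    sites <- readr::read_tsv(path,
      col_types = readr::cols(
        contig = readr::col_character(), pos = readr::col_integer(),
        ref = readr::col_character(), alt = readr::col_character(),
        .default = readr::col_integer()
      ), progress = FALSE, na = c("", "NA", ".")
    )
    multi <- grepl(",", sites$alt)
    if (any(multi)) {
      inform_filter("multi-allelic sites", sum(multi))
      sites <- sites[!multi, , drop = FALSE]
    }
  }
  site_matrix(sites, case = case, control = control)
}

#' Write a site matrix as TSV
#'
#' @param sm A [site_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(sm, path) {
  readr::write_tsv(as_tibble(as.data.frame(sm)), path, progress = FALSE)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with the conventions used throughout this
#' package: sequences are plain named character vectors, read case-insensitively
#' and stored in upper case. Round-trips are identity on A/C/G/T/N sequences.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector (empty for an empty file).
#' @export
read_fasta <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) abort(paste0("No such file: ", path))
  if (info$size == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  dup <- unique(names(out)[duplicated(names(out))])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sequence names: ", paste(dup, collapse = ", ")))
  }
  out
}

#' @param sequences Named character vector of DNA sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("All sequences must be named.")
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(toupper(sequences)), path
  )
  invisible(path)
}

#' Read a breed-category configuration
#'
#' A YAML map from breed name to one of the horn-status categories
#' `completely_polled`, `completely_horned`, `sex_dependent`, `variable`.
#'
#' @param path YAML file path.
#' @return A tibble with columns `breed` and `breed_category`.
#' @export
read_breed_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) return(tibble(breed = character(0), breed_category = character(0)))
  cat <- unlist(cfg)
  bad <- setdiff(unique(cat), BREED_CATEGORIES)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown breed category: ", paste(bad, collapse = ", "),
      " (expected: ", paste(BREED_CATEGORIES, collapse = ", "), ")"
    ))
  }
  tibble(breed = names(cat), breed_category = unname(cat))
}

#' Write a run manifest
#'
#' Records inputs, parameters and the seed of a run next to its outputs, so
#' any output directory is self-describing and reruns are comparable.
#'
#' @param path Output YAML path.
#' @param inputs Named list or character vector of input descriptions.
#' @param params Named list of parameters.
#' @param seed Integer seed or NULL.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), params = list(), seed = NULL) {
  yaml::write_yaml(
    list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = inputs, params = params, seed = seed
    ),
    path
  )
  invisible(path)
}
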