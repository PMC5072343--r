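# Case/control windowed F_ST selection scan: MAF filter, case-major-allele
# frequency profiles, per-window Nei-style G_ST on window-mean frequencies,
# mean + k*SD threshold, and merged above-threshold windows as the called
# identity-by-descent interval(s).

# Per-site alternate-allele frequency over non-missing calls in `samples`.
alt_freq <- function(sm, samples) {
  mat <- as.matrix(as.data.frame(sm)[, samples, drop = FALSE])
  n_called <- rowSums(!is.na(mat))
  freq <- rowSums(mat, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0] <- NA_real_
  list(freq = freq, n_called = n_called)
}

#' Keep informative sites: minor allele frequency above a floor
#'
#' Pooled-sample MAF (cases + controls, non-missing calls) must exceed
#' `maf_min` for a site to be retained; sites with call rate below
#' `min_call_rate` are dropped first. Removal counts are logged as
#' structured messages.
#'
#' @param sm A [site_matrix()].
#' @param maf_min MAF floor; sites with MAF strictly greater are kept
#'   (default 0.05).
#' @param min_call_rate Minimum fraction of samples with a non-missing call.
#' @return A filtered [site_matrix()] (possibly with zero rows, with a
#'   warning).
#' @export
filter_informative <- function(sm, maf_min = 0.05, min_call_rate = 0.8) {
  samples <- c(case_samples(sm), control_samples(sm))
  af <- alt_freq(sm, samples)
  low_call <- af$n_called < min_call_rate * length(samples)
  if (any(low_call)) {
    inform_filter("sites below call-rate floor", sum(low_call))
  }
  maf <- pmin(af$freq, 1 - af$freq)
  keep <- !low_call & !is.na(maf) & maf > maf_min
  n_removed <- sum(!keep & !low_call)
  if (n_removed > 0) inform_filter("sites at or below MAF floor", n_removed)
  out <- rewrap_site_matrix(as.data.frame(sm)[keep, , drop = FALSE], sm)
  if (nrow(out) == 0) warn("No informative sites remain.", class = "hornscan_filter")
  out
}

#' Per-site case-major-allele frequency profile
#'
#' For each site, identifies the major allele among the cases (frequency >=
#' 0.5 in cases; an exact 50/50 tie resolves to the reference allele) and
#' reports the frequency of that same allele in cases and in controls. Sites
#' with no non-missing case call are dropped with a logged count.
#'
#' @param sm A [site_matrix()].
#' @return A tibble with columns `contig`, `pos`, `major_allele` (`"ref"` or
#'   `"alt"`), `freq_case`, `freq_control`.
#' @export
case_major_profile <- function(sm) {
  ca <- alt_freq(sm, case_samples(sm))
  co <- alt_freq(sm, control_samples(sm))
  drop <- is.na(ca$freq)
  if (any(drop)) inform_filter("sites with no case calls", sum(drop))
  major_is_alt <- ca$freq > 0.5 # tie (exactly 0.5) -> reference allele
  tibble(
    contig = sm$contig, pos = sm$pos,
    major_allele = ifelse(major_is_alt, "alt", "ref"),
    freq_case = ifelse(major_is_alt, ca$freq, 1 - ca$freq),
    freq_control = ifelse(major_is_alt, co$freq, 1 - co$freq)
  )[!drop, , drop = FALSE]
}

# Nei-style G_ST from two group mean frequencies of the same allele,
# with equal group weights; 0 when the pooled locus is monomorphic.
gst_from_freqs <- function(p_case, p_control) {
  p_bar <- (p_case + p_control) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  h_s <- (2 * p_case * (1 - p_case) + 2 * p_control * (1 - p_control)) / 2
  ifelse(h_t == 0, 0, (h_t - h_s) / h_t)
}

#' Sliding-window group frequencies and F_ST
#'
#' Windows are laid on a regular grid (`step` apart, `window_size` wide,
#' 1-based half-open) anchored at `region[1]` (or the first site). Within a
#' window, the case and control frequencies of the case-major allele are
#' averaged over sites, and F_ST is a Nei-style G_ST computed from those two
#' window-mean frequencies: with p-bar their average, H_T = 2*p*(1-p) at
#' p-bar, H_S the mean of the two within-group heterozygosities, and
#' F_ST = (H_T - H_S)/H_T (0 when H_T = 0). Windows without sites carry
#' `n_sites = 0` and `NA` statistics.
#'
#' @param profile A profile tibble from [case_major_profile()].
#' @param window_size Window width in bp (default 20000).
#' @param step Grid step in bp (default 5000; set `step = window_size` for
#'   non-overlapping windows).
#' @param region Optional length-2 vector anchoring and bounding the grid;
#'   defaults to the span of the profile.
#' @return A tibble with columns `start`, `end` (half-open), `n_sites`,
#'   `freq_case`, `freq_control`, `fst`.
#' @export
window_fst <- function(profile, window_size = 20000, step = 5000, region = NULL) {
  if (window_size <= 0) abort("`window_size` must be positive.")
  if (step <= 0) abort("`step` must be positive.")
  if (nrow(profile) == 0) abort("Empty profile.")
  region <- region %||% range(profile$pos)
  starts <- seq.int(region[1], max(region[1], region[2]), by = step)
  out <- purrr::map_dfr(starts, function(s) {
    e <- s + window_size
    in_w <- profile$pos >= s & profile$pos < e
    n <- sum(in_w)
    if (n == 0) {
      return(tibble(
        start = s, end = e, n_sites = 0L,
        freq_case = NA_real_, freq_control = NA_real_, fst = NA_real_
      ))
    }
    p_c <- mean(profile$freq_case[in_w])
    p_h <- mean(profile$freq_control[in_w])
    tibble(
      start = s, end = e, n_sites = n,
      freq_case = p_c, freq_control = p_h,
      fst = gst_from_freqs(p_c, p_h)
    )
  })
  out
}

# Population (n-divisor) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Call identity-by-descent intervals from windowed F_ST
#'
#' The threshold is mean + `k_sd` * SD of F_ST over non-empty windows
#' (population SD, n divisor); the called intervals are maximal unions of
#' overlapping or adjacent windows whose F_ST strictly exceeds it.
#'
#' @param windows A window tibble from [window_fst()].
#' @param k_sd SD multiplier (default 1).
#' @return A `scan_result` object: list with `windows`, `threshold`, `k_sd`
#'   and `ibd_intervals` (tibble of half-open `start`/`end`).
#' @export
call_ibd <- function(windows, k_sd = 1.0) {
  nonempty <- windows[windows$n_sites > 0, , drop = FALSE]
  if (nrow(nonempty) < 2) abort("Need at least 2 non-empty windows.")
  threshold <- mean(nonempty$fst) + k_sd * sd_pop(nonempty$fst)
  above <- nonempty[nonempty$fst > threshold, , drop = FALSE]
  ibd <- merge_intervals(above$start, above$end)
  structure(
    list(
      windows = windows, threshold = threshold, k_sd = k_sd,
      ibd_intervals = ibd
    ),
    class = "scan_result"
  )
}

# Merge half-open intervals that overlap or touch.
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Run the full selection scan
#'
#' Convenience pipeline: MAF filter, case-major profile, windowed F_ST,
#' threshold and IBD calling.
#'
#' @inheritParams filter_informative
#' @inheritParams window_fst
#' @inheritParams call_ibd
#' @return A `scan_result` (see [call_ibd()]).
#' @export
scan_selection <- function(sm, maf_min = 0.05, window_size = 20000,
                           step = 5000, k_sd = 1.0, region = NULL,
                           min_call_rate = 0.8) {
  sm <- filter_informative(sm, maf_min = maf_min, min_call_rate = min_call_rate)
  profile <- case_major_profile(sm)
  windows <- window_fst(profile, window_size = window_size, step = step, region = region)
  call_ibd(windows, k_sd = k_sd)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "Windowed F_ST scan: %d windows (%d with sites), threshold %.4f (mean + %g SD)\n",
    nrow(x$windows), sum(x$windows$n_sites > 0), x$threshold, x$k_sd
  ))
  if (nrow(x$ibd_intervals) == 0) {
    cat("No interval above threshold.\n")
  } else {
    cat("Called IBD interval(s):\n")
    print(x$ibd_intervals)
  }
  invisible(x)
}

#' Tidy a selection-scan result
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return The per-window tibble with an `above_threshold` flag.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  dplyr::mutate(x$windows, above_threshold = .data$fst > x$threshold)
}

#' One-row summary of a selection-scan result
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return A one-row tibble: threshold, k_sd, window counts, number of called
#'   intervals and total called span (bp).
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble(
    threshold = x$threshold, k_sd = x$k_sd,
    n_windows = nrow(x$windows),
    n_windows_nonempty = sum(x$windows$n_sites > 0),
    n_ibd_intervals = nrow(x$ibd_intervals),
    ibd_span = sum(x$ibd_intervals$end - x$ibd_intervals$start)
  )
}

#' Plot a selection-scan result
#'
#' Case and control mean frequencies of the case-major allele (black and
#' grey), the per-window F_ST curve, the calling threshold, and the called
#' interval(s) as shaded bands.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  w <- object$windows[object$windows$n_sites > 0, , drop = FALSE]
  w$mid <- (w$start + w$end) / 2
  long <- tidyr::pivot_longer(
    w[, c("mid", "freq_case", "freq_control", "fst")],
    cols = c("freq_case", "freq_control", "fst"),
    names_to = "series", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value, colour = .data$series))
  if (nrow(object$ibd_intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$ibd_intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      freq_case = "black", freq_control = "grey60", fst = "red"
    )) +
    ggplot2::labs(
      x = "position (bp)", y = "window mean frequency / F_ST",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Write scan outputs: per-window TSV and called intervals as BED
#'
#' The BED file is 0-based half-open, converted from the internal 1-based
#' half-open windows. A run manifest is written alongside.
#'
#' @param result A `scan_result`.
#' @param prefix Output path prefix; writes `<prefix>_windows.tsv`,
#'   `<prefix>_ibd.bed` and `<prefix>_manifest.yaml`.
#' @param contig Contig name used in the BED file.
#' @param seed Seed recorded in the manifest (if the input was simulated).
#' @return Invisibly, the paths written.
#' @export
write_scan_outputs <- function(result, prefix, contig = "OAR10", seed = NULL) {
  windows_path <- paste0(prefix, "_windows.tsv")
  bed_path <- paste0(prefix, "_ibd.bed")
  manifest_path <- paste0(prefix, "_manifest.yaml")
  readr::write_tsv(result$windows, windows_path, progress = FALSE)
  bed <- tibble(
    chrom = contig,
    start = result$ibd_intervals$start - 1L, # 1-based half-open -> BED
    end = result$ibd_intervals$end - 1L
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  write_manifest(
    manifest_path,
    inputs = list(windows = nrow(result$windows)),
    params = list(k_sd = result$k_sd, threshold = result$threshold),
    seed = seed
  )
  invisible(c(windows_path, bed_path, manifest_path))
}
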