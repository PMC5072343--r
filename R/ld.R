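# Two-locus linkage disequilibrium from unphased diploid genotypes:
# EM haplotype-frequency estimation (the only ambiguous class is the double
# heterozygote), then D, D' and r2.

#' Cross-tabulate two markers into a 3x3 dosage table
#'
#' Rows index the dosage (0/1/2 copies of the second allele) at `marker1`,
#' columns at `marker2`; animals missing either genotype are dropped.
#'
#' @param panel A panel tibble.
#' @param marker1,marker2 Marker column names.
#' @param markers Marker table fixing allele order (see [default_markers()]).
#' @return A 3x3 integer matrix.
#' @export
two_locus_counts <- function(panel, marker1, marker2, markers = default_markers()) {
  for (m in c(marker1, marker2)) {
    if (!m %in% names(panel)) abort(sprintf("Marker '%s' not in panel.", m))
  }
  second_allele <- function(m) {
    if (m %in% markers$name) {
      markers$allele2[markers$name == m]
    } else {
      al <- sort(unique(unlist(strsplit(stats::na.omit(panel[[m]]), "/"))))
      if (length(al) > 2) abort(sprintf("Marker '%s' is not biallelic.", m))
      al[length(al)]
    }
  }
  d1 <- allele_dosage(panel[[marker1]], second_allele(marker1))
  d2 <- allele_dosage(panel[[marker2]], second_allele(marker2))
  keep <- !is.na(d1) & !is.na(d2)
  counts <- matrix(0L, 3, 3, dimnames = list(dosage1 = 0:2, dosage2 = 0:2))
  for (i in which(keep)) {
    counts[d1[i] + 1L, d2[i] + 1L] <- counts[d1[i] + 1L, d2[i] + 1L] + 1L
  }
  counts
}

# Genotype-class probabilities under HWE given haplotype frequencies
# h = c(p_ab, p_aB, p_Ab, p_AB) indexed by [dosage1][dosage2].
genotype_probs <- function(h11, h12, h21, h22) {
  # haplotype hXY: X = allele at locus 1 (1 = first/ref-like, 2 = second),
  # Y = allele at locus 2. Dosage counts copies of the second allele.
  p <- matrix(0, 3, 3)
  p[1, 1] <- h11^2
  p[1, 2] <- 2 * h11 * h12
  p[1, 3] <- h12^2
  p[2, 1] <- 2 * h11 * h21
  p[2, 2] <- 2 * h11 * h22 + 2 * h12 * h21
  p[2, 3] <- 2 * h12 * h22
  p[3, 1] <- h21^2
  p[3, 2] <- 2 * h21 * h22
  p[3, 3] <- h22^2
  p
}

ld_loglik <- function(counts, h11, h12, h21, h22) {
  p <- genotype_probs(h11, h12, h21, h22)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

#' EM haplotype-frequency estimation from a two-locus genotype table
#'
#' Estimates the four haplotype frequencies from unphased diploid counts.
#' All genotype classes except the double heterozygote have known phase; the
#' E-step splits the double heterozygotes between the two phase
#' configurations in proportion to the current haplotype-frequency products,
#' and the M-step renormalises expected haplotype counts. Because linkage
#' equilibrium is an exact fixed point of the EM map for some tables (and the
#' likelihood can be bimodal in the one free haplotype frequency), the fit is
#' run from three starts - linkage equilibrium and the two near-boundary
#' phase configurations - and the run with the highest final log-likelihood
#' is returned. Within a run the log-likelihood is non-decreasing across
#' iterations.
#'
#' @param counts A 3x3 matrix of genotype counts (dosages 0/1/2 of each
#'   marker's second allele), as from [two_locus_counts()].
#' @param tol Convergence tolerance on the maximum absolute frequency change.
#' @param max_iter Iteration cap.
#' @return An object of class `ld_fit`: haplotype frequencies (`hap` of the
#'   form `11`, `12`, `21`, `22` for first/second allele at locus 1 then
#'   locus 2), allele frequencies, log-likelihood and iteration count.
#' @export
em_haplotypes <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) abort("Empty genotype table.")
  # Allele frequencies (of each locus's second allele) are fixed by the data.
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    abort("LD undefined: at least one locus is monomorphic in this sample.")
  }
  # Feasible range of the one free parameter, the 22-haplotype frequency.
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  starts <- unique(pmin(pmax(
    c(pA * pB, lo + 0.01 * (hi - lo), hi - 0.01 * (hi - lo)), lo
  ), hi))
  runs <- lapply(starts, function(p22) {
    em_run(counts, pA, pB, p22, tol = tol, max_iter = max_iter)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  h <- best$h
  structure(
    list(
      haplotypes = tibble(
        hap = c("11", "12", "21", "22"),
        freq = c(h[1, 1], h[1, 2], h[2, 1], h[2, 2])
      ),
      pA = pA, pB = pB, loglik = best$loglik, iterations = best$iterations,
      n = n, converged = best$converged
    ),
    class = "ld_fit"
  )
}

# One EM run from a given initial 22-haplotype frequency.
em_run <- function(counts, pA, pB, p22_init, tol, max_iter) {
  # h[x, y]: haplotype with allele x at locus 1 and y at locus 2
  # (1 = first allele, 2 = second allele).
  h <- matrix(
    c(1 - pA - pB + p22_init, pB - p22_init, pA - p22_init, p22_init),
    2, 2,
    byrow = TRUE
  )
  ll <- ld_loglik(counts, h[1, 1], h[1, 2], h[2, 1], h[2, 2])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # Expected haplotype counts; every class but the double het is unambiguous.
    e <- matrix(0, 2, 2)
    add <- function(x, y, k) e[x, y] <<- e[x, y] + k
    add(1, 1, 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
    add(1, 2, 2 * counts[1, 3] + counts[1, 2] + counts[2, 3])
    add(2, 1, 2 * counts[3, 1] + counts[2, 1] + counts[3, 2])
    add(2, 2, 2 * counts[3, 3] + counts[2, 3] + counts[3, 2])
    dh <- counts[2, 2]
    if (dh > 0) {
      cis <- h[1, 1] * h[2, 2]
      trans <- h[1, 2] * h[2, 1]
      w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
      add(1, 1, dh * w)
      add(2, 2, dh * w)
      add(1, 2, dh * (1 - w))
      add(2, 1, dh * (1 - w))
    }
    h_new <- e / sum(e)
    delta <- max(abs(h_new - h))
    h <- h_new
    ll <- ld_loglik(counts, h[1, 1], h[1, 2], h[2, 1], h[2, 2])
    if (delta < tol || iter >= max_iter) break
  }
  list(h = h, loglik = ll, iterations = iter, converged = iter < max_iter)
}

#' @export
print.ld_fit <- function(x, ...) {
  cat(sprintf(
    "EM haplotype fit (n = %d, %d iterations, logLik = %.4f)\n",
    x$n, x$iterations, x$loglik
  ))
  print(x$haplotypes)
  invisible(x)
}

#' Tidy an EM haplotype fit
#'
#' @param x An `ld_fit`.
#' @param ... Unused.
#' @return The haplotype-frequency tibble.
#' @method tidy ld_fit
#' @export
tidy.ld_fit <- function(x, ...) x$haplotypes

#' One-row summary of an EM haplotype fit
#'
#' @param x An `ld_fit`.
#' @param ... Unused.
#' @return A one-row tibble: n, allele frequencies, logLik, iterations,
#'   convergence flag.
#' @method glance ld_fit
#' @export
glance.ld_fit <- function(x, ...) {
  tibble(
    n = x$n, pA = x$pA, pB = x$pB, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' D = p22 - pA*pB (the coefficient for the two second alleles), D' = D
#' scaled by its sign-dependent maximum, and r2 = D^2 / (pA(1-pA) pB(1-pB)).
#'
#' @param fit An `ld_fit` from [em_haplotypes()], or a named numeric vector
#'   of four haplotype frequencies (`11`, `12`, `21`, `22`).
#' @return A one-row tibble: `pA`, `pB`, `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(fit) {
  if (inherits(fit, "ld_fit")) {
    h <- setNames(fit$haplotypes$freq, fit$haplotypes$hap)
  } else {
    h <- fit[c("11", "12", "21", "22")]
    if (anyNA(h)) abort("Need haplotype frequencies named 11, 12, 21, 22.")
    h <- h / sum(h)
  }
  pA <- h[["21"]] + h[["22"]]
  pB <- h[["12"]] + h[["22"]]
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    abort("LD undefined: monomorphic locus.")
  }
  d <- h[["22"]] - pA * pB
  d_max <- if (d >= 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  tibble(
    pA = pA, pB = pB, D = d,
    D_prime = if (d == 0) 0 else d / d_max,
    r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB))
  )
}

#' Per-group r2 between two markers, with a ratio of two named groups
#'
#' Estimates haplotype frequencies by EM within each group of a panel and
#' reports D, D' and r2 per group; optionally the ratio of r2 between two
#' named groups (rounded to `digits`, as in printed reports). Groups in which
#' either locus is monomorphic are skipped with a warning; a near-zero
#' denominator r2 is floored at `eps` with a warning.
#'
#' @param panel A panel tibble.
#' @param marker1,marker2 Marker column names.
#' @param group Column name defining the grouping (default `breed_category`).
#' @param ratio_groups Optional length-2 character vector: ratio =
#'   r2(first) / r2(second).
#' @param digits Rounding for the reported ratio.
#' @param eps Denominator floor for the ratio.
#' @param markers Marker table fixing allele order.
#' @return A tibble (group, n, pA, pB, D, D_prime, r2) with attribute
#'   `r2_ratio` when `ratio_groups` is given.
#' @export
grouped_r2 <- function(panel, marker1, marker2, group = "breed_category",
                       ratio_groups = NULL, digits = 2, eps = 1e-12,
                       markers = default_markers()) {
  if (!group %in% names(panel)) abort(sprintf("No grouping column '%s'.", group))
  groups <- unique(panel[[group]])
  rows <- purrr::map(groups, function(g) {
    sub <- panel[panel[[group]] == g, , drop = FALSE]
    fit <- tryCatch(
      em_haplotypes(two_locus_counts(sub, marker1, marker2, markers = markers)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(sprintf("Group '%s' skipped: LD undefined (monomorphic locus).", g),
        class = "hornscan_filter"
      )
      return(NULL)
    }
    dplyr::bind_cols(tibble(group = g, n = fit$n), ld_stats(fit))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(ratio_groups)) {
    stopifnot(length(ratio_groups) == 2)
    num <- out$r2[match(ratio_groups[1], out$group)]
    den <- out$r2[match(ratio_groups[2], out$group)]
    if (is.na(num) || is.na(den)) abort("Ratio group not present in results.")
    if (den < eps) {
      warn("Denominator r2 below eps; ratio floored.", class = "hornscan_filter")
      den <- eps
    }
    attr(out, "r2_ratio") <- r2_ratio(num, den, digits = digits)
  }
  out
}

#' Ratio of two r2 values, report-style
#'
#' The rounded quotient used when comparing linkage strength between sample
#' groups (e.g. fixed-horn-status vs variable breeds).
#'
#' @param r2_num,r2_den Numerator and denominator r2.
#' @param digits Decimal places (half-up rounding).
#' @return A number.
#' @export
#' @examples
#' r2_ratio(0.635, 0.194)
r2_ratio <- function(r2_num, r2_den, digits = 2) {
  round_half_up(r2_num / r2_den, digits)
}
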