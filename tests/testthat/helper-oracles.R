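# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (loops, enumeration, grid search) so they share no code
# path with the implementation they check.

# Brute-force window statistics: explicit loops over sites, explicit
# heterozygosity arithmetic.
brute_window_stats <- function(profile, starts, window_size) {
  out <- data.frame(
    start = starts, n_sites = NA_integer_,
    freq_case = NA_real_, freq_control = NA_real_, fst = NA_real_
  )
  for (k in seq_along(starts)) {
    s <- starts[k]
    pc <- c()
    ph <- c()
    for (i in seq_len(nrow(profile))) {
      if (profile$pos[i] >= s && profile$pos[i] < s + window_size) {
        pc <- c(pc, profile$freq_case[i])
        ph <- c(ph, profile$freq_control[i])
      }
    }
    out$n_sites[k] <- length(pc)
    if (length(pc) > 0) {
      mc <- sum(pc) / length(pc)
      mh <- sum(ph) / length(ph)
      pbar <- (mc + mh) / 2
      ht <- 2 * pbar * (1 - pbar)
      hs <- (2 * mc * (1 - mc) + 2 * mh * (1 - mh)) / 2
      out$freq_case[k] <- mc
      out$freq_control[k] <- mh
      out$fst[k] <- if (ht == 0) 0 else (ht - hs) / ht
    }
  }
  out
}

# Multinomial log-likelihood of a 3x3 dosage table given four haplotype
# frequencies, by explicit enumeration of ordered haplotype pairs.
hap_table_loglik <- function(counts, p11, p12, p21, p22) {
  haps <- list(
    c(0, 0, p11), c(0, 1, p12), c(1, 0, p21), c(1, 1, p22)
  )
  ll <- 0
  for (d1 in 0:2) {
    for (d2 in 0:2) {
      if (counts[d1 + 1, d2 + 1] == 0) next
      prob <- 0
      for (h1 in haps) {
        for (h2 in haps) {
          if (h1[1] + h2[1] == d1 && h1[2] + h2[2] == d2) {
            prob <- prob + h1[3] * h2[3]
          }
        }
      }
      ll <- ll + counts[d1 + 1, d2 + 1] * log(prob)
    }
  }
  ll
}

# Grid-search maximum-likelihood haplotype frequencies. The allele
# frequencies are fixed by the genotype margins, so the likelihood has a
# single free parameter: the frequency of the double-second-allele haplotype.
# A second, finer pass around the coarse optimum removes grid-resolution
# error from the comparison.
grid_ml_haplotypes <- function(counts, step = 1e-3, refine = 100) {
  n <- sum(counts)
  pA <- 0
  pB <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      pA <- pA + counts[i, j] * (i - 1)
      pB <- pB + counts[i, j] * (j - 1)
    }
  }
  pA <- pA / (2 * n)
  pB <- pB / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  search <- function(grid) {
    best <- NULL
    best_ll <- -Inf
    for (p22 in grid) {
      ll <- hap_table_loglik(
        counts,
        max(0, 1 - pA - pB + p22), max(0, pB - p22), max(0, pA - p22), p22
      )
      if (!is.nan(ll) && ll > best_ll) {
        best_ll <- ll
        best <- p22
      }
    }
    list(p22 = best, loglik = best_ll)
  }
  coarse <- search(unique(c(seq(lo, hi, by = step), hi)))
  best <- coarse
  if (refine > 1) {
    fine_grid <- seq(
      max(lo, coarse$p22 - step), min(hi, coarse$p22 + step),
      by = step / refine
    )
    best <- search(unique(c(fine_grid, coarse$p22)))
  }
  d <- best$p22 - pA * pB
  list(
    p22 = best$p22, pA = pA, pB = pB, loglik = best$loglik,
    r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB))
  )
}

# Random two-locus genotype table: sample true haplotype frequencies, draw
# 2n haplotypes, pair them into n diploids. Redraws until both loci are
# polymorphic.
random_counts_table <- function(n) {
  repeat {
    f <- rgamma(4, 1)
    f <- f / sum(f)
    haps <- sample(1:4, 2 * n, replace = TRUE, prob = f)
    a1 <- c(0, 0, 1, 1)[haps]
    a2 <- c(0, 1, 0, 1)[haps]
    d1 <- a1[seq(1, 2 * n, 2)] + a1[seq(2, 2 * n, 2)]
    d2 <- a2[seq(1, 2 * n, 2)] + a2[seq(2, 2 * n, 2)]
    if (length(unique(d1)) == 1 || length(unique(d2)) == 1) next
    if (sum(d1) %in% c(0, 2 * n) || sum(d2) %in% c(0, 2 * n)) next
    counts <- matrix(0L, 3, 3)
    for (i in seq_len(n)) {
      counts[d1[i] + 1, d2[i] + 1] <- counts[d1[i] + 1, d2[i] + 1] + 1L
    }
    return(counts)
  }
}

# Small hand-rolled site matrix: dosage rows given per site.
tiny_site_matrix <- function(dosages, pos = NULL, n_case = NULL) {
  dosages <- as.matrix(dosages)
  n <- ncol(dosages)
  n_case <- n_case %||% (n %/% 2)
  pos <- pos %||% seq(100, by = 100, length.out = nrow(dosages))
  samples <- sprintf("s%02d", seq_len(n))
  df <- tibble::tibble(
    contig = "chr1", pos = as.integer(pos),
    ref = "A", alt = "G"
  )
  for (i in seq_len(n)) df[[samples[i]]] <- as.integer(dosages[, i])
  site_matrix(df,
    case = samples[seq_len(n_case)],
    control = samples[(n_case + 1):n]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_silent_filter <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}
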