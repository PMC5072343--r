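# EM haplotype-frequency estimation and D/D'/r2.

counts_from <- function(...) matrix(c(...), 3, 3, byrow = TRUE)

test_that("phase-unambiguous tables are solved exactly", {
  cts <- counts_from(
    4, 0, 0,
    0, 0, 0,
    0, 0, 4
  )
  fit <- em_haplotypes(cts)
  h <- setNames(fit$haplotypes$freq, fit$haplotypes$hap)
  expect_equal(unname(h[c("11", "22")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(h[c("12", "21")]), c(0, 0), tolerance = 1e-9)
})

test_that("the symmetric double-het table matches the grid-search ML oracle", {
  cts <- counts_from(
    4, 0, 0,
    0, 2, 0,
    0, 0, 4
  )
  fit <- em_haplotypes(cts)
  oracle <- grid_ml_haplotypes(cts, step = 1e-3)
  h22 <- fit$haplotypes$freq[fit$haplotypes$hap == "22"]
  expect_lt(abs(h22 - oracle$p22), 1e-3)
  expect_lt(abs(ld_stats(fit)$r2 - oracle$r2), 1e-3)
})

test_that("independent loci give D near zero under sampling noise", {
  withr::with_seed(31, {
    pA <- 0.3
    pB <- 0.6
    d1 <- rbinom(400, 2, pA)
    d2 <- rbinom(400, 2, pB)
  })
  cts <- matrix(0L, 3, 3)
  for (i in seq_along(d1)) {
    cts[d1[i] + 1, d2[i] + 1] <- cts[d1[i] + 1, d2[i] + 1] + 1L
  }
  fit <- em_haplotypes(cts)
  se <- sqrt(pA * (1 - pA) * pB * (1 - pB) / 400)
  expect_lt(abs(ld_stats(fit)$D), 2 * se)
})

test_that("monomorphic loci are refused", {
  cts <- counts_from(
    4, 2, 1,
    0, 0, 0,
    0, 0, 0
  )
  expect_error(em_haplotypes(cts), "monomorphic")
})

test_that("ld statistics match their closed forms", {
  complete <- ld_stats(c("11" = 0.5, "12" = 0, "21" = 0, "22" = 0.5))
  expect_equal(complete$D, 0.25)
  expect_equal(complete$D_prime, 1)
  expect_equal(complete$r2, 1)

  equilibrium <- ld_stats(c("11" = 0.35, "12" = 0.35, "21" = 0.15, "22" = 0.15))
  expect_equal(equilibrium$D, 0, tolerance = 1e-12)
  expect_equal(equilibrium$r2, 0, tolerance = 1e-12)

  partial <- ld_stats(c("11" = 0.4, "12" = 0.1, "21" = 0.1, "22" = 0.4))
  expect_equal(partial$D, 0.15)
  expect_equal(partial$r2, 0.36)

  expect_error(ld_stats(c("11" = 0.5, "12" = 0.5, "21" = 0, "22" = 0)), "monomorphic")
})

test_that("estimates are invariant under allele-label swaps", {
  withr::with_seed(17, cts <- random_counts_table(25))
  fit <- em_haplotypes(cts)
  s <- ld_stats(fit)
  # swap alleles at locus 1: reverse the row order
  fit_swap <- em_haplotypes(cts[3:1, ])
  s_swap <- ld_stats(fit_swap)
  expect_equal(s$r2, s_swap$r2, tolerance = 1e-8)
  expect_equal(abs(s$D_prime), abs(s_swap$D_prime), tolerance = 1e-8)
  expect_equal(s$D, -s_swap$D, tolerance = 1e-8)
})

test_that("the EM log-likelihood never decreases across iterations", {
  withr::with_seed(23, tables <- replicate(5, random_counts_table(20), simplify = FALSE))
  for (cts in tables) {
    fit2 <- em_haplotypes(cts, max_iter = 2)
    fit5 <- em_haplotypes(cts, max_iter = 5)
    fit_full <- em_haplotypes(cts)
    expect_lte(fit2$loglik, fit5$loglik + 1e-10)
    expect_lte(fit5$loglik, fit_full$loglik + 1e-10)
  }
})

test_that("grouped r2 reports per group and guards the ratio", {
  panel <- dplyr::bind_rows(
    synth_breed_panel("variable", 40, 40, seed = 2),
    synth_breed_panel("sex_dependent", 40, 40, seed = 3)
  )
  # second marker in strong LD with the first, with some recombinants
  withr::with_seed(6, {
    flip <- runif(nrow(panel)) < 0.2
    panel$rs421908034 <- ifelse(
      xor(panel$RXFP2_ins == "der/der", flip),
      "A/A", ifelse(panel$RXFP2_ins == "anc/der", "A/G", "G/G")
    )
  })
  res <- grouped_r2(panel, "RXFP2_ins", "rs421908034",
    ratio_groups = c("variable", "sex_dependent")
  )
  expect_equal(nrow(res), 2L)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_equal(
    attr(res, "r2_ratio"),
    round(res$r2[res$group == "variable"] / res$r2[res$group == "sex_dependent"], 2),
    tolerance = 0.01
  )

  expect_equal(r2_ratio(0.42, 0.42), 1.00) # identical groups: ratio 1
})

test_that("a monomorphic group is skipped with a warning, not an error", {
  panel <- dplyr::bind_rows(
    synth_breed_panel("completely_horned", 10, 10, seed = 4), # anc/anc only
    synth_breed_panel("variable", 30, 30, seed = 5)
  )
  panel$rs421908034 <- ifelse(panel$RXFP2_ins == "der/der", "A/A",
    ifelse(panel$RXFP2_ins == "anc/der", "A/G", "G/G")
  )
  panel$rs421908034[c(1, 25)] <- "A/G" # keep marker 2 polymorphic overall
  expect_warning(
    res <- grouped_r2(panel, "RXFP2_ins", "rs421908034"),
    "skipped"
  )
  expect_equal(res$group, "variable")
})
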