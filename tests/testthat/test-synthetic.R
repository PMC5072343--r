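# The generators define the study conditions every stage is tested under:
# seed determinism, the fixed case haplotype, the published assay geometry.

test_that("scan simulator is deterministic and fixes cases inside the segment", {
  a <- simulate_scan_data(seed = 7)
  b <- simulate_scan_data(seed = 7)
  expect_identical(a, b)

  inside <- a$pos >= 29436000 & a$pos <= 29476000
  expect_gt(sum(inside), 0)
  case_cols <- as.matrix(as.data.frame(a)[inside, attr(a, "case_samples")])
  expect_true(all(case_cols == 2L))

  no_ibd <- simulate_scan_data(ibd_interval = NULL, seed = 7)
  expect_true(all(vapply(
    attr(no_ibd, "case_samples"),
    function(s) any(no_ibd[[s]] != 2L), logical(1)
  )))
})

test_that("control allele frequencies converge to the background Beta mean", {
  sm <- simulate_scan_data(
    n_case = 2, n_control = 500, ibd_interval = NULL, seed = 9
  )
  ctrl <- as.matrix(as.data.frame(sm)[, attr(sm, "control_samples")])
  site_freq <- rowMeans(ctrl) / 2
  se <- sd(site_freq) / sqrt(length(site_freq))
  expect_lt(abs(mean(site_freq) - 0.5), 3 * se)
})

test_that("simulator validates its parameters", {
  expect_error(simulate_scan_data(n_case = 1), "at least 2")
  expect_error(
    simulate_scan_data(ibd_interval = c(1, 2), region = c(10, 20)),
    "inside"
  )
})

test_that("allele templates realise the published amplicon geometry", {
  fx <- synth_allele_sequences(seed = 1)
  expect_identical(fx, synth_allele_sequences(seed = 1))

  der_len <- pcr(fx$sequences[["der"]], fx$primers[["F1"]], fx$primers[["R1"]])$length
  anc_len <- pcr(fx$sequences[["anc"]], fx$primers[["F1"]], fx$primers[["R1"]])$length
  expect_equal(der_len, anc_len + 1780)
  expect_equal(der_len, 2286)

  # the insertion-internal reverse primer has no site on the ancestral allele
  expect_equal(nrow(find_sites(fx$sequences[["anc"]], fx$primers[["R2"]])), 0)

  no_ins <- synth_allele_sequences(insertion_length = 0, seed = 1)
  expect_identical(no_ins$sequences[["anc"]], no_ins$sequences[["der"]])

  expect_error(
    synth_allele_sequences(f1r2_product = 30, seed = 1),
    "geometry|exceed"
  )
})

test_that("exon-14 RFLP templates digest to the published patterns", {
  for (seed in 1:3) {
    a <- synth_rflp_fixture("A", seed = seed)
    g <- synth_rflp_fixture("G", seed = seed)
    expect_equal(digest(a$sequence, "TCNGA:3"), c(726L, 28L))
    expect_equal(digest(g$sequence, "TCNGA:3"), c(429L, 297L, 28L))
    expect_equal(sum(digest(g$sequence, "TCNGA:3")), 754L)
    expect_equal(nchar(a$sequence), 754L)
  }
})

test_that("ACRS templates digest to the published patterns", {
  a <- synth_acrs_fixture("A", seed = 2)
  g <- synth_acrs_fixture("G", seed = 2)
  expect_equal(digest(a$sequence, "TCNGA:3"), 104L)
  expect_equal(digest(g$sequence, "TCNGA:3"), c(82L, 22L))
  # the published primer pair brackets the product
  expect_equal(pcr(g$sequence, g$forward, g$reverse)$length, 104L)
})

test_that("breed panels follow the model exactly at zero discordance", {
  horned <- synth_breed_panel("completely_horned", 20, 20, seed = 3)
  expect_true(all(horned$RXFP2_ins == "anc/anc"))
  expect_true(all(horned$phenotype == "horned"))

  for (cat in c(
    "completely_polled", "completely_horned", "sex_dependent", "variable"
  )) {
    for (policy in c("intermediate", "horned", "polled")) {
      panel <- synth_breed_panel(cat, 25, 25, discordance_rate = 0, seed = 11)
      tab <- suppressWarnings(concordance(panel, scur_policy = policy))
      expect_equal(tab$discordant[tab$breed == "(all)"], 0L)
    }
  }
})

test_that("observed discordance tracks the requested rate", {
  panel <- synth_breed_panel("variable", 100, 100, discordance_rate = 0.5, seed = 5)
  tab <- concordance(panel)
  disc <- tab$discordant[tab$breed == "(all)"]
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(disc, bounds[1])
  expect_lte(disc, bounds[2])
  expect_identical(
    panel, synth_breed_panel("variable", 100, 100, discordance_rate = 0.5, seed = 5)
  )
})
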