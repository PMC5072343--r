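# In-silico PCR, restriction digestion and fragment-pattern genotype calls.

test_that("primer site search is exact and strand-aware", {
  expect_equal(nrow(find_sites("ACGTACGTACGTACGT", "AAAAAAAAAA")), 0L)

  primer <- "ACGTTGCAAC" # template equal to the primer: one hit at 1
  hits <- find_sites(primer, primer)
  expect_equal(hits$position[hits$strand == "+"], 1L)

  pal <- "GAATTCGAATTC" # self reverse-complementary: one hit per strand
  hits_pal <- find_sites(pal, pal)
  expect_setequal(hits_pal$strand, c("-", "+"))
  expect_equal(hits_pal$position, c(1L, 1L))

  expect_error(find_sites("ACGT", "ACG"), "at least 10")
})

test_that("pcr reports every forward/reverse pairing within the size cap", {
  fx <- synth_allele_sequences(seed = 2)
  der <- pcr(fx$sequences[["der"]], fx$primers[["F1"]], fx$primers[["R1"]])
  expect_equal(der$length, 2286L)
  anc <- pcr(fx$sequences[["anc"]], fx$primers[["F1"]], fx$primers[["R1"]])
  expect_equal(anc$length, 506L)
  expect_equal(
    nrow(pcr(fx$sequences[["anc"]], fx$primers[["F1"]], fx$primers[["R2"]])), 0L
  )
  # size cap suppresses the long product
  capped <- pcr(fx$sequences[["der"]], fx$primers[["F1"]], fx$primers[["R1"]],
    max_len = 1000
  )
  expect_equal(nrow(capped), 0L)
})

test_that("pcr length multisets are strand-symmetric", {
  fx <- synth_allele_sequences(seed = 13)
  tmpl <- fx$sequences[["der"]]
  fwd <- pcr(tmpl, fx$primers[["F1"]], fx$primers[["R1"]])$length
  rc <- pcr(revcomp(tmpl), fx$primers[["R1"]], fx$primers[["F1"]])$length
  expect_equal(sort(fwd), sort(rc))
})

test_that("multiplex fragment patterns call all three genotypes", {
  fx <- synth_allele_sequences(seed = 3)
  anc <- fx$sequences[["anc"]]
  der <- fx$sequences[["der"]]
  hom_der <- multiplex_genotype(c(der, der), fx$primers)
  expect_equal(hom_der$genotype, "der/der")
  expect_setequal(hom_der$fragments, c(2286L, 389L, 676L))

  hom_anc <- multiplex_genotype(c(anc, anc), fx$primers)
  expect_equal(hom_anc$genotype, "anc/anc")
  expect_equal(hom_anc$fragments, 506L)

  het <- multiplex_genotype(c(anc, der), fx$primers)
  expect_equal(het$genotype, "anc/der")

  none <- multiplex_genotype("ACGTACGTACGTACGTACGTACGT", fx$primers)
  expect_equal(none$genotype, "uncallable")
})

test_that("multiplex genotyping recovers the generating genotype across seeds", {
  for (seed in 1:5) {
    fx <- synth_allele_sequences(seed = seed)
    anc <- fx$sequences[["anc"]]
    der <- fx$sequences[["der"]]
    expect_equal(multiplex_genotype(c(anc, anc), fx$primers)$genotype, "anc/anc")
    expect_equal(multiplex_genotype(c(anc, der), fx$primers)$genotype, "anc/der")
    expect_equal(multiplex_genotype(c(der, der), fx$primers)$genotype, "der/der")
  }
})

test_that("digestion cuts at IUPAC sites and conserves total length", {
  expect_equal(digest("AAATCAGAAAA", "TCNGA:3"), c(6L, 5L))
  expect_equal(digest("ACGTACGTACGT", "TCNGA:3"), 12L) # no motif: full length

  withr::with_seed(19, {
    for (i in 1:10) {
      seqlen <- sample(50:400, 1)
      s <- paste(sample(c("A", "C", "G", "T"), seqlen, TRUE), collapse = "")
      frags <- digest(s, "TCNGA:3")
      expect_equal(sum(frags), seqlen)
      expect_equal(frags, sort(frags, decreasing = TRUE))
    }
  })
})

test_that("non-palindromic patterns are matched on both strands", {
  enz <- restriction_enzyme("toy", "GACGC", 2)
  # GCGTC is the reverse complement: a minus-strand site
  expect_equal(digest("AAAGCGTCAAAA", enz), c(6L, 6L)) # mirrored cut offset
  expect_equal(digest("AAAGACGCAAAA", enz), c(7L, 5L))
})

test_that("fragment patterns call RFLP genotypes, with optional gel floor", {
  patterns <- list(A = c(104), G = c(82, 22))
  expect_equal(rflp_call(c(104), patterns), "A/A")
  expect_equal(rflp_call(c(104, 82, 22), patterns), "A/G")
  expect_equal(rflp_call(c(82, 22), patterns), "G/G")
  expect_equal(rflp_call(c(90), patterns), "uncallable")

  # with a 25-bp detection floor the 22-bp band is invisible on both sides
  expect_equal(rflp_call(c(82), patterns, min_fragment = 25), "G/G")

  exon14 <- list(A = c(726, 28), G = c(429, 297, 28))
  g <- synth_rflp_fixture("G", seed = 21)
  expect_equal(rflp_call(digest(g$sequence, "TCNGA:3"), exon14), "G/G")
  a <- synth_rflp_fixture("A", seed = 21)
  expect_equal(rflp_call(digest(a$sequence, "TCNGA:3"), exon14), "A/A")
  expect_equal(rflp_call(c(726, 429, 297, 28), exon14), "A/G")
})
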