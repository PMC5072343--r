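# Windowed F_ST selection scan: filtering, frequency profiles, the G_ST
# estimator, threshold calling and interval merging.

test_that("MAF filter keeps sites strictly above the floor, pooled over groups", {
  # 24 samples: site 1 monomorphic, site 2 has 3/48 alternate alleles
  d <- rbind(rep(0L, 24), c(1L, 1L, 1L, rep(0L, 21)))
  sm <- tiny_site_matrix(d)
  kept <- expect_silent_filter(filter_informative(sm, maf_min = 0.05))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos, 200L) # MAF 0.0625 > 0.05 retained

  all_kept <- expect_silent_filter(filter_informative(sm, maf_min = 0))
  expect_equal(nrow(all_kept), 1L) # monomorphic site still removed

  expect_warning(
    expect_silent_filter_result <- suppressMessages(
      filter_informative(tiny_site_matrix(rbind(rep(0L, 24))))
    ),
    "No informative sites"
  )
})

test_that("low-call-rate sites are dropped before the MAF computation", {
  d <- rbind(c(1L, NA, NA, NA, NA, NA, NA, NA), c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L))
  sm <- tiny_site_matrix(d)
  kept <- expect_silent_filter(filter_informative(sm))
  expect_equal(kept$pos, 200L)
})

test_that("case-major profile follows the definition, ties go to the reference", {
  # site 1: case alt freq 0.9 -> major alt; site 2: tie 0.5 -> reference
  d <- rbind(
    c(2L, 2L, 2L, 2L, 1L, 0L, 0L, 0L, 1L, 0L), # cases 9/10 alt, controls 1/10
    c(1L, 1L, 1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L) # cases 5/10 alt: tie
  )
  sm <- tiny_site_matrix(d)
  prof <- case_major_profile(sm)
  expect_equal(prof$major_allele, c("alt", "ref"))
  expect_equal(prof$freq_case, c(0.9, 0.5))
  expect_equal(prof$freq_control, c(0.1, 1.0))
})

test_that("fixed difference and identical groups hit the F_ST bounds", {
  d <- rbind(
    c(2L, 2L, 2L, 0L, 0L, 0L), # cases fixed alt, controls fixed ref
    c(1L, 1L, 0L, 1L, 1L, 0L) # identical frequencies
  )
  sm <- tiny_site_matrix(d, pos = c(100, 50100))
  w <- window_fst(case_major_profile(sm), window_size = 1000, step = 1000)
  w <- w[w$n_sites > 0, ]
  expect_equal(w$fst, c(1, 0))
})

test_that("window F_ST matches the closed form of the estimator", {
  profile <- tibble::tibble(
    contig = "c", pos = c(10L, 20L), major_allele = "alt",
    freq_case = c(0.9, 0.9), freq_control = c(0.1, 0.1)
  )
  w <- window_fst(profile, window_size = 100, step = 100)
  expect_equal(w$fst[1], (0.5 - 0.18) / 0.5) # = 0.64
  expect_error(window_fst(profile, window_size = 0), "positive")
})

test_that("window means and F_ST agree with brute-force recomputation", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n_sites <- sample(10:50, 1)
      pos <- sort(sample.int(5000, n_sites))
      d <- matrix(rbinom(n_sites * 12, 2, runif(n_sites)), nrow = n_sites)
    })
    sm <- tiny_site_matrix(d, pos = pos)
    profile <- case_major_profile(sm)
    w <- window_fst(profile, window_size = 1000, step = 400)
    oracle <- brute_window_stats(profile, w$start, 1000)
    expect_equal(w$n_sites, oracle$n_sites)
    expect_equal(w$freq_case, oracle$freq_case, tolerance = 1e-12)
    expect_equal(w$fst, oracle$fst, tolerance = 1e-12)
    expect_true(all(is.na(w$fst) | (w$fst >= 0 & w$fst <= 1)))
  }
})

test_that("per-site F_ST is invariant under swapping case and control labels", {
  # The invariance is exact at the site level (the case-major allele is
  # re-derived and G_ST is unchanged by jointly complementing and swapping
  # the two group frequencies); single-site windows expose it.
  withr::with_seed(4, {
    d <- matrix(rbinom(30 * 10, 2, runif(30)), nrow = 30)
  })
  sm <- tiny_site_matrix(d, pos = seq(50, by = 120, length.out = 30))
  swapped <- site_matrix(
    tibble::as_tibble(as.data.frame(sm)),
    case = attr(sm, "control_samples"), control = attr(sm, "case_samples")
  )
  w1 <- window_fst(case_major_profile(sm), window_size = 120, step = 120)
  w2 <- window_fst(case_major_profile(swapped), window_size = 120, step = 120)
  expect_true(all(w1$n_sites <= 1))
  expect_equal(w1$fst, w2$fst, tolerance = 1e-12)
})

test_that("threshold calling handles flat scans and isolated spikes", {
  flat <- tibble::tibble(
    start = c(1L, 101L), end = c(101L, 201L), n_sites = 1L,
    freq_case = 0.5, freq_control = 0.5, fst = 0.2
  )
  res <- call_ibd(flat)
  expect_equal(nrow(res$ibd_intervals), 0L) # sd 0: nothing strictly above mean

  spike <- tibble::tibble(
    start = seq(1L, by = 100L, length.out = 10),
    end = seq(101L, by = 100L, length.out = 10),
    n_sites = 1L, freq_case = 0.5, freq_control = 0.5,
    fst = c(0.9, rep(0.01, 9))
  )
  res2 <- call_ibd(spike)
  expect_equal(res2$ibd_intervals$start, 1L)
  expect_equal(res2$ibd_intervals$end, 101L)

  expect_error(call_ibd(flat[1, ]), "at least 2")
})

test_that("adjacent and overlapping windows merge into maximal intervals", {
  w <- tibble::tibble(
    start = c(1L, 51L, 101L, 301L), end = c(101L, 151L, 201L, 401L),
    n_sites = 1L, freq_case = 0.5, freq_control = 0.5,
    fst = c(0.9, 0.9, 0.9, 0.9)
  )
  w <- rbind(w, tibble::tibble(
    start = 501L, end = 601L, n_sites = 1L,
    freq_case = 0.5, freq_control = 0.5, fst = 0
  ))
  res <- call_ibd(w, k_sd = 0.2)
  expect_equal(res$ibd_intervals$start, c(1L, 301L))
  expect_equal(res$ibd_intervals$end, c(201L, 401L))
})

test_that("the called interval brackets the true segment at a fixed seed", {
  sm <- simulate_scan_data(seed = 42)
  res <- expect_silent_filter(scan_selection(sm, region = c(29331000, 29577000)))
  expect_equal(nrow(res$ibd_intervals), 1L)
  expect_lte(abs(res$ibd_intervals$start - 29436000), 5000)
  expect_lte(abs(res$ibd_intervals$end - 29476000), 5000)
})

test_that("scan results expose tidy, glance, autoplot and writers", {
  sm <- simulate_scan_data(seed = 8)
  res <- expect_silent_filter(scan_selection(sm, region = c(29331000, 29577000)))
  td <- tidy(res)
  expect_true(all(c("start", "fst", "above_threshold") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_ibd_intervals, nrow(res$ibd_intervals))
  expect_s3_class(autoplot(res), "ggplot")

  prefix <- file.path(withr::local_tempdir(), "scan")
  paths <- write_scan_outputs(res, prefix, seed = 8)
  expect_true(all(file.exists(paths)))
  bed <- readr::read_tsv(paths[2], col_names = c("chrom", "start", "end"),
    col_types = "cii", progress = FALSE
  )
  expect_equal(bed$start, res$ibd_intervals$start - 1L) # 0-based half-open
})
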