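test_that("core-site selection uses a strict prevalence inequality", {
  pres <- matrix(TRUE, 10, 3)
  pres[1, 2] <- FALSE          # site 2: 9/10 = 0.90, not > 0.90
  freqs <- array(0, c(10, 3, 4)); freqs[, , 1] <- 1
  pan <- allele_frequency_panel("sp", freqs, presence = pres)
  keep <- select_core_sites(pan, 0.90)
  expect_identical(keep, c(TRUE, FALSE, TRUE))
  # threshold 0: every site present somewhere is kept
  expect_true(all(select_core_sites(pan, 0)))
})

test_that("genomic similarity matches hand arithmetic and limits", {
  expect_equal(genomic_similarity(c(1, 0, 0, 0)), 1)
  expect_equal(genomic_similarity(rep(0.25, 4)), 0.25)
  expect_equal(genomic_similarity(rbind(c(0.8, 0.2, 0, 0),
                                        c(0.5, 0.5, 0, 0))), 0.59)
  expect_error(genomic_similarity(rbind(c(1, 0, 0, 0)), mask = FALSE),
               class = "kincoop_data_error")
})

test_that("sum of squared frequencies equals brute-force pairwise identity", {
  # enumerable instances: identity of two random haplotypes drawn with
  # replacement, averaged over all ordered pairs
  cases <- list(
    rbind(c(0.8, 0.2, 0, 0), c(0.5, 0.5, 0, 0)),
    rbind(c(0.25, 0.25, 0.25, 0.25)),
    rbind(c(0.5, 0.3, 0.2, 0), c(1, 0, 0, 0), c(0.1, 0.9, 0, 0)))
  for (fr in cases)
    expect_equal(genomic_similarity(fr), brute_force_similarity(fr),
                 tolerance = 1e-12)
})

test_that("corrected similarity removes the finite-sample self-pair term", {
  # frequencies backed by n = 4 haploids: counts (2, 2, 0, 0)
  fr <- rbind(c(0.5, 0.5, 0, 0))
  # without replacement: pairs identical = (2*1 + 2*1) / (4*3)
  expect_equal(genomic_similarity(fr, depth = 4, correct = TRUE), 4 / 12)
  expect_error(genomic_similarity(fr, depth = 1, correct = TRUE),
               class = "kincoop_data_error")
})

test_that("pooled frequencies are depth-weighted means over present hosts", {
  pA <- rbind(c(1, 0, 0, 0)); pB <- rbind(c(0, 1, 0, 0))
  pan <- toy_panel(list(pA, pB), depth = matrix(1, 2, 1))
  expect_equal(pooled_frequencies(pan)$freqs[1, 1], 0.5)
  pan2 <- toy_panel(list(pA, pB), depth = matrix(c(3, 1), 2, 1))
  expect_equal(pooled_frequencies(pan2)$freqs[1, 1], 0.75)
  expect_equal(pooled_frequencies(pan2, weights = "equal")$freqs[1, 1], 0.5)
  # single host present at a site: pooled equals that host
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  freqs <- array(0, c(2, 2, 4))
  freqs[1, , 1] <- c(0.6, 0.3); freqs[1, , 2] <- c(0.4, 0.7)
  freqs[2, 1, 1] <- 1
  pan3 <- allele_frequency_panel("sp", freqs, presence = pres)
  expect_equal(pooled_frequencies(pan3)$freqs[2, ], c(0.3, 0.7, 0, 0))
})

test_that("relatedness formula matches hand values and error cases", {
  expect_equal(relatedness(1, 0.5), 1)
  expect_equal(relatedness(0.7, 0.7), 0)
  expect_equal(relatedness(0.8, 0.6), 0.5)
  expect_error(relatedness(1, 1), class = "kincoop_relatedness_undefined")
})

test_that("species observed in a single host are dropped with a reason", {
  fr <- rbind(c(0.5, 0.5, 0, 0))
  single <- toy_panel(list(fr), species = "lonely")
  pair <- toy_panel(list(fr, rbind(c(0.9, 0.1, 0, 0))), species = "ok")
  expect_message(
    rt <- build_relatedness_table(list(single, pair), min_core_sites = 1),
    "lonely")
  expect_false("lonely" %in% rt$summary$species)
  expect_true("ok" %in% rt$summary$species)
  expect_identical(rt$dropped$species, "lonely")
})

test_that("identical host subpopulations have exactly zero relatedness", {
  fr <- rbind(c(0.6, 0.4, 0, 0), c(0.2, 0.3, 0.5, 0))
  pan <- toy_panel(list(fr, fr))
  rt <- build_relatedness_table(pan, min_core_sites = 1)
  expect_equal(rt$table$r, c(0, 0))
})

test_that("a host matching the pooled frequencies has zero relatedness", {
  f1 <- rbind(c(0.9, 0.1, 0, 0)); f2 <- rbind(c(0.5, 0.5, 0, 0))
  pooled <- (f1 + f2) / 2
  pan <- toy_panel(list(f1, f2, pooled))
  rt <- build_relatedness_table(pan, min_core_sites = 1)
  expect_equal(rt$table$r[3], 0, tolerance = 1e-12)
})

test_that("relatedness is invariant to allele relabeling and site order", {
  f1 <- rbind(c(0.7, 0.2, 0.1, 0), c(0.3, 0.3, 0.4, 0))
  f2 <- rbind(c(0.1, 0.8, 0.1, 0), c(0.5, 0.25, 0.25, 0))
  pan <- toy_panel(list(f1, f2))
  r0 <- build_relatedness_table(pan, min_core_sites = 1)$table$r
  # permute alleles (same permutation everywhere) and reverse site order
  perm <- c(3, 1, 4, 2)
  pan2 <- toy_panel(list(f1[2:1, perm], f2[2:1, perm]))
  r2 <- build_relatedness_table(pan2, min_core_sites = 1)$table$r
  expect_equal(r0, r2, tolerance = 1e-12)
})

test_that("globally monomorphic species are dropped, not returned as NaN", {
  fr <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  pan <- toy_panel(list(fr, fr), species = "mono")
  expect_message(rt <- build_relatedness_table(pan, min_core_sites = 1),
                 "monomorphic")
  expect_equal(nrow(rt$summary), 0L)
})

test_that("panel TSVs round-trip through their writer and reader", {
  p <- island_model_params(3, 6, 0.2, 1e-3, 12, 15, seed = 3)
  pan <- simulate_island_model(p)
  tf <- tempfile(fileext = ".tsv")
  write_panel_tsv(pan, tf)
  back <- read_panel_tsv(tf)[[1]]
  expect_equal(back$freqs, pan$freqs, tolerance = 1e-12)
  expect_identical(back$presence, pan$presence)
  expect_equal(back$depth, pan$depth)
})
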