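test_that("parameter validation rejects invalid probabilities and counts", {
  expect_error(island_model_params(10, 10, 1.2, 0, 10, 10),
               class = "kincoop_parameter_error")
  expect_error(island_model_params(10, 10, 0.1, -1e-3, 10, 10),
               class = "kincoop_parameter_error")
  expect_error(island_model_params(0, 10, 0.1, 0, 10, 10),
               class = "kincoop_parameter_error")
})

test_that("same parameters and seed give bitwise-identical panels", {
  p <- island_model_params(5, 8, 0.2, 1e-3, 40, 60, seed = 11)
  expect_identical(simulate_island_model(p), simulate_island_model(p))
})

test_that("allele frequencies sum to one at every (deme, site)", {
  for (s in 1:3) {
    p <- island_model_params(4, 6, runif(1, 0, 0.5), 1e-3, 30, 20, seed = s)
    pan <- simulate_island_model(p)
    tot <- apply(pan$freqs, c(1, 2), sum)
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})

test_that("closed demes without mutation drift to fixation", {
  p <- island_model_params(4, 5, migration = 0, mutation = 0,
                           n_sites = 30, n_generations = 800, seed = 2)
  pan <- simulate_island_model(p)
  # every deme monomorphic at every site: one allele at frequency 1
  mx <- apply(pan$freqs, c(1, 2), max)
  expect_true(all(mx == 1))
  for (d in seq_len(4))
    expect_equal(genomic_similarity(pan$freqs[d, , ]), 1)
})

test_that("full mixing with large demes gives relatedness near zero", {
  p <- island_model_params(10, 100, migration = 1, mutation = 1e-3,
                           n_sites = 200, n_generations = 100, seed = 4)
  pan <- simulate_island_model(p)
  rt <- suppressMessages(build_relatedness_table(pan, min_core_sites = 50,
                                                 correct = TRUE))
  se <- sd(rt$table$r) / sqrt(nrow(rt$table))
  expect_lt(abs(rt$summary$mean_r), 3 * se + 1e-3)
})

test_that("equilibrium relatedness decreases with migration rate", {
  mean_r <- sapply(c(0.01, 0.05, 0.2), function(m) {
    reps <- sapply(1:10, function(s) {
      p <- island_model_params(10, 10, m, 1e-3, 80, 150,
                               seed = 1000 * s + round(1e4 * m))
      pan <- simulate_island_model(p)
      rt <- suppressMessages(build_relatedness_table(pan, min_core_sites = 20,
                                                     correct = TRUE))
      rt$summary$mean_r
    })
    mean(reps)
  })
  expect_true(all(diff(mean_r) < 0))
})
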