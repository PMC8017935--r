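# Poisson and Gaussian phylogenetic mixed models: oracles, recovery,
# diagnostics bookkeeping

test_that("with variances pinned near zero the Poisson fit matches IRLS", {
  set.seed(7)
  n <- 80
  R <- runif(n, 0.1, 0.95)
  X <- cbind(`(Intercept)` = 1, relatedness = R)
  y <- rpois(n, exp(2 + 0.8 * R))
  C <- diag(n)
  dimnames(C) <- list(paste0("s", 1:n), paste0("s", 1:n))
  fit <- fit_poisson_pmm(y, X, C,
                         prior = prior_spec(fix = list(phylo = 1e-2,
                                                       resid = 1e-2)),
                         mcmc = mcmc_settings(15000, 2000, 5, 2, seed = 11))
  mle <- glm(y ~ R, family = poisson)
  draws <- do.call(rbind, fit$draws)
  for (j in 1:2) {
    post_sd <- sd(draws[, j])
    expect_lt(abs(fit$summary$post_mean[j] - coef(mle)[j]), 2 * post_sd)
  }
  expect_true(all(fit$psrf < 1.1))
})

test_that("the true slope is recovered inside the 95% CI in >= 90% of replicates", {
  cover <- 0
  for (i in 1:20) {
    sim <- simulate_comparative_dataset(comparative_sim_params(
      n_species = 100, true_slope = 0.6, true_intercept = 3,
      phylo_variance = 0.05, residual_variance = 0.05, seed = i))
    C <- phylo_covariance(sim$tree, scale = TRUE)
    X <- cbind(`(Intercept)` = 1, relatedness = sim$data$relatedness)
    fit <- fit_poisson_pmm(sim$data$count, X,
                           C[sim$data$species, sim$data$species],
                           mcmc = mcmc_settings(12000, 2000, 5, 1,
                                                seed = 100 + i))
    s <- fit$summary[fit$summary$term == "relatedness", ]
    cover <- cover + (s$ci_lower <= 0.6 && 0.6 <= s$ci_upper)
  }
  expect_gte(cover, 18)
})

test_that("a constant predictor is flagged and carries no information", {
  set.seed(3)
  n <- 40
  X <- cbind(`(Intercept)` = 1, relatedness = rep(0.5, n))
  y <- rpois(n, 20)
  C <- diag(n); dimnames(C) <- list(paste0("s", 1:n), paste0("s", 1:n))
  expect_warning(
    fit <- fit_poisson_pmm(y, X, C,
                           mcmc = mcmc_settings(4000, 1000, 5, 1, seed = 2)),
    "collinear")
  expect_gt(fit$summary$pmcmc[fit$summary$term == "relatedness"], 0.8)
})

test_that("count and alignment validation fire", {
  C <- diag(3); dimnames(C) <- list(letters[1:3], letters[1:3])
  expect_error(fit_poisson_pmm(c(1.5, 2, 3), cbind(1, 1:3), C),
               class = "kincoop_data_error")
  expect_error(fit_poisson_pmm(c(1, 2), cbind(1, 1:2), C),
               class = "kincoop_data_error")
})

test_that("retained draw bookkeeping follows burn-in and thinning", {
  set.seed(1)
  n <- 12
  C <- diag(n); dimnames(C) <- list(paste0("s", 1:n), paste0("s", 1:n))
  mc <- mcmc_settings(n_iterations = 1037, burn_in = 200, thinning = 7,
                      n_chains = 3)
  fit <- fit_poisson_pmm(rpois(n, 5), matrix(1, n, 1,
                                             dimnames = list(NULL, "b0")),
                         C, mcmc = mc)
  expect_identical(nrow(do.call(rbind, fit$draws)),
                   3L * ((1037L - 200L) %/% 7L))
})

test_that("intercept-only Gaussian fit with tiny random effects finds the grand mean", {
  set.seed(9)
  ns <- 8; nh <- 6
  species <- rep(sprintf("sp%d", 1:ns), each = nh)
  host <- rep(sprintf("h%d", 1:nh), ns)
  y <- rnorm(length(species), 0.6, 0.1)
  tr <- ape::rcoal(ns, tip.label = sprintf("sp%d", 1:ns))
  C <- phylo_covariance(tr, scale = TRUE)
  fit <- fit_gaussian_pmm(y, matrix(1, length(y), 1,
                                    dimnames = list(NULL, "b0")),
                          species, host, C,
                          prior = prior_spec(fix = list(host = 1e-8,
                                                        species = 1e-8,
                                                        phylo = 1e-8)),
                          mcmc = mcmc_settings(4000, 1000, 4, 2, seed = 5))
  expect_equal(fit$summary$post_mean[1], mean(y), tolerance = 0.02)
})

test_that("variance components are recovered from a known partition", {
  set.seed(5)
  ns <- 40; nh <- 25
  species <- sprintf("sp%03d", 1:ns); hosts <- sprintf("h%03d", 1:nh)
  tr <- ape::rcoal(ns, tip.label = species)
  C <- phylo_covariance(tr, scale = TRUE)
  g <- expand.grid(species = species, host = hosts,
                   stringsAsFactors = FALSE)
  uh <- rnorm(nh, 0, sqrt(0.1)); us <- rnorm(ns, 0, sqrt(0.05))
  y <- 0.5 + uh[match(g$host, hosts)] + us[match(g$species, species)] +
    rnorm(nrow(g), 0, sqrt(0.02))
  fit <- fit_gaussian_pmm(y, matrix(1, nrow(g), 1,
                                    dimnames = list(NULL, "b0")),
                          g$species, g$host, C,
                          prior = prior_spec(px = TRUE),
                          mcmc = mcmc_settings(5000, 1000, 4, 2, seed = 9))
  draws <- do.call(rbind, fit$draws)
  # iid and phylogenetic species components are only jointly identified
  # with one observation per (species, host); compare their sum
  sp_total <- draws[, "var_species"] + draws[, "var_phylo"]
  checks <- list(list(draws[, "var_host"], 0.1),
                 list(sp_total, 0.05),
                 list(draws[, "var_resid"], 0.02))
  for (ch in checks)
    expect_lt(abs(mean(ch[[1]]) - ch[[2]]), 2 * sd(ch[[1]]))
})

test_that("duplicating every observation tightens fixed-effect posteriors", {
  set.seed(13)
  ns <- 10; nh <- 8
  species <- rep(sprintf("sp%d", 1:ns), each = nh)
  host <- rep(sprintf("h%d", 1:nh), ns)
  x <- runif(length(species))
  y <- 0.3 + 0.5 * x + rnorm(length(x), 0, 0.1)
  tr <- ape::rcoal(ns, tip.label = sprintf("sp%d", 1:ns))
  C <- phylo_covariance(tr, scale = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  mc <- mcmc_settings(4000, 1000, 4, 2, seed = 3)
  f1 <- fit_gaussian_pmm(y, X, species, host, C, mcmc = mc)
  f2 <- fit_gaussian_pmm(rep(y, 2), rbind(X, X), rep(species, 2),
                         rep(host, 2), C, mcmc = mc)
  d1 <- do.call(rbind, f1$draws)[, "x"]
  d2 <- do.call(rbind, f2$draws)[, "x"]
  expect_lt(sd(d2), sd(d1))
  expect_lt(abs(mean(d1) - mean(d2)), 3 * sqrt(sd(d1)^2 + sd(d2)^2))
})

test_that("species missing from the covariance are a data error", {
  y <- rnorm(4)
  C <- diag(2); dimnames(C) <- list(c("a", "b"), c("a", "b"))
  expect_error(
    fit_gaussian_pmm(y, matrix(1, 4, 1), c("a", "b", "c", "c"),
                     c("h1", "h1", "h2", "h2"), C),
    "absent")
})

test_that("pmcmc counts tail mass symmetrically", {
  expect_equal(pmcmc(c(0.5, 1, 2)), 0)
  sym <- c(seq(-1, -0.01, length.out = 500), seq(0.01, 1, length.out = 500))
  expect_equal(pmcmc(sym), 1)
  d <- c(rep(-1, 25), rep(1, 975))
  expect_equal(pmcmc(d), 0.05)
  # negation invariance
  for (s in 1:5) {
    x <- rnorm(500, mean = runif(1, -1, 1))
    expect_equal(pmcmc(x), pmcmc(-x))
  }
})

test_that("Gelman-Rubin separates mixed from divergent chains", {
  set.seed(4)
  same <- list(rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(same), 1.01)
  apart <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(apart), 3)
  ident <- list(cbind(a = 1:100 / 100), cbind(a = 1:100 / 100))
  expect_equal(unname(gelman_rubin(ident)), 1, tolerance = 0.01)
  expect_error(gelman_rubin(list(rnorm(10))),
               class = "kincoop_diagnostic_error")
})

test_that("chain bookkeeping and prior validation reject bad settings", {
  expect_error(mcmc_settings(n_iterations = 100, burn_in = 100),
               class = "kincoop_parameter_error")
  expect_error(mcmc_settings(thinning = 0),
               class = "kincoop_parameter_error")
  expect_error(prior_spec(nu = 0), class = "kincoop_parameter_error")
  paper <- mcmc_settings(preset = "paper")
  expect_identical(paper$n_iterations, 1000000L)
  expect_identical(paper$thinning, 50L)
})
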