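printed_slopes <- function() {
  effect_estimates(
    label = c("secretome", "siderophores", "biofilm", "quorum_sensing",
              "secretion_systems", "antibiotic_degradation"),
    estimate = c(0.59, 1.56, 1.06, 0.39, 0.48, 0.86),
    ci_lower = c(0.08, 0.42, 0.06, -1.34, -2.27, -0.26),
    ci_upper = c(1.07, 2.78, 2.10, 2.21, 3.08, 2.03))
}

test_that("a single estimate passes through the meta-analysis unchanged", {
  est <- effect_estimates("only", 0.42, se = 0.1)
  m <- meta_analysis(est)
  expect_equal(m$mu, 0.42)
  expect_equal(m$se, 0.1)
})

test_that("symmetric estimates with equal precision pool to their midpoint", {
  est <- effect_estimates(c("a", "b"), c(0, 1), se = c(0.2, 0.2))
  expect_equal(meta_analysis(est)$mu, 0.5)
})

test_that("the fixed-effect limit equals the inverse-variance weighted mean", {
  est <- printed_slopes()
  m <- meta_analysis(est, method = "FE")
  w <- 1 / est$se^2
  expect_equal(m$mu, sum(w * est$estimate) / sum(w), tolerance = 1e-9)
  expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-9)
  expect_equal(m$tau2, 0)
})

test_that("meta-analysis invariants hold: z ratio and CI construction", {
  m <- meta_analysis(printed_slopes())
  expect_equal(m$z, m$mu / m$se, tolerance = 1e-9)
  expect_equal(m$ci_lower, m$mu - qnorm(0.975) * m$se, tolerance = 1e-9)
  expect_equal(m$ci_upper, m$mu + qnorm(0.975) * m$se, tolerance = 1e-9)
  expect_gte(m$tau2, 0)
  expect_error(meta_analysis(effect_estimates("x", 1, se = 0)),
               class = "kincoop_data_error")
})

test_that("Wald test matches closed forms and rejects singular covariance", {
  w0 <- wald_joint_test(c(0, 0), diag(2))
  expect_equal(w0$W, 0); expect_equal(w0$p, 1)
  w2 <- wald_joint_test(c(1, 1), diag(2))
  expect_equal(w2$W, 2)
  expect_equal(w2$p, exp(-1), tolerance = 1e-9)
  V <- matrix(c(1, 1, 1, 1), 2)
  expect_error(wald_joint_test(c(1, 2), V),
               class = "kincoop_numerical_error")
})

test_that("Wald statistic is invariant under orthonormal rotation", {
  set.seed(2)
  for (i in 1:5) {
    b <- rnorm(4)
    A <- matrix(rnorm(16), 4)
    V <- crossprod(A) + diag(4)
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
    w1 <- wald_joint_test(b, V)
    w2 <- wald_joint_test(drop(Q %*% b), Q %*% V %*% t(Q))
    expect_equal(w1$W, w2$W, tolerance = 1e-9)
  }
})

test_that("island equilibrium relatedness hits its limits and decreases", {
  expect_equal(island_equilibrium_relatedness(5, 0), 1)
  expect_equal(island_equilibrium_relatedness(50, 0), 1)
  expect_equal(island_equilibrium_relatedness(10, 1), 0)
  expect_equal(island_equilibrium_relatedness(10, 0.1), 0.81 / 2.71,
               tolerance = 1e-4)
  grid_m <- seq(0.01, 0.99, by = 0.07)
  r_m <- island_equilibrium_relatedness(10, grid_m)
  expect_true(all(diff(r_m) < 0))
  r_n <- sapply(c(1, 2, 5, 10, 50), island_equilibrium_relatedness,
                migration = 0.2)
  expect_true(all(diff(r_n) < 0))
})

test_that("log-link effect size converts slopes to percentage changes", {
  expect_equal(predicted_count_increase(0.59, 0.12, 0.93),
               100 * (exp(0.59 * 0.81) - 1))
  expect_equal(predicted_count_increase(0, 0.1, 0.9), 0)
})

test_that("path summary requires every component fit", {
  expect_error(path_summary(list(), list(), NULL, NULL, NULL),
               class = "kincoop_configuration_error")
})
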