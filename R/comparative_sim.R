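#' Parameters for the comparative-dataset simulator
#'
#' Ground-truth generative model for the phylogenetic Poisson regression of
#' cooperative gene counts on mean relatedness: counts are
#' `Pois(exp(b0 + br * R_i + bn * log(N_i) + u_i + e_i))` with a Brownian
#' phylogenetic effect `u ~ MVN(0, phylo_variance * C)` on a simulated
#' ultrametric tree and iid residual `e`.
#'
#' @param n_species number of tip species.
#' @param true_slope ground-truth slope of log-counts on relatedness (br).
#' @param true_intercept intercept b0 on the log scale.
#' @param genome_size_coef coefficient bn on log genome size (CDS count).
#' @param phylo_variance,residual_variance variance components (>= 0).
#' @param relatedness_range interval within `[0, 1]` into which the
#'   Brownian relatedness trait is mapped.
#' @param trait_bm_variance Brownian variance of the latent logit-scale
#'   relatedness trait (controls phylogenetic signal in R).
#' @param mean_log_cds,sd_log_cds log-normal genome-size distribution
#'   (defaults: around 3,000 CDS, a realistic bacterial scale).
#' @param seed RNG seed.
#' @return A list of class `comparative_sim_params`.
#' @export
comparative_sim_params <- function(n_species, true_slope = 0.6,
                                   true_intercept = 3, genome_size_coef = 0,
                                   phylo_variance = 0.05,
                                   residual_variance = 0.05,
                                   relatedness_range = c(0.1, 0.95),
                                   trait_bm_variance = 1,
                                   mean_log_cds = log(3000), sd_log_cds = 0.3,
                                   seed = 1L) {
  assert_count(n_species, "n_species", min = 2L)
  if (phylo_variance < 0 || residual_variance < 0)
    stop_kc("variances must be >= 0", class = "kincoop_parameter_error")
  if (length(relatedness_range) != 2L || any(relatedness_range < 0) ||
      any(relatedness_range > 1) || diff(relatedness_range) <= 0)
    stop_kc("relatedness_range must be an increasing interval in [0, 1]",
            class = "kincoop_parameter_error")
  structure(list(n_species = as.integer(n_species), true_slope = true_slope,
                 true_intercept = true_intercept,
                 genome_size_coef = genome_size_coef,
                 phylo_variance = phylo_variance,
                 residual_variance = residual_variance,
                 relatedness_range = relatedness_range,
                 trait_bm_variance = trait_bm_variance,
                 mean_log_cds = mean_log_cds, sd_log_cds = sd_log_cds,
                 seed = as.integer(seed)),
            class = "comparative_sim_params")
}

#' Simulate a phylogeny plus comparative trait/count dataset
#'
#' Draws a random ultrametric coalescent tree (depth scaled to 1), a
#' Brownian relatedness trait on the logit scale mapped into
#' `relatedness_range`, log-normal genome sizes, and Poisson cooperative
#' gene counts from the log-link model in [comparative_sim_params()]. The
#' phylogenetic covariance used for simulation is scaled to unit diagonal,
#' so `phylo_variance` is on the same scale as `residual_variance`.
#'
#' @param params a `comparative_sim_params` object.
#' @return List with `tree` (ape `phylo`, ultrametric), `data` (data.frame:
#'   species, relatedness, total_cds, count, and the latent `u_phylo`,
#'   `resid` used), and `params`.
#' @export
simulate_comparative_dataset <- function(params) {
  stopifnot(inherits(params, "comparative_sim_params"))
  set.seed(params$seed)
  n <- params$n_species
  tree <- ape::rcoal(n, tip.label = sprintf("sp%03d", seq_len(n)))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  C <- ape::vcv(tree)
  C <- C / mean(diag(C))
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop_kc("degenerate tree: phylogenetic covariance not PSD",
            class = "kincoop_simulation_error")

  cu <- chol(C + diag(1e-10, n))
  # latent relatedness: Brownian on the logit scale, mapped into the range
  z <- rmvn_chol(rep(0, n), cu * sqrt(params$trait_bm_variance))
  R <- params$relatedness_range[1] + diff(params$relatedness_range) * plogis(z)

  total_cds <- pmax(1, round(rlnorm(n, params$mean_log_cds, params$sd_log_cds)))
  u <- if (params$phylo_variance > 0)
    rmvn_chol(rep(0, n), cu * sqrt(params$phylo_variance)) else numeric(n)
  e <- rnorm(n, 0, sqrt(params$residual_variance))
  eta <- params$true_intercept + params$true_slope * R +
    params$genome_size_coef * log(total_cds) + u + e
  y <- rpois(n, exp(eta))

  dat <- data.frame(species = tree$tip.label, relatedness = R,
                    total_cds = total_cds, count = y,
                    u_phylo = u, resid = e)
  list(tree = tree, data = dat, params = params)
}
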