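# Shared settings for the analysis scripts. Each script is a thin driver
# over the kincoop package; run them in order from the repository root:
#   Rscript analysis/01_simulate_community.R
#   Rscript analysis/02_relatedness.R
#   ...
# All outputs land under results/.

library(kincoop)

RESULTS_DIR <- "results"
RUN_DIR <- file.path(RESULTS_DIR, "synthetic")
FITS_DIR <- file.path(RESULTS_DIR, "fits")
GLOBAL_SEED <- 1L

# the synthetic study conditions: a small community whose migration rates
# span an order of magnitude, observed in a dozen hosts
analysis_config <- function(seed = GLOBAL_SEED) {
  pipeline_config(n_species = 20, n_hosts = 12, n_sites = 300,
                  deme_size = 10, mutation = 1e-4,
                  true_slope = 2, migration_range = c(0.02, 0.5),
                  min_core_sites = 100,
                  mcmc = mcmc_settings(n_iterations = 20000L,
                                       burn_in = 4000L, thinning = 8L,
                                       n_chains = 2L, seed = seed),
                  seed = seed, out_dir = RUN_DIR)
}

dir.create(RUN_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(FITS_DIR, showWarnings = FALSE, recursive = TRUE)
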