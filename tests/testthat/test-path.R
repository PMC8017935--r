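# path classification on fitted models from worlds with known causal
# structure

make_null_world <- function(seed) {
  # relatedness varies but counts, abundance and sporulation are all
  # independent noise
  set.seed(seed)
  ns <- 25; nh <- 8
  species <- sprintf("sp%03d", 1:ns)
  hosts <- sprintf("h%02d", 1:nh)
  tree <- ape::rcoal(ns, tip.label = species)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tab <- expand.grid(species = species, host = hosts,
                     stringsAsFactors = FALSE)
  tab$r <- plogis(rnorm(nrow(tab), 0.8, 0.8))
  tab$s_within <- NA; tab$s_across <- NA; tab$n_core_sites <- 100L
  rel <- structure(list(
    table = tab,
    summary = data.frame(species = species,
                         mean_r = tapply(tab$r, tab$species, mean)[species],
                         n_hosts = nh, n_core_sites = 100L),
    dropped = data.frame()), class = "relatedness_table")
  counts <- data.frame(species = species,
                       secretome = rpois(ns, 60),
                       biofilm = rpois(ns, 15),
                       quorum_sensing = rpois(ns, 6),
                       secretion_systems = rpois(ns, 8),
                       siderophores = rpois(ns, 8),
                       antibiotic_degradation = rpois(ns, 8),
                       total_cds = 3000L,
                       gram = sample(c("positive", "negative"), ns, TRUE),
                       sporulation_score = runif(ns),
                       mean_relative_abundance = NA)
  ab <- simulate_relative_abundance(species, hosts, seed = seed + 1)
  counts$mean_relative_abundance <-
    tapply(ab$relative_abundance, ab$species, mean)[species]
  list(tree = tree, rel = rel, counts = counts, abundance = ab)
}

test_that("in a null world relatedness->cooperation edges are mostly absent", {
  mc <- mcmc_settings(3000, 600, 4, 1, seed = 77)
  n_sig <- 0; n_edges <- 0
  for (rep in 1:3) {
    w <- make_null_world(400 + rep)
    model_table <- suppressMessages(merge_model_table(w$counts,
                                                      w$rel$summary))
    base <- fit_cooperation_models(model_table, w$tree, eco = FALSE,
                                   mcmc = mc)
    eco <- fit_cooperation_models(model_table, w$tree, eco = TRUE,
                                  mcmc = mc)
    rel_fit <- fit_relatedness_model(w$rel, w$counts, w$abundance, w$tree,
                                     mcmc = mc)
    rel_rev <- fit_relatedness_model(w$rel, w$counts, w$abundance, w$tree,
                                     reverse = TRUE, mcmc = mc)
    ps <- path_summary(base, eco, rel_fit, rel_rev, reverse_wald(rel_rev))
    e <- ps$edges
    rel_edges <- e[e$from == "relatedness", ]
    n_edges <- n_edges + nrow(rel_edges)
    n_sig <- n_sig + sum(rel_edges$classification == "significant")
  }
  expect_equal(n_edges, 18)
  expect_lte(n_sig, 2)   # ~5% false-positive rate under the null
})

test_that("the generative scenario is recovered as migration -> relatedness -> cooperation", {
  cfg <- pipeline_config(n_species = 15, n_hosts = 10, n_sites = 200,
                         min_core_sites = 50,
                         mcmc = mcmc_settings(4000, 1000, 4, 2, seed = 5),
                         seed = 7, out_dir = tempfile("kc_path_"))
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  e <- res$path$edges
  mig_rel <- e[e$from == "migration" & e$to == "relatedness", ]
  expect_lt(mig_rel$estimate, 0)
  expect_lt(mig_rel$pmcmc, 0.05)
  rel_coop <- e[e$from == "relatedness", ]
  expect_gte(sum(rel_coop$classification == "significant" &
                   rel_coop$sign > 0), 4)
  # migration acts through relatedness: indirect roles dominate and at
  # most one class shows a direct migration edge
  mig_coop <- e[e$from == "migration" & e$to != "relatedness", ]
  expect_lte(sum(mig_coop$classification == "significant"), 1)
  expect_gte(sum(mig_coop$role %in% c("indirect", "direct+indirect")), 4)
  unlink(cfg$out_dir, recursive = TRUE)
})
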