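#' Build the fixed-effect design for a cooperation count model
#'
#' Response: the count for one cooperation class. Predictors: intercept,
#' mean relatedness, and `log(N_i)` with `N_i = total_cds - Y_i` (the CDS
#' not involved in the class) to absorb nonlinear scaling with genome
#' size; optionally mean relative abundance and sporulation score; the
#' secretome model additionally gets a gram-profile intercept shift.
#'
#' @param counts cooperation-counts table ([build_cooperation_counts()])
#'   merged with a `mean_r` column (see [merge_model_table()]).
#' @param class one of `"secretome"` or the five class names.
#' @param eco include relative abundance + sporulation score.
#' @return List with `y`, `X` (design matrix), `species`.
#' @export
cooperation_design <- function(counts, class, eco = FALSE) {
  if (!class %in% c("secretome", COOPERATION_CLASSES))
    stop_kc("unknown cooperation class: ", class,
            class = "kincoop_configuration_error")
  y <- counts[[class]]
  n_other <- counts$total_cds - y
  if (any(n_other <= 0))
    stop_kc("total_cds - count must be positive for log genome size",
            class = "kincoop_data_error")
  X <- cbind(`(Intercept)` = 1, relatedness = counts$mean_r,
             log_cds_other = log(n_other))
  if (eco)
    X <- cbind(X, mean_relative_abundance = counts$mean_relative_abundance,
               sporulation_score = counts$sporulation_score)
  if (class == "secretome")
    X <- cbind(X, gram_positive = as.numeric(counts$gram == "positive"))
  list(y = y, X = X, species = counts$species)
}

#' Merge cooperation counts with per-species mean relatedness
#'
#' Inner join; species missing a relatedness estimate are dropped with a
#' message.
#'
#' @param counts cooperation-counts table.
#' @param rel_summary per-species summary of a `relatedness_table`.
#' @return counts with a `mean_r` column.
#' @export
merge_model_table <- function(counts, rel_summary) {
  lost <- setdiff(counts$species, rel_summary$species)
  if (length(lost))
    message("species without relatedness estimate dropped from models: ",
            paste(lost, collapse = ", "))
  m <- merge(counts, rel_summary[, c("species", "mean_r")], by = "species")
  m[order(m$species), ]
}

#' Fit the six cooperation count models
#'
#' One phylogenetic Poisson mixed model per cooperation class, with or
#' without the ecological covariates.
#'
#' @param model_table output of [merge_model_table()].
#' @param tree ultrametric phylogeny covering the species.
#' @param eco include ecological covariates.
#' @param prior,mcmc passed to [fit_poisson_pmm()].
#' @return Named list of `phylo_fit` (secretome + five classes).
#' @export
fit_cooperation_models <- function(model_table, tree, eco = FALSE,
                                   prior = prior_spec(),
                                   mcmc = mcmc_settings()) {
  check_species_on_tree(model_table$species, tree)
  C <- phylo_covariance(tree, scale = TRUE)
  C <- C[model_table$species, model_table$species]
  fits <- list()
  for (cl in c("secretome", COOPERATION_CLASSES)) {
    d <- cooperation_design(model_table, cl, eco = eco)
    fits[[cl]] <- fit_poisson_pmm(d$y, d$X, C, prior = prior, mcmc = mcmc)
  }
  fits
}

#' Fit the Gaussian model of within-host relatedness
#'
#' Relatedness per (species, host) regressed on within-host relative
#' abundance and sporulation score, with host, species and phylogenetic
#' random effects; `reverse = TRUE` adds the six cooperation counts
#' (per 1,000 genes, for comparable scale) as fixed predictors and is the
#' substrate of the reverse-causation Wald test.
#'
#' @param rel_table a `relatedness_table`.
#' @param counts cooperation-counts table (sporulation scores and counts).
#' @param abundance data.frame `species`, `host`, `relative_abundance`.
#' @param tree phylogeny covering the species.
#' @param reverse add the six cooperation counts as predictors.
#' @param prior,mcmc passed to [fit_gaussian_pmm()].
#' @return A `phylo_fit`.
#' @export
fit_relatedness_model <- function(rel_table, counts, abundance, tree,
                                  reverse = FALSE,
                                  prior = prior_spec(px = TRUE),
                                  mcmc = mcmc_settings()) {
  tab <- rel_table$table
  tab <- merge(tab, abundance, by = c("species", "host"))
  tab <- merge(tab, counts, by = "species")
  tab <- tab[order(tab$species, tab$host), ]
  check_species_on_tree(unique(tab$species), tree)
  C <- phylo_covariance(tree, scale = TRUE)
  X <- cbind(`(Intercept)` = 1,
             mean_relative_abundance = tab$relative_abundance,
             sporulation_score = tab$sporulation_score)
  if (reverse) {
    cnt <- as.matrix(tab[, c("secretome", COOPERATION_CLASSES)]) / 1000
    colnames(cnt) <- c("secretome", COOPERATION_CLASSES)
    X <- cbind(X, cnt)
  }
  fit_gaussian_pmm(tab$r, X, tab$species, tab$host, C, prior = prior,
                   mcmc = mcmc)
}

check_species_on_tree <- function(species, tree) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp))
    stop_kc("species absent from tree: ",
            paste(missing_sp, collapse = ", "), class = "kincoop_data_error")
  invisible(TRUE)
}

#' Reverse-causation joint Wald test from a fitted relatedness model
#'
#' Extracts the posterior means and covariance of the six cooperation
#' coefficients from the reverse-causation fit and applies
#' [wald_joint_test()].
#'
#' @param rel_fit_reverse a `phylo_fit` from
#'   `fit_relatedness_model(..., reverse = TRUE)`.
#' @return List with `W`, `df`, `p`.
#' @export
reverse_wald <- function(rel_fit_reverse) {
  terms <- c("secretome", COOPERATION_CLASSES)
  draws <- do.call(rbind, rel_fit_reverse$draws)
  if (!all(terms %in% colnames(draws)))
    stop_kc("reverse-causation fit lacks cooperation coefficients",
            class = "kincoop_configuration_error")
  b <- colMeans(draws[, terms])
  V <- stats::cov(draws[, terms])
  wald_joint_test(b, V, df = length(terms))
}

#' Meta-analysis of the relatedness slopes of fitted count models
#'
#' Pulls the posterior mean and SD of the relatedness slope from each
#' class fit and pools them with [meta_analysis()]; the posterior SD
#' serves as the per-class standard error.
#'
#' @param fits named list of `phylo_fit` (one per class).
#' @param term design column to pool (default `"relatedness"`).
#' @param method tau^2 estimator.
#' @return A `meta_result`.
#' @export
meta_from_fits <- function(fits, term = "relatedness", method = "REML") {
  est <- vapply(fits, function(f) {
    d <- do.call(rbind, f$draws)[, term]
    c(mean(d), sd(d))
  }, numeric(2))
  meta_analysis(effect_estimates(colnames(est) %||% names(fits),
                                 est[1, ], se = est[2, ]),
                method = method)
}

#' Pipeline configuration
#'
#' Defaults reproduce the documented analysis settings: core-site
#' prevalence 0.90 (strict), at least 2 hosts, 100 core sites, sporulation
#' e-value cutoff 1e-10.
#'
#' @param mode `"synthetic"` (generate everything) or `"tables"` (read the
#'   TSV/Newick inputs in `paths`).
#' @param n_species,n_hosts,n_sites,deme_size,mutation synthetic-world
#'   sizes: species, demes (hosts), unlinked sites, haploid individuals
#'   per deme, mutation rate.
#' @param n_generations island-model generations (default `10 * deme_size`
#'   burn-in plus 200).
#' @param true_slope ground-truth slope of log social gene content on
#'   relatedness in the synthetic world.
#' @param migration_range per-species migration rates are equally spaced
#'   in this interval.
#' @param prevalence_threshold,min_hosts,min_core_sites relatedness
#'   filters.
#' @param corrected_similarity use the sample-size-corrected similarity
#'   (default TRUE: synthetic demes are finite samples of known size).
#' @param evalue_cutoff sporulation hit cutoff (inclusive).
#' @param mcmc an [mcmc_settings()].
#' @param seed global seed; stages derive child seeds by fixed offsets.
#' @param out_dir run directory for artifacts.
#' @param paths named list of input paths for `"tables"` mode: `panels`,
#'   `annotations`, `hits`, `abundance`, `tree`, `social_terms`,
#'   `signature`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "tables"),
                            n_species = 20L, n_hosts = 12L, n_sites = 300L,
                            deme_size = 10L, mutation = 1e-4,
                            n_generations = NULL, true_slope = 2,
                            migration_range = c(0.02, 0.5),
                            prevalence_threshold = 0.90, min_hosts = 2L,
                            min_core_sites = 100L,
                            corrected_similarity = TRUE,
                            evalue_cutoff = 1e-10,
                            mcmc = mcmc_settings(n_iterations = 6000L,
                                                 burn_in = 1000L,
                                                 thinning = 5L),
                            seed = 1L, out_dir = tempfile("kincoop_run_"),
                            paths = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_species = as.integer(n_species),
                 n_hosts = as.integer(n_hosts),
                 n_sites = as.integer(n_sites),
                 deme_size = as.integer(deme_size), mutation = mutation,
                 n_generations = n_generations %||%
                   (10L * as.integer(deme_size) + 200L),
                 true_slope = true_slope,
                 migration_range = migration_range,
                 prevalence_threshold = prevalence_threshold,
                 min_hosts = as.integer(min_hosts),
                 min_core_sites = as.integer(min_core_sites),
                 corrected_similarity = corrected_similarity,
                 evalue_cutoff = evalue_cutoff, mcmc = mcmc,
                 seed = as.integer(seed), out_dir = out_dir, paths = paths),
            class = "pipeline_config")
}

write_manifest <- function(path, values) {
  keys <- sort(names(values))
  lines <- vapply(keys, function(k)
    paste0(k, "=", paste(format(values[[k]], trim = TRUE), collapse = ",")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run manifest back as a named character list
#' @param path manifest file written by [run_pipeline()].
#' @return Named list of character values.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
           vapply(kv, `[[`, "", 1))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_kc("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "kincoop_stage_error"))
}

#' Run the full comparative pipeline
#'
#' Synthetic mode generates a ground-truth world in which migration shapes
#' relatedness (per-species island models with migration rates spread over
#' `migration_range`; sporulation scores increase with migration) and
#' relatedness shapes social gene content (per-class annotation
#' probabilities scale as `exp(true_slope * r)`), then runs: relatedness
#' estimation, trait quantification, the six count models with and
#' without ecological covariates, the Gaussian relatedness models (forward
#' and reverse), meta-analyses, the joint Wald test, and the path summary.
#' All artifacts are written under `config$out_dir` as TSV/Newick plus a
#' key-value run manifest; every dropped species is logged.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list of all intermediate objects plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  if (config$mode == "synthetic") {
    world <- stage("simulate", simulate_synthetic_community(config))
    panels <- world$panels; annotations <- world$annotations
    hits <- world$hits; abundance <- world$abundance; tree <- world$tree
    sets <- world$sets
    write_panel_tsv(panels, out("panels.tsv"))
    write_tsv_kc(annotations, out("gene_annotations.tsv"))
    write_tsv_kc(hits, out("sporulation_hits.tsv"))
    write_tsv_kc(abundance, out("relative_abundance.tsv"))
    ape::write.tree(tree, out("tree.nwk"))
  } else {
    p <- config$paths
    for (need in c("panels", "annotations", "hits", "abundance", "tree"))
      if (is.null(p[[need]]))
        stop_kc("tables mode needs path: ", need,
                class = "kincoop_configuration_error")
    panels <- stage("ingest", read_panel_tsv(p$panels))
    annotations <- stage("ingest", read_tsv_kc(p$annotations))
    hits <- stage("ingest", read_tsv_kc(p$hits))
    abundance <- stage("ingest", read_tsv_kc(p$abundance))
    tree <- stage("ingest", ape::read.tree(p$tree))
    sets <- read_social_term_sets(
      p$social_terms %||% kc_fixture("social_go_terms_synthetic.tsv"))
  }

  rel <- stage("relatedness", build_relatedness_table(
    panels, prevalence_threshold = config$prevalence_threshold,
    min_hosts = config$min_hosts, min_core_sites = config$min_core_sites,
    correct = config$corrected_similarity))
  write_relatedness_tsv(rel, out("relatedness.tsv"))

  counts <- stage("traits", build_cooperation_counts(
    annotations, sets, hits, abundance = abundance,
    evalue_cutoff = config$evalue_cutoff))
  write_tsv_kc(counts, out("cooperation_counts.tsv"))

  model_table <- stage("fit", merge_model_table(counts, rel$summary))
  mcmc_fit <- config$mcmc
  mcmc_fit$seed <- child_seed(config$seed, "fit")
  coop_fits <- stage("fit", fit_cooperation_models(model_table, tree,
                                                   eco = FALSE,
                                                   mcmc = mcmc_fit))
  coop_fits_eco <- stage("fit", fit_cooperation_models(model_table, tree,
                                                       eco = TRUE,
                                                       mcmc = mcmc_fit))
  rel_fit <- stage("fit", fit_relatedness_model(rel, counts, abundance,
                                                tree, mcmc = mcmc_fit))
  rel_fit_rev <- stage("fit", fit_relatedness_model(rel, counts, abundance,
                                                    tree, reverse = TRUE,
                                                    mcmc = mcmc_fit))
  dir.create(out("fits"), showWarnings = FALSE)
  for (cl in names(coop_fits)) {
    write_fit_summary(coop_fits[[cl]], out(file.path("fits",
                                                     paste0(cl, "_base.tsv"))))
    write_fit_summary(coop_fits_eco[[cl]],
                      out(file.path("fits", paste0(cl, "_eco.tsv"))))
  }
  write_fit_summary(rel_fit, out("fits/relatedness_model.tsv"))
  write_fit_summary(rel_fit_rev, out("fits/relatedness_model_reverse.tsv"))

  meta <- stage("meta", meta_from_fits(coop_fits))
  meta_eco <- stage("meta", meta_from_fits(coop_fits_eco))
  write_tsv_kc(data.frame(model = c("base", "eco"),
                          mu = c(meta$mu, meta_eco$mu),
                          se = c(meta$se, meta_eco$se),
                          z = c(meta$z, meta_eco$z),
                          ci_lower = c(meta$ci_lower, meta_eco$ci_lower),
                          ci_upper = c(meta$ci_upper, meta_eco$ci_upper),
                          p = c(meta$p, meta_eco$p),
                          tau2 = c(meta$tau2, meta_eco$tau2)),
               out("meta_analysis.tsv"))

  wald <- stage("path", reverse_wald(rel_fit_rev))
  path <- stage("path", path_summary(coop_fits, coop_fits_eco, rel_fit,
                                     rel_fit_rev, wald))
  write_tsv_kc(path$edges, out("path_edges.tsv"))

  write_manifest(out("manifest.txt"), list(
    package_version = as.character(packageVersion("kincoop")),
    mode = config$mode, seed = config$seed,
    n_species = config$n_species, n_hosts = config$n_hosts,
    n_sites = config$n_sites, deme_size = config$deme_size,
    prevalence_threshold = config$prevalence_threshold,
    min_hosts = config$min_hosts, min_core_sites = config$min_core_sites,
    corrected_similarity = config$corrected_similarity,
    evalue_cutoff = config$evalue_cutoff,
    mcmc_iterations = config$mcmc$n_iterations,
    mcmc_burn_in = config$mcmc$burn_in,
    mcmc_thinning = config$mcmc$thinning,
    mcmc_chains = config$mcmc$n_chains,
    species_dropped = if (nrow(rel$dropped)) rel$dropped$species else "none",
    wald_W = sprintf("%.6f", wald$W), wald_p = sprintf("%.6f", wald$p),
    meta_mu = sprintf("%.6f", meta$mu)))

  invisible(list(out_dir = config$out_dir, relatedness = rel,
                 counts = counts, coop_fits = coop_fits,
                 coop_fits_eco = coop_fits_eco, rel_fit = rel_fit,
                 rel_fit_reverse = rel_fit_rev, meta = meta,
                 meta_eco = meta_eco, wald = wald, path = path))
}

#' Generate the ground-truth synthetic community
#'
#' The synthetic world realises the causal scenario the pipeline is built
#' to detect: per-species migration rates (spread over
#' `migration_range`) drive equilibrium relatedness through the island
#' model, sporulation scores increase with migration, and per-class social
#' gene content scales as `exp(true_slope * r)`. Relative abundance is
#' generated independently of deme size (no group-size effect).
#'
#' @param config a [pipeline_config()] (synthetic mode fields are used).
#' @return List with `panels`, `annotations`, `hits`, `abundance`, `tree`,
#'   `sets`, and the ground truth `migration` and `r_theory`.
#' @export
simulate_synthetic_community <- function(config) {
  seed_sim <- child_seed(config$seed, "simulate")
  set.seed(seed_sim)
  n <- config$n_species
  species <- sprintf("sp%03d", seq_len(n))
  m_i <- seq(config$migration_range[1], config$migration_range[2],
             length.out = n)[sample.int(n)]
  r_theory <- island_equilibrium_relatedness(config$deme_size, m_i)

  panels <- lapply(seq_len(n), function(i) {
    p <- island_model_params(config$n_hosts, config$deme_size, m_i[i],
                             config$mutation, config$n_sites,
                             config$n_generations,
                             seed = seed_sim + i)
    simulate_island_model(p, species = species[i])
  })

  # social gene content scales as exp(true_slope * r); base rates per class
  base_p <- c(biofilm = 0.004, quorum_sensing = 0.001,
              secretion_systems = 0.002, siderophores = 0.002,
              antibiotic_degradation = 0.002)
  p_soc <- outer(exp(config$true_slope * r_theory), base_p)
  colnames(p_soc) <- names(base_p)
  gt <- gene_table_sim_params(
    n_genes_per_species = pmax(500, round(rlnorm(n, log(3000), 0.25))),
    p_extracellular = pmin(0.2, 0.01 * exp(config$true_slope * r_theory)),
    p_social_per_class = pmin(p_soc, 0.9),
    p_sporulation_gene = pmin(1, 0.1 + 1.6 * m_i),
    seed = seed_sim + 10000L)
  tabs <- generate_gene_tables(gt, species)
  abundance <- simulate_relative_abundance(
    species, sprintf("deme%03d", seq_len(config$n_hosts)),
    seed = seed_sim + 20000L)
  set.seed(child_seed(config$seed, "tree"))
  tree <- ape::rcoal(n, tip.label = species)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  sets <- read_social_term_sets(kc_fixture("social_go_terms_synthetic.tsv"))
  list(panels = panels, annotations = tabs$annotations,
       hits = tabs$sporulation_hits, abundance = abundance, tree = tree,
       sets = sets, migration = m_i, r_theory = r_theory)
}

#' Write a fit summary (and PSRF) as TSV
#'
#' One row per term: posterior mean, 95% CI, PMCMC, PSRF.
#'
#' @param fit a `phylo_fit`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  s <- fit$summary
  s$psrf <- if (!is.null(fit$psrf)) fit$psrf[s$term] else NA_real_
  write_tsv_kc(s, path)
}
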