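#' Parameters for the gene-annotation table simulator
#'
#' Per-species annotation fixtures with known ground truth: each gene
#' independently receives an extracellular localization with probability
#' `p_extracellular`, one random term from each cooperation-class set with
#' the class probability, and background (non-social) terms; each signature
#' gene is present with probability `p_sporulation_gene`.
#'
#' Probabilities may be scalars (shared by all species) or per-species
#' (vector / `n_species x 5` matrix), which lets a caller tie social gene
#' content to a species-level driver such as simulated relatedness.
#'
#' @param n_genes_per_species genes per species (scalar or per-species).
#' @param p_extracellular probability of extracellular localization.
#' @param p_social_per_class named probabilities for the five classes
#'   (vector of 5, or `n_species x 5` matrix).
#' @param p_sporulation_gene probability each signature gene is present.
#' @param p_background probability a gene carries background terms.
#' @param seed RNG seed.
#' @return List of class `gene_table_sim_params`.
#' @export
gene_table_sim_params <- function(n_genes_per_species = 3000,
                                  p_extracellular = 0.03,
                                  p_social_per_class =
                                    c(biofilm = 0.01, quorum_sensing = 0.002,
                                      secretion_systems = 0.004,
                                      siderophores = 0.006,
                                      antibiotic_degradation = 0.005),
                                  p_sporulation_gene = 0.5,
                                  p_background = 0.6, seed = 1L) {
  assert_prob(p_extracellular, "p_extracellular")
  assert_prob(unlist(p_social_per_class), "p_social_per_class")
  assert_prob(p_sporulation_gene, "p_sporulation_gene")
  assert_prob(p_background, "p_background")
  if (any(n_genes_per_species < 1))
    stop_kc("n_genes_per_species must be >= 1",
            class = "kincoop_parameter_error")
  structure(list(n_genes_per_species = n_genes_per_species,
                 p_extracellular = p_extracellular,
                 p_social_per_class = p_social_per_class,
                 p_sporulation_gene = p_sporulation_gene,
                 p_background = p_background, seed = as.integer(seed)),
            class = "gene_table_sim_params")
}

per_species_param <- function(x, i, n_species, name) {
  if (is.matrix(x)) return(x[if (nrow(x) == 1L) 1L else i, ])
  if (length(x) == 1L) return(x)
  if (length(x) == n_species) return(x[i])
  if (length(x) == 5L) return(x)
  stop_kc(name, " must be scalar, per-species, or per-class",
          class = "kincoop_parameter_error")
}

#' Simulate gene annotation tables and sporulation hits
#'
#' @param params a `gene_table_sim_params`.
#' @param species_list character vector of species ids (nonempty).
#' @param term_sets a `social_term_sets`; default: the shipped synthetic
#'   118-term curated list.
#' @param background_terms pool of non-social term ids; default: the
#'   non-social terms of the shipped synthetic ontology.
#' @param signature signature gene names; default: shipped synthetic 66.
#' @param gram optional per-species gram profile (`"positive"`/
#'   `"negative"`); default randomly assigned.
#' @return List with `annotations` (data.frame: species, gene_id,
#'   localization, go_terms `;`-separated, gram) and `sporulation_hits`
#'   (data.frame: species, gene, evalue).
#' @export
generate_gene_tables <- function(params, species_list, term_sets = NULL,
                                 background_terms = NULL, signature = NULL,
                                 gram = NULL) {
  stopifnot(inherits(params, "gene_table_sim_params"))
  if (length(species_list) == 0L)
    stop_kc("species_list is empty", class = "kincoop_parameter_error")
  term_sets <- term_sets %||%
    read_social_term_sets(kc_fixture("social_go_terms_synthetic.tsv"))
  if (is.null(background_terms)) {
    ont <- read_ontology_tsv(kc_fixture("ontology_synthetic.tsv"))
    background_terms <- setdiff(ont$terms$term_id,
                                unlist(term_sets$sets, use.names = FALSE))
  }
  signature <- signature %||%
    read_tsv_kc(kc_fixture("sporulation_signature_synthetic.tsv"))$gene
  set.seed(params$seed)
  nsp <- length(species_list)
  gram <- gram %||% sample(c("positive", "negative"), nsp, replace = TRUE)
  gram <- rep_len(gram, nsp)
  classes <- names(term_sets$sets)

  ann <- vector("list", nsp); hits <- vector("list", nsp)
  for (i in seq_len(nsp)) {
    sp <- species_list[i]
    ng <- as.integer(rep_len(params$n_genes_per_species, nsp)[i])
    p_ex <- per_species_param(params$p_extracellular, i, nsp,
                              "p_extracellular")
    loc <- ifelse(runif(ng) < p_ex, "extracellular",
                  sample(c("cytoplasmic", "membrane", "cellwall",
                           "periplasmic", "unknown"),
                         ng, replace = TRUE,
                         prob = c(0.60, 0.25, 0.05, 0.05, 0.05)))
    go <- vector("list", ng)
    p_soc <- per_species_param(params$p_social_per_class, i, nsp,
                               "p_social_per_class")
    p_soc <- rep_len(p_soc, length(classes))
    for (k in seq_along(classes)) {
      has <- runif(ng) < p_soc[k]
      if (any(has)) {
        terms <- sample(term_sets$sets[[classes[k]]], sum(has),
                        replace = TRUE)
        go[has] <- Map(c, go[has], terms)
      }
    }
    bg <- runif(ng) < params$p_background
    if (any(bg))
      go[bg] <- Map(c, go[bg],
                    sample(background_terms, sum(bg), replace = TRUE))
    ann[[i]] <- data.frame(
      species = sp, gene_id = sprintf("%s_g%05d", sp, seq_len(ng)),
      localization = loc,
      go_terms = vapply(go, function(g) paste(unique(g), collapse = ";"), ""),
      gram = gram[i])

    p_sp <- per_species_param(params$p_sporulation_gene, i, nsp,
                              "p_sporulation_gene")
    present <- signature[runif(length(signature)) < p_sp]
    if (length(present))
      hits[[i]] <- data.frame(species = sp, gene = present,
                              evalue = 10^-runif(length(present), 15, 60))
  }
  list(annotations = do.call(rbind, ann),
       sporulation_hits = do.call(rbind, hits) %||%
         data.frame(species = character(), gene = character(),
                    evalue = numeric()))
}

#' Simulate per-host relative abundances
#'
#' Log-normal species loads normalised within each host to sum to one: a
#' simple stand-in for compositional species profiles.
#'
#' @param species_list,hosts identifier vectors.
#' @param sdlog spread of species loads (default 1).
#' @param seed RNG seed.
#' @return data.frame `species`, `host`, `relative_abundance`.
#' @export
simulate_relative_abundance <- function(species_list, hosts, sdlog = 1,
                                        seed = 1L) {
  set.seed(seed)
  g <- expand.grid(species = species_list, host = hosts,
                   stringsAsFactors = FALSE)
  g$load <- rlnorm(nrow(g), 0, sdlog)
  tot <- tapply(g$load, g$host, sum)
  g$relative_abundance <- g$load / as.numeric(tot[g$host])
  g[, c("species", "host", "relative_abundance")]
}
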