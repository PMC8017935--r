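# shared fixtures, built in code

read_tsv_kc_test <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# small panel from explicit per-host frequency matrices
toy_panel <- function(freq_list, species = "toy", presence = NULL,
                      depth = NULL) {
  nh <- length(freq_list)
  ns <- nrow(freq_list[[1]])
  freqs <- array(0, c(nh, ns, 4))
  for (h in seq_len(nh)) freqs[h, , ] <- freq_list[[h]]
  allele_frequency_panel(species, freqs, presence = presence, depth = depth)
}

# 6-node toy ontology:
#   root -> hub -> {match1, plain}; match1 -> {kid1, kid2}
toy_ontology <- function() {
  read_ontology_tsv(data.frame(
    term_id = c("T0", "T1", "T2", "T3", "T4", "T5"),
    name = c("root process", "community behaviour hub",
             "biofilm formation", "polysaccharide production",
             "pellicle biofilm assembly step", "matrix maturation step"),
    parent_ids = c("", "T0", "T1", "T1", "T2", "T2")))
}

toy_annotations <- function() {
  data.frame(
    species = "spX",
    gene_id = paste0("g", 1:4),
    localization = c("extracellular", "cytoplasmic", "extracellular",
                     "membrane"),
    go_terms = c("B1;B2", "B1;S1", "", "Q1"),
    gram = "negative")
}

toy_sets <- function() {
  structure(list(sets = list(biofilm = c("B1", "B2"), siderophores = "S1",
                             quorum_sensing = "Q1"),
                 provenance = data.frame()),
            class = "social_term_sets")
}

# brute-force identity-by-state: enumerate every ordered haplotype pair
# drawn with replacement from the per-site frequency distribution
# (independent sites) and average the proportion of identical sites
brute_force_similarity <- function(freqs) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  ns <- nrow(freqs)
  haps <- as.matrix(expand.grid(rep(list(1:4), ns)))
  hp <- apply(haps, 1, function(h) prod(freqs[cbind(seq_len(ns), h)]))
  keep <- hp > 0
  haps <- haps[keep, , drop = FALSE]; hp <- hp[keep]
  s <- 0
  for (i in seq_along(hp)) for (j in seq_along(hp)) {
    s <- s + hp[i] * hp[j] * mean(haps[i, ] == haps[j, ])
  }
  s
}
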