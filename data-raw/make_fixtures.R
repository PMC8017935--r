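# Deterministic generation of the plain-text fixtures shipped under
# inst/extdata/. These are clearly-labelled synthetic stand-ins: the real
# curated social-GO list and sporulation signature are dataset artifacts
# not redistributed here; the class sizes (48/5/11/29/25 = 118 terms) and
# signature length (66 genes) follow the published counts.
# Run from the package root: Rscript data-raw/make_fixtures.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

classes <- c("biofilm", "quorum_sensing", "secretion_systems",
             "siderophores", "antibiotic_degradation")
sizes <- c(biofilm = 48, quorum_sensing = 5, secretion_systems = 11,
           siderophores = 29, antibiotic_degradation = 25)

core_phrases <- list(
  biofilm = c("biofilm formation", "biofilm matrix organization",
              "extracellular polysaccharide biosynthetic process",
              "cell adhesion involved in biofilm formation",
              "cell aggregation"),
  quorum_sensing = c("quorum sensing", "autoinducer biosynthetic process"),
  secretion_systems = c("type II protein secretion system",
                        "type III protein secretion system",
                        "type IV protein secretion system",
                        "type VI protein secretion system"),
  siderophores = c("siderophore biosynthetic process",
                   "siderophore transport", "enterobactin biosynthetic process",
                   "pyoverdine biosynthetic process",
                   "iron chelate transport"),
  antibiotic_degradation = c("antibiotic catabolic process",
                             "beta-lactamase activity",
                             "response to antibiotic",
                             "penicillin catabolic process"))

modifiers <- c("", "regulation of ", "positive regulation of ",
               "negative regulation of ", "single-species ",
               "multi-species ", "aerobic ", "anaerobic ",
               "surface-attached ", "host-associated ",
               "cyclic-di-GMP-dependent ", "stress-induced ")

next_id <- local({i <- 0L; function() {i <<- i + 1L; sprintf("GO:99%05d", i)}})

social <- do.call(rbind, lapply(classes, function(cl) {
  nm <- character(0)
  for (mod in modifiers) for (ph in core_phrases[[cl]]) {
    nm <- c(nm, paste0(mod, ph))
    if (length(nm) >= sizes[[cl]]) break
  }
  nm <- unique(nm)[seq_len(sizes[[cl]])]
  data.frame(class = cl, term_id = vapply(nm, function(x) next_id(), ""),
             name = nm, row.names = NULL)
}))
stopifnot(nrow(social) == 118, !anyDuplicated(social$term_id))
write.table(social, "inst/extdata/social_go_terms_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# toy ontology: a root, one hub per class, the 118 social terms under their
# hub, plus deliberately generic background terms (including the classic
# near-miss "polysaccharide production")
root <- data.frame(term_id = "GO:9900000", name = "biological_process",
                   parent_ids = "")
hubs <- data.frame(term_id = sprintf("GO:98%05d", seq_along(classes)),
                   name = c("cell surface community process",
                            "cell-cell signaling",
                            "protein transport machinery",
                            "metal ion acquisition",
                            "xenobiotic catabolic process"),
                   parent_ids = "GO:9900000")
soc <- data.frame(term_id = social$term_id, name = social$name,
                  parent_ids = hubs$term_id[match(social$class, classes)])
background <- data.frame(
  term_id = sprintf("GO:97%05d", 1:30),
  name = c("polysaccharide production", "carbohydrate metabolic process",
           "amino acid biosynthetic process", "DNA replication",
           "translation", "transcription", "cell division",
           "peptidoglycan biosynthetic process", "glycolytic process",
           "tricarboxylic acid cycle", "fatty acid biosynthetic process",
           "purine nucleotide biosynthetic process",
           "pyrimidine nucleotide biosynthetic process",
           "tRNA aminoacylation", "ribosome biogenesis",
           "protein folding", "proteolysis", "DNA repair",
           "oxidative phosphorylation", "nitrogen metabolic process",
           "sulfur metabolic process", "phosphate ion transport",
           "potassium ion transport", "sodium ion transport",
           "cell wall organization", "lipopolysaccharide biosynthetic process",
           "chemotaxis", "flagellum assembly", "sporulation",
           "cold-shock response"),
  parent_ids = "GO:9900000")
ontology <- rbind(root, hubs, soc, background)
write.table(ontology, "inst/extdata/ontology_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

keywords <- data.frame(
  class = rep(classes, c(4, 2, 1, 4, 4)),
  keyword = c("biofilm", "extracellular polysaccharide", "cell adhesion",
              "cell aggregation",
              "quorum sensing", "autoinducer",
              "secretion system",
              "siderophore", "enterobactin", "pyoverdine", "iron chelate",
              "antibiotic catabolic", "beta-lactamase",
              "response to antibiotic", "penicillin catabolic"))
write.table(keywords, "inst/extdata/social_keywords.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# 66 synthetic sporulation-signature gene labels (sporulation sigma factors
# and stage genes naming style)
stages <- c("0", "II", "III", "IV", "V", "VI")
suffix <- c("A", "B", "D", "E", "G", "J", "M", "P", "Q", "R", "T")
genes <- as.vector(outer(stages, suffix, function(s, x) paste0("spo", s, x)))
stopifnot(length(genes) == 66, !anyDuplicated(genes))
write.table(data.frame(gene = genes),
            "inst/extdata/sporulation_signature_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written:", nrow(social), "social terms,", nrow(ontology),
    "ontology terms,", length(genes), "signature genes\n")
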