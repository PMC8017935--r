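# Quantify the six cooperation classes, sporulation scores and relative
# abundance per species from the annotation tables.

source("analysis/00_config.R")

cfg <- analysis_config()
annotations <- read.delim(file.path(RUN_DIR, "gene_annotations.tsv"))
hits <- read.delim(file.path(RUN_DIR, "sporulation_hits.tsv"))
abundance <- read.delim(file.path(RUN_DIR, "relative_abundance.tsv"))
sets <- read_social_term_sets(kc_fixture("social_go_terms_synthetic.tsv"))

counts <- build_cooperation_counts(annotations, sets, hits,
                                   abundance = abundance,
                                   evalue_cutoff = cfg$evalue_cutoff)
write.table(counts, file.path(RESULTS_DIR, "cooperation_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

classes <- c("secretome", "biofilm", "quorum_sensing", "secretion_systems",
             "siderophores", "antibiotic_degradation")
cat(sprintf("cooperation counts for %d species (%d-%d CDS per genome)\n",
            nrow(counts), min(counts$total_cds), max(counts$total_cds)))
for (cl in classes)
  cat(sprintf("  %-22s median %4.0f  range %d-%d\n", cl,
              median(counts[[cl]]), min(counts[[cl]]), max(counts[[cl]])))
cat(sprintf("sporulation scores span %.2f-%.2f\n",
            min(counts$sporulation_score), max(counts$sporulation_score)))
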