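test_that("secretome counting is a direct localization count", {
  expect_identical(count_secretome(toy_annotations())$secretome, 2L)
  tab <- toy_annotations(); tab$localization <- "unknown"
  expect_identical(count_secretome(tab)$secretome, 0L)
  tab$gram <- NA_character_
  expect_error(count_secretome(tab), class = "kincoop_data_error")
  tab2 <- toy_annotations(); tab2$gram[2] <- "positive"
  expect_error(count_secretome(tab2), class = "kincoop_data_error")
})

test_that("keyword matching expands to descendants and direct parents", {
  ont <- toy_ontology()
  sets <- build_social_term_sets(ont, list(biofilm = "biofilm"))
  # matched: T2 (name contains "biofilm") and T4 ("pellicle biofilm ...");
  # children of T2: T4, T5; direct parent of T2: T1
  expect_setequal(sets$sets$biofilm, c("T2", "T4", "T5", "T1"))
  # the generic sibling "polysaccharide production" stays out
  expect_false("T3" %in% sets$sets$biofilm)
  # direct-children mode behaves the same on this two-level toy
  sets2 <- build_social_term_sets(ont, list(biofilm = "biofilm"),
                                  descendants = "direct")
  expect_setequal(sets2$sets$biofilm, c("T2", "T4", "T5", "T1"))
})

test_that("curation removes a term without touching independent matches", {
  ont <- toy_ontology()
  cur <- data.frame(class = "biofilm", term_id = "T5", action = "exclude")
  sets <- build_social_term_sets(ont, list(biofilm = "biofilm"),
                                 curation = cur)
  expect_false("T5" %in% sets$sets$biofilm)
  # T4 matched the keyword on its own and survives
  expect_true(all(c("T2", "T4") %in% sets$sets$biofilm))
  prov <- sets$provenance
  expect_identical(prov$provenance[prov$term_id == "T5"], "curated-out")
  # curated include adds an otherwise unmatched term
  cur2 <- data.frame(class = "biofilm", term_id = "T3", action = "include")
  sets3 <- build_social_term_sets(ont, list(biofilm = "biofilm"),
                                  curation = cur2)
  expect_true("T3" %in% sets3$sets$biofilm)
})

test_that("a cyclic ontology is rejected", {
  expect_error(read_ontology_tsv(data.frame(
    term_id = c("A", "B"), name = c("a", "b"), parent_ids = c("B", "A"))),
    class = "kincoop_data_error")
})

test_that("genes count once per class but may hit several classes", {
  cc <- count_cooperative_genes(toy_annotations(), toy_sets())
  # g1 has two biofilm terms -> 1; g2 has one biofilm + one siderophore
  expect_identical(cc$biofilm, 2L + 0L)         # g1 and g2
  expect_identical(cc$siderophores, 1L)          # g2 only
  expect_identical(cc$quorum_sensing, 1L)        # g4
  expect_identical(cc$total_cds, 4L)
  # empty annotation set -> all zero
  empty <- toy_annotations(); empty$go_terms <- ""
  cc0 <- count_cooperative_genes(empty, toy_sets())
  expect_true(all(cc0[, c("biofilm", "siderophores", "quorum_sensing")] == 0))
})

test_that("class counts are monotone under growing term sets", {
  small <- toy_sets()
  big <- small; big$sets$biofilm <- c(big$sets$biofilm, "S1", "Q1")
  c_small <- count_cooperative_genes(toy_annotations(), small)
  c_big <- count_cooperative_genes(toy_annotations(), big)
  expect_true(all(c_big$biofilm >= c_small$biofilm))
})

test_that("sporulation scores hit the printed boundary cases", {
  sig <- read_tsv_kc_test(kc_fixture("sporulation_signature_synthetic.tsv"))
  full <- data.frame(species = "sp", gene = sig$gene, evalue = 1e-12)
  expect_equal(sporulation_score(full)$sporulation_score, 1)
  none <- full[0, ]
  expect_equal(sporulation_score(none, species = "sp")$sporulation_score, 0)
  # copy number ignored: one gene hit twice is 1/66, not 2/66
  dup <- data.frame(species = "sp", gene = sig$gene[c(1, 1)],
                    evalue = c(1e-20, 1e-30))
  expect_equal(sporulation_score(dup)$sporulation_score, 1 / 66)
  half <- data.frame(species = "sp", gene = sig$gene[1:33], evalue = 1e-15)
  expect_equal(sporulation_score(half)$sporulation_score, 0.5)
})

test_that("the e-value cutoff is inclusive and hits are order-invariant", {
  sig <- c("gA", "gB")
  hits <- data.frame(species = "sp", gene = c("gA", "gB"),
                     evalue = c(1e-10, 1e-9))
  expect_equal(sporulation_score(hits, sig)$sporulation_score, 0.5)
  shuffled <- hits[2:1, ]
  expect_equal(sporulation_score(shuffled, sig), sporulation_score(hits, sig))
  expect_error(sporulation_score(data.frame(species = "sp", gene = "nope",
                                            evalue = 1e-30), sig),
               class = "kincoop_data_error")
})

test_that("cooperation-counts assembly joins all trait blocks", {
  gt <- gene_table_sim_params(n_genes_per_species = 300, seed = 2)
  tabs <- generate_gene_tables(gt, c("a", "b"))
  sets <- read_social_term_sets(kc_fixture("social_go_terms_synthetic.tsv"))
  ab <- simulate_relative_abundance(c("a", "b"), c("h1", "h2"), seed = 1)
  cc <- build_cooperation_counts(tabs$annotations, sets,
                                 tabs$sporulation_hits, abundance = ab)
  expect_identical(cc$species, c("a", "b"))
  expect_true(all(c("secretome", "biofilm", "total_cds", "gram",
                    "sporulation_score", "mean_relative_abundance")
                  %in% names(cc)))
  expect_true(all(cc$secretome <= cc$total_cds))
  expect_false(anyNA(cc$mean_relative_abundance))
})
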