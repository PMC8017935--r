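#' Secretome size per species
#'
#' Number of protein-coding genes whose product is predicted to have an
#' extracellular final localization. The gram profile is carried alongside
#' because localization prediction depends on it and it later enters the
#' secretome model as an intercept.
#'
#' @param table gene annotation data.frame with columns `species`,
#'   `gene_id`, `localization`, `gram` (and `go_terms`, unused here).
#' @param species optional single species; default all.
#' @return data.frame with columns `species`, `secretome`, `gram`.
#' @export
count_secretome <- function(table, species = NULL) {
  if (!is.null(species)) {
    table <- table[table$species %in% species, , drop = FALSE]
    if (nrow(table) == 0L)
      stop_kc("species not in annotation table: ", species,
              class = "kincoop_data_error")
  }
  if (any(is.na(table$gram) | !nzchar(table$gram)))
    stop_kc("missing gram profile: extracellular localization prediction ",
            "requires it", class = "kincoop_data_error")
  sp <- unique(table$species)
  gram <- vapply(sp, function(s) {
    g <- unique(table$gram[table$species == s])
    if (length(g) != 1L)
      stop_kc("gram profile not constant within species ", s,
              class = "kincoop_data_error")
    g
  }, "")
  cnt <- vapply(sp, function(s)
    sum(table$species == s & table$localization == "extracellular"), 0L)
  data.frame(species = sp, secretome = as.integer(cnt), gram = gram,
             row.names = NULL)
}

split_go <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(g) g[nzchar(g)])
}

#' Cooperative gene counts per class
#'
#' Per cooperation class, the number of genes with at least one associated
#' ontology term in that class set. A gene counts once per class however
#' many of its terms match, and may count toward several classes.
#'
#' @param table gene annotation data.frame (see [count_secretome()]); GO
#'   terms are `;`-separated in column `go_terms`.
#' @param sets a `social_term_sets`.
#' @param species optional single species; default all.
#' @return data.frame: `species` plus one integer column per class, and
#'   `total_cds` (genes in the table).
#' @export
count_cooperative_genes <- function(table, sets, species = NULL) {
  stopifnot(inherits(sets, "social_term_sets"))
  if (!is.null(species)) table <- table[table$species %in% species, ,
                                        drop = FALSE]
  gos <- split_go(table$go_terms)
  out <- lapply(split(seq_len(nrow(table)), table$species), function(idx) {
    row <- list(species = table$species[idx[1]])
    for (cl in names(sets$sets)) {
      set <- sets$sets[[cl]]
      row[[cl]] <- sum(vapply(gos[idx], function(g) any(g %in% set), TRUE))
    }
    row$total_cds <- length(idx)
    as.data.frame(row)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sporulation score from signature-gene hits
#'
#' Fraction of the sporulation signature genes with at least one hit at
#' e-value at or below the cutoff (the cutoff is inclusive). Gene copy
#' number is ignored: a gene hit twice counts once.
#'
#' @param hits data.frame with columns `species`, `gene`, `evalue`.
#' @param signature character vector of signature gene names (66 genes in
#'   the shipped synthetic signature, [kc_fixture()]
#'   `"sporulation_signature_synthetic.tsv"`).
#' @param evalue_cutoff inclusive e-value threshold (default `1e-10`).
#' @param species optional species subset; species present in `species`
#'   but with no hits score 0.
#' @return data.frame with columns `species`, `sporulation_score` in
#'   `[0, 1]`.
#' @export
sporulation_score <- function(hits, signature = NULL,
                              evalue_cutoff = 1e-10, species = NULL) {
  signature <- signature %||%
    read_tsv_kc(kc_fixture("sporulation_signature_synthetic.tsv"))$gene
  bad <- setdiff(unique(hits$gene), signature)
  if (length(bad))
    stop_kc("hits reference unknown signature gene(s): ",
            paste(utils::head(bad, 5), collapse = ", "),
            class = "kincoop_data_error")
  species <- species %||% unique(hits$species)
  keep <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  score <- vapply(species, function(s)
    length(unique(keep$gene[keep$species == s])) / length(signature), 0)
  data.frame(species = species, sporulation_score = score, row.names = NULL)
}

#' Assemble the per-species cooperation-counts table
#'
#' Joins secretome size, the five class counts, sporulation scores and mean
#' relative abundance into the modeling substrate: one row per species with
#' columns `species`, `secretome`, the five classes, `total_cds`, `gram`,
#' `sporulation_score`, `mean_relative_abundance`.
#'
#' @param annotations gene annotation data.frame.
#' @param sets a `social_term_sets`.
#' @param hits sporulation hit table.
#' @param signature signature gene list (default: shipped synthetic 66).
#' @param abundance optional data.frame `species`, `host`,
#'   `relative_abundance`; averaged per species. Absent -> `NA`.
#' @param evalue_cutoff inclusive e-value cutoff for sporulation hits.
#' @return data.frame of cooperation counts.
#' @export
build_cooperation_counts <- function(annotations, sets, hits,
                                     signature = NULL, abundance = NULL,
                                     evalue_cutoff = 1e-10) {
  sec <- count_secretome(annotations)
  soc <- count_cooperative_genes(annotations, sets)
  spo <- sporulation_score(hits, signature, evalue_cutoff,
                           species = sec$species)
  out <- merge(merge(sec, soc, by = "species"), spo, by = "species")
  out$mean_relative_abundance <- NA_real_
  if (!is.null(abundance)) {
    m <- tapply(abundance$relative_abundance, abundance$species, mean)
    out$mean_relative_abundance <- as.numeric(m[out$species])
  }
  cols <- c("species", "secretome", COOPERATION_CLASSES, "total_cds",
            "gram", "sporulation_score", "mean_relative_abundance")
  out[order(out$species), cols]
}
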