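# Synthesize the per-class fits: random-effects meta-analysis of the
# relatedness slopes, the reverse-causation Wald test, and the
# direct/indirect path summary. Works entirely from the fit-summary TSVs
# (standard errors recovered from CI widths) plus the stored Wald result.

source("analysis/00_config.R")

classes <- c("secretome", "biofilm", "quorum_sensing", "secretion_systems",
             "siderophores", "antibiotic_degradation")
read_fit <- function(name)
  list(summary = read.delim(file.path(FITS_DIR, paste0(name, ".tsv"))))
base <- lapply(setNames(classes, classes),
               function(cl) read_fit(paste0(cl, "_base")))
eco <- lapply(setNames(classes, classes),
              function(cl) read_fit(paste0(cl, "_eco")))
rel_fit <- read_fit("relatedness_model")
rel_rev <- read_fit("relatedness_model_reverse")
wald_tab <- read.delim(file.path(RESULTS_DIR, "wald_reverse.tsv"))
wald <- list(W = wald_tab$W, df = wald_tab$df, p = wald_tab$p)

slopes <- function(fits) {
  rows <- lapply(names(fits), function(cl) {
    s <- fits[[cl]]$summary
    s[s$term == "relatedness", c("post_mean", "ci_lower", "ci_upper")]
  })
  d <- do.call(rbind, rows)
  effect_estimates(names(fits), d$post_mean, ci_lower = d$ci_lower,
                   ci_upper = d$ci_upper)
}
meta_base <- meta_analysis(slopes(base))
meta_eco <- meta_analysis(slopes(eco))
write.table(data.frame(model = c("base", "eco"),
                       mu = c(meta_base$mu, meta_eco$mu),
                       se = c(meta_base$se, meta_eco$se),
                       z = c(meta_base$z, meta_eco$z),
                       ci_lower = c(meta_base$ci_lower, meta_eco$ci_lower),
                       ci_upper = c(meta_base$ci_upper, meta_eco$ci_upper),
                       p = c(meta_base$p, meta_eco$p),
                       tau2 = c(meta_base$tau2, meta_eco$tau2)),
            file.path(RESULTS_DIR, "meta_analysis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("overall effect of relatedness on cooperative gene content:\n")
cat(sprintf("  relatedness-only models:   mu = %.2f (SE %.2f), z = %.2f, p = %.2g\n",
            meta_base$mu, meta_base$se, meta_base$z, meta_base$p))
cat(sprintf("  ecology-controlled models: mu = %.2f (SE %.2f), z = %.2f, p = %.2g\n",
            meta_eco$mu, meta_eco$se, meta_eco$z, meta_eco$p))
cat(sprintf("  slope retained after controlling for ecology: %.0f%% of the base estimate\n",
            100 * meta_eco$mu / meta_base$mu))

ps <- path_summary(base, eco, rel_fit, rel_rev, wald)
write.table(ps$edges, file.path(RESULTS_DIR, "path_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

e <- ps$edges
cat("\npath summary:\n")
mig <- e[e$from == "migration" & e$to == "relatedness", ]
grp <- e[e$from == "group_size" & e$to == "relatedness", ]
cat(sprintf("  migration -> relatedness: %.2f (%s)\n", mig$estimate,
            mig$classification))
cat(sprintf("  group size -> relatedness: %.2f (%s)\n", grp$estimate,
            grp$classification))
for (cl in classes) {
  rc <- e[e$from == "relatedness" & e$to == cl, ]
  direct_eco <- e[e$to == cl & e$from %in% c("migration", "group_size") &
                    e$classification == "significant", "from"]
  cat(sprintf("  relatedness -> %-22s %s (beta %.2f)%s\n", cl,
              rc$classification, rc$estimate,
              if (length(direct_eco))
                paste0("; direct ecological effect: ",
                       paste(direct_eco, collapse = ", ")) else ""))
}
cat(sprintf("  reverse causation (cooperation -> relatedness): joint Wald W = %.2f, df = %d, p = %.2f\n",
            wald$W, wald$df, wald$p))
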