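# kincoop

Kin selection and cooperative gene content in host-associated microbial
communities.

## The problem

Hamilton's rule predicts that cooperation is favoured when the benefit to
recipients, weighted by their genetic relatedness to the actor, exceeds
its cost (*rb > c*). Whether this prediction holds broadly across
microbes — rather than in single-species experiments — is a comparative
question: across many bacterial species of a community such as the human
gut microbiota, does within-host relatedness predict how many cooperative
genes a genome carries?

`kincoop` implements the full comparative workflow for researchers in
microbial evolution and microbiome science:

1. **Relatedness estimation** from strain-level allele-frequency panels.
   For species *s* in host *h*, with per-site allele frequencies
   *p<sub>a</sub>* over the four nucleotides, the average genomic
   similarity at *k* core-genome sites is
   S̄ = (1/k) Σ<sub>sites</sub> Σ<sub>a</sub> p<sub>a</sub>², the
   probability that two randomly drawn haploid individuals are identical
   by state. Relatedness is the FST-like contrast of within-host against
   pooled across-host similarity:

   r<sub>s,h</sub> = (S̄<sub>s,h</sub> − S̄<sub>s</sub>) / (1 − S̄<sub>s</sub>)

   Core sites are those present in >90% of hosts (strict); species seen
   in a single host are dropped.
2. **Cooperation quantification**: secretome size (genes with predicted
   extracellular localization), five ontology-based cooperation classes
   (biofilm, quorum sensing, secretion systems, siderophores, antibiotic
   degradation; a gene counts once per class if any of its terms is in
   the curated class set), sporulation scores (fraction of a 66-gene
   signature detected at e-value ≤ 1e-10) and relative abundances.
3. **Bayesian phylogenetic mixed models** (Metropolis-within-Gibbs MCMC):
   Poisson models of class counts,
   E[Y<sub>i</sub>] = exp(β₀ + β<sub>r</sub>R<sub>i</sub> +
   β<sub>n</sub> log N<sub>i</sub> + u<sub>p,i</sub> + ε<sub>i</sub>)
   with a Brownian phylogenetic effect u<sub>p</sub> ~ MVN(0, σ²<sub>p</sub>C),
   and a Gaussian model partitioning within-host relatedness into host,
   species, phylogenetic and residual components, with sporulation
   (migration proxy) and relative abundance (group-size proxy) as
   predictors.
4. **Synthesis**: random-effects meta-analysis of the six class slopes
   (REML τ²; weights 1/(se²+τ²)), a joint Wald test for reverse
   causation, infinite-island equilibrium theory
   r = (1−m)²/(N −(N−1)(1−m)²), and a direct/indirect path summary.

A Wright–Fisher island-model simulator and annotation-table generators
provide synthetic data with known ground truth for every stage.

## Worked example

Pooling the six published per-class slopes of cooperative gene content on
relatedness, with standard errors recovered from the 95% CI widths:

```r
library(kincoop)
est <- effect_estimates(
  label = c("secretome", "siderophores", "biofilm", "quorum_sensing",
            "secretion_systems", "antibiotic_degradation"),
  estimate = c(0.59, 1.56, 1.06, 0.39, 0.48, 0.86),
  ci_lower = c(0.08, 0.42, 0.06, -1.34, -2.27, -0.26),
  ci_upper = c(1.07, 2.78, 2.10, 2.21, 3.08, 2.03))
meta_analysis(est)
#> <meta_result> mu = 0.773 (SE 0.193), z = 4.00, CI95 [0.394, 1.151], p = 6.3e-05, tau2 = 0 (REML, k = 6)
```

The pooled slope is positive and highly significant: higher relatedness
predicts more cooperative genes across cooperation classes. On the log
link, the secretome slope of 0.59 implies
`predicted_count_increase(0.59, 0.12, 0.93)` = **61.3%** more secreted
products between the least (r = 0.12) and most (r = 0.93) related
species.

The island-model simulator matches the infinite-island equilibrium:

```r
island_equilibrium_relatedness(10, 0.1)
#> [1] 0.298893
p <- island_model_params(n_demes = 20, deme_size = 10, migration = 0.1,
                         mutation = 1e-4, n_sites = 500,
                         n_generations = 500, seed = 1)
rt <- build_relatedness_table(simulate_island_model(p), correct = TRUE)
rt$summary$mean_r
#> [1] 0.2857732
```

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
with known ground truth, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_community.R   # island-model panels, gene tables, tree
Rscript analysis/02_relatedness.R          # per species x host relatedness
Rscript analysis/03_traits.R               # six cooperation classes + sporulation
Rscript analysis/04_fit_models.R           # 14 phylogenetic mixed models
Rscript analysis/05_synthesis.R            # meta-analysis, Wald test, path summary
```

`run_pipeline(pipeline_config(...))` performs the same end-to-end run as
a single call, in synthetic or tables mode.

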