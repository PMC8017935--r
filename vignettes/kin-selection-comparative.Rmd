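---
title: "Methods: comparative analysis of kin selection in microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of kin selection in microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kincoop)
```

This vignette documents the models, estimators and design decisions
behind `kincoop`, in the spirit of a methods supplement: what each stage
assumes, which knobs matter, and what the synthetic validation does and
does not establish.

## 1. Relatedness from metagenomic allele frequencies

The unit of observation is a species-by-host allele-frequency panel:
frequencies of A/C/G/T at each core-genome site, estimated from reads
mapped within one host, plus a presence mask and depth. The genomic
similarity

$$\bar S = \frac{1}{k}\sum_{\text{sites}}\sum_{a} p_a^2$$

is the probability that two haploid individuals drawn at random (with
replacement) are identical by state, i.e. one minus the mean per-site
genetic diversity. Relatedness of the subpopulation in host $h$ is the
FST-like quantity

$$r_{s,h} = \frac{\bar S_{s,h} - \bar S_s}{1 - \bar S_s},$$

where $\bar S_s$ is computed from frequencies pooled across hosts. It is
the statistical association between interacting cells relative to the
population average — Hamilton's regression definition of relatedness,
not a pedigree quantity.

Decisions worth knowing:

* **Core sites are strict**: a site must be present in *more than*
  `prevalence_threshold` (default 0.90) of the hosts; 9 of 10 hosts does
  not qualify. Species in fewer than `min_hosts = 2` hosts carry no
  across-host contrast and are dropped (logged, never silent), as are
  species with fewer than `min_core_sites = 100` core sites — the
  threshold is parameterised because the excluded-species rule it mimics
  was qualitative ("very small core genome").
* **Pooling is depth-weighted** by default (`pool_weights = "depth"`),
  mirroring read pooling across samples; an unweighted option exists.
  Whether reference pipelines weight hosts by depth or equally is not
  documented anywhere we trust, so the choice is ours and recorded here.
* **With-replacement vs corrected similarity.** $\sum_a p_a^2$ is the
  plug-in (with-replacement) estimator; when a frequency is backed by $n$
  sampled individuals it is inflated by the self-pair term $1/n$. With
  sequencing-depth-backed frequencies ($n$ in the hundreds) this is
  negligible and the plug-in form is the default. For simulated demes of
  size 10 it is not negligible, so the finite-sample correction
  $(n\sum p_a^2 - 1)/(n-1)$ is available (`correct = TRUE`) and is what
  the island-model validation uses; the `depth` field then carries the
  number of haploid individuals.
* Within-host similarity for host $h$ uses only the core sites present
  in $h$ (partial presence is tolerated to maximise data use); per-species
  mean relatedness is the unweighted arithmetic mean over hosts.
* A species monomorphic at every core site across all hosts has
  $\bar S_s = 1$ and undefined relatedness; it is dropped with a logged
  reason rather than returned as NaN.

## 2. The Wright–Fisher island model

`simulate_island_model()` runs a haploid metapopulation: `n_demes` demes
(hosts) of constant size $N$, unlinked 4-state sites, discrete
generations. Each offspring draws its parent from its own deme with
probability $1-m$ and from the pooled metapopulation otherwise, then
mutates to one of the other three nucleotides with total probability
$\mu$. Resampling is multinomial per site (implemented as vectorised
sequential binomials); sites are exchangeable and unlinked by design —
no linkage, no selection, no read-level noise.

The classical infinite-island identity-by-descent equilibrium

$$r = \frac{(1-m)^2}{N - (N-1)(1-m)^2}$$

(`island_equilibrium_relatedness()`) decreases in both deme size and
migration. Because the source text for this equilibrium is cited rather
than printed in the study this package follows, the simulator — not the
formula — is treated as the source of truth: the analysis scripts map
theory against simulation over a grid of $(m, N)$ and the acceptance
suite requires agreement within three Monte-Carlo standard errors of the
across-deme mean at $N = 10$, $m = 0.1$.

Two systematic departures are expected and documented rather than hidden:
the plug-in similarity overestimates relatedness by roughly $1/N$ at
small deme sizes (hence the corrected estimator in validation runs), and
with a finite number of demes the pooled "population" contains the focal
deme and its relatives, depressing the measured value by order $1/d$
(about 0.01 at 20 demes). The burn-in heuristic is $10N$ generations
before reading off frequencies; mutation and drift parameters are free
because the study conditions behind the published theory curves are not
stated.

## 3. Cooperation traits

* **Secretome size** counts genes whose product has a predicted
  extracellular final localization. The gram profile must be present
  (localization prediction depends on it) and constant within a species;
  it later enters the secretome model as an intercept shift.
* **Social ontology term sets.** From a term graph (TSV: `term_id`,
  `name`, `parent_ids`), `build_social_term_sets()` keyword-matches term
  *names* (case-insensitive substring; definitions are not searched),
  then adds **all descendants** (transitive — ontology annotations
  propagate downward; a `descendants = "direct"` flag restricts to
  direct children) and the **direct parents** of matched terms, then
  applies a manual curation list. Provenance per term
  (keyword-matched / child / parent / curated-in / curated-out) is
  retained. The specificity burden sits in curation: "extracellular
  polysaccharide production" is confidently social, bare "polysaccharide
  production" is not.
* **Class counts**: a gene counts once toward a class if *any* of its
  terms is in the class set, and may count toward several classes.
* **Sporulation score** = fraction of the 66 signature genes with at
  least one hit at e-value $\le$ 1e-10. The cutoff is read inclusively
  (a hit at exactly 1e-10 counts); copy number is ignored.
* The shipped 118-term curated list (48 biofilm, 5 quorum sensing, 11
  secretion systems, 29 siderophores, 25 antibiotic degradation) and the
  66-gene signature are **synthetic stand-ins** with the published class
  sizes (`inst/extdata/*_synthetic.tsv`); real curated lists can be
  dropped in via the same TSV schema. Upstream annotation-resolution
  steps (hit ranking across ontologies, localization prediction, BLAST
  execution) are out of scope: the package consumes resolved tables.

## 4. Phylogenetic mixed models

Counts for class $Y$ follow a log-link Poisson model

$$E[Y_i] = \exp\!\big(\beta_0 + \beta_r R_i + \beta_n \log N_i +
u_{p,i} + \varepsilon_i\big),$$

with $R_i$ mean relatedness, $N_i$ the CDS count *not* in the class
(total CDS − $Y_i$; the log term absorbs nonlinear scaling of gene
content with genome size), $u_p \sim \mathrm{MVN}(0, \sigma^2_p C)$ a
Brownian phylogenetic effect, and an observation-level residual
$\varepsilon$ acting as overdispersion (with one observation per species
it doubles as the non-phylogenetic interspecies variance). The
ecology-controlled variant adds mean relative abundance and sporulation
score; the secretome model adds a gram-profile intercept. The Gaussian
relatedness model partitions within-host relatedness into host, species
(iid), species (phylogenetic) and residual components with abundance and
sporulation as fixed effects; the reverse-causation variant adds the six
class counts (scaled per 1,000 genes) as predictors.

$C$ is the shared-path-length (Brownian) covariance of an ultrametric
tree (`phylo_covariance()`, ultrametricity enforced at tolerance 1e-6;
non-ultrametric input is an error, not silently smoothed) and is scaled
to unit diagonal before fitting so $\sigma^2_p$ is comparable across
trees (raw option retained).

**Sampler.** Metropolis-within-Gibbs, written for this model family:

* each latent log-rate gets a univariate random-walk Metropolis step,
  vectorised over species, with per-observation step sizes adapted
  toward 0.44 acceptance during burn-in only;
* $(\beta, u)$ updates are exact conjugate normals given the latents.
  The phylogenetic block is diagonalised once in the eigenbasis of $C$,
  making its update $O(n^2)$ per iteration with no repeated
  factorisations;
* variances are conjugate inverse-gamma under the univariate
  inverse-Wishart prior ($V = 1$, $\nu = 0.002$, the conventional weakly
  informative choice). The Gaussian model's random-effect variances can
  instead use a parameter-expanded prior ($V = 1$, $\nu = 1$, working
  parameter $\alpha \sim N(0, 1000)$), which mixes better near zero and
  is the default there; the residual variance always keeps the
  inverse-Wishart form. Fixed effects get $N(0, 10^{10})$.

Defaults are desk-scale — 50,000 iterations, burn-in 5,000, thinning 10,
two chains; `mcmc_settings(preset = "paper")` selects the reference
long-run settings (10⁶ iterations, thinning 50). The analysis scripts use
20,000-iteration chains on 20 species, which the convergence diagnostics
accept (max PSRF 1.02 across all fits in the shipped run); tests use
shorter chains on smaller problems sized to keep the whole suite under a
few minutes. Significance of fixed effects is reported as PMCMC — twice
the smaller posterior tail mass across zero, capped at one. This
sign-symmetric form equals "twice the posterior probability that the
estimate is negative" for positive estimates (the phrasing that assumes
positive effects) and behaves correctly for negative ones; that
divergence is deliberate. The Gelman–Rubin PSRF is computed per
parameter on two or more chains and anything above 1.1 raises a warning,
never silently.

Degenerate designs are detected, not patched: a constant predictor (or
any near-collinear design) triggers a warning and its coefficient simply
follows its diffuse prior, yielding PMCMC near 1. Sampler correctness is
established by three oracles in the test suite: agreement with IRLS
(`glm`) on star trees with variances pinned small, 95%-CI coverage of a
known slope across 20 simulated comparative datasets, and recovery of a
known host/species/residual variance partition.

## 5. Synthesis

* **Meta-analysis** pools the six per-class relatedness slopes under
  $y_i = \mu + m_i + \epsilon_i$ with known measurement SEs and
  between-class heterogeneity $\tau^2$ estimated by REML (the reference
  ecosystem default; DerSimonian–Laird and a fixed-effect $\tau^2 = 0$
  variant are options). Implementation is delegated to `metafor::rma`;
  the fixed-effect limit is cross-checked against the hand-computed
  inverse-variance mean in the tests. When only credible intervals are
  printed, SEs are recovered as width/3.92 (symmetric normal
  approximation) — the documented route for reproducing the published
  pooled effect from main-text numbers; posterior SDs are used when
  draws are available.
* **Reverse causation** is assessed per coefficient (PMCMC) and jointly:
  $W = b^\top V^{-1} b$ on the posterior mean and covariance of the six
  count coefficients, against $\chi^2_6$.
* **Path summary** classifies edges at PMCMC < 0.05 (significant) and
  0.05–0.10 ("marginal", mirroring the language used for relative
  abundance): ecology → relatedness from the Gaussian fit; relatedness →
  cooperation from the ecology-controlled count fits, with the relative
  slope change against the ecology-free fit reported (`slope_shift`, the
  "similar effect size" check); ecology → cooperation direct edges from
  the same fits; and cooperation → relatedness reverse edges plus the
  joint Wald. An ecological factor is *indirect* for a class when it
  predicts relatedness and relatedness predicts that class.

## 6. The synthetic study conditions

The generators exist so every stage can be validated against known
truth, and their defaults are the package's study conditions:

* `simulate_comparative_dataset()`: coalescent (hence ultrametric) trees
  rescaled to depth 1; mean relatedness simulated as Brownian motion on
  the logit scale and mapped into [0.1, 0.95] (bounded without
  truncation artifacts); genome sizes log-normal around 3,000 CDS (sd
  0.3 on the log scale, a realistic bacterial spread); counts Poisson
  with the stated log-link model, $C$ unit-diagonal so the simulated
  $\sigma^2_p$ is on the residual scale.
* The pipeline's synthetic world wires the causal chain the path
  analysis is meant to detect: per-species migration rates equally
  spaced over [0.02, 0.5] (island equilibria r ≈ 0.71 down to 0.03 at
  deme size 10), sporulation-gene presence increasing with migration,
  and per-class annotation probabilities scaling as
  $\exp(2 \cdot r)$ — a strong, detectable slope at 20 species. Relative
  abundance is generated independently of deme size, so the synthetic
  world contains *no* group-size effect by construction.
* What the synthetic data deliberately lack: read-level sequencing error
  and coverage variation, linkage between sites, selection,
  between-class correlation of gene content beyond shared relatedness,
  compositional coupling between abundance and population size, and
  phylogenetic signal in relatedness arising from the island model
  (migration rates are assigned independently of the tree). Passing
  tests therefore demonstrate estimator and sampler correctness under
  the stated population-genetic model — not robustness to the
  quality-control realities of real metagenomes, which are upstream of
  this package's inputs.

## 7. Numerical choices and degenerate inputs

* Eigenvalues of $C$ are floored at 1e-10; trees whose covariance is
  materially non-PSD are a simulation error.
* Chain bookkeeping is exact: retained draws =
  `n_chains * floor((n_iterations - burn_in) / thinning)`; chain $c$
  seeds the RNG with `seed + c - 1`; the pipeline fans a single global
  seed into fixed per-stage offsets so stages can be rerun in isolation.
* Credible intervals are equal-tailed (2.5%, 97.5%) quantiles.
* Similarity requires at least one usable site; corrected similarity
  requires depth ≥ 2 everywhere it is applied; a pooled site where all
  depths are zero is a data error.
* Ties in the major-allele column of panel TSVs break toward A < C < G
  < T order; the column is informational only.
* `wald_joint_test` refuses singular covariance with the condition
  number in the error message rather than pseudo-inverting.

## 8. Known limitations

* Relatedness point estimates enter the count models without their
  sampling uncertainty; the bivariate measurement-error formulation is
  intentionally out of scope.
* One observation per species makes $\sigma^2_e$ and true overdispersion
  indistinguishable in the Poisson models, and the iid-species vs
  phylogenetic variance split in the Gaussian model is weakly identified
  with a single panel per species-host; their sum is the robust
  quantity.
* The single-sampler design (no alternative evolution models such as
  Ornstein–Uhlenbeck, no within-species trees) matches the scope of the
  comparative question; extending the covariance model would require new
  oracles.
* Shipped ontology/signature fixtures are synthetic; conclusions about
  real communities require real curated lists and real panels supplied
  through the tables mode.
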