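#' Parameters for the Wright-Fisher island-model simulator
#'
#' A haploid metapopulation of `n_demes` demes (hosts) of `deme_size`
#' individuals each, evolving by multinomial Wright-Fisher resampling at
#' `n_sites` unlinked 4-state sites. Each offspring draws its parent from
#' its own deme with probability `1 - migration` and from the pooled
#' metapopulation otherwise (infinite-island style migrant pool), then
#' mutates to one of the three other nucleotides with total probability
#' `mutation`.
#'
#' @param n_demes number of demes (hosts).
#' @param deme_size haploid individuals per deme (the "group size" N).
#' @param migration per-individual per-generation migration probability m.
#' @param mutation per-site per-generation mutation probability.
#' @param n_sites number of unlinked sites.
#' @param n_generations generations to run; quasi-equilibrium needs roughly
#'   `10 * deme_size` generations of burn-in plus mixing time, which is the
#'   caller's responsibility.
#' @param seed integer RNG seed.
#' @return A list of class `island_model_params`.
#' @export
island_model_params <- function(n_demes, deme_size, migration, mutation,
                                n_sites, n_generations, seed = 1L) {
  assert_count(n_demes, "n_demes")
  assert_count(deme_size, "deme_size")
  assert_prob(migration, "migration")
  assert_prob(mutation, "mutation")
  assert_count(n_sites, "n_sites")
  assert_count(n_generations, "n_generations", min = 0L)
  structure(list(n_demes = as.integer(n_demes),
                 deme_size = as.integer(deme_size),
                 migration = migration, mutation = mutation,
                 n_sites = as.integer(n_sites),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed)),
            class = "island_model_params")
}

# Multinomial(N, prob rows) for every row of an L x 4 probability matrix,
# via sequential binomials (vectorised over sites).
rmultinom_rows <- function(N, prob) {
  L <- nrow(prob)
  rem <- rep.int(N, L)
  out <- matrix(0L, L, 4L)
  tail_p <- prob[, 4L] + prob[, 3L] + prob[, 2L] + prob[, 1L]
  for (a in 1:3) {
    pr <- ifelse(tail_p > 0, prob[, a] / tail_p, 0)
    x <- rbinom(L, rem, pmin(pmax(pr, 0), 1))
    out[, a] <- x
    rem <- rem - x
    tail_p <- tail_p - prob[, a]
  }
  out[, 4L] <- rem
  out
}

#' Simulate an island-model allele-frequency panel
#'
#' Runs the haploid Wright-Fisher island model described in
#' [island_model_params()] and returns the final-generation allele
#' frequencies per deme as an allele-frequency panel, with `depth` set to
#' the deme size (so downstream sample-size corrections know how many
#' haploid individuals back each frequency).
#'
#' @param params an `island_model_params` object.
#' @param species species label attached to the panel.
#' @param init `"polymorphic"` (default) starts every deme from a shared
#'   per-site Dirichlet(1,1,1,1) frequency vector; `"monomorphic"` fixes a
#'   random allele per site metapopulation-wide; or a `n_sites x 4`
#'   frequency matrix.
#' @return An [allele_frequency_panel()] (`afp`) with one host per deme.
#' @export
simulate_island_model <- function(params, species = "sim_species",
                                  init = "polymorphic") {
  stopifnot(inherits(params, "island_model_params"))
  set.seed(params$seed)
  D <- params$n_demes; N <- params$deme_size; L <- params$n_sites
  m <- params$migration; mu <- params$mutation

  if (is.matrix(init)) {
    p0 <- init
    if (!all(dim(p0) == c(L, 4L)))
      stop_kc("init matrix must be n_sites x 4", class = "kincoop_parameter_error")
  } else if (identical(init, "polymorphic")) {
    p0 <- matrix(rgamma(L * 4L, 1), L, 4L)
    p0 <- p0 / rowSums(p0)
  } else if (identical(init, "monomorphic")) {
    p0 <- matrix(0, L, 4L)
    p0[cbind(seq_len(L), sample.int(4L, L, replace = TRUE))] <- 1
  } else stop_kc("unknown init: ", init, class = "kincoop_parameter_error")

  # counts[d, , ]: L x 4 allele counts in deme d
  counts <- array(0L, c(D, L, 4L))
  for (d in seq_len(D)) counts[d, , ] <- rmultinom_rows(N, p0)

  if (params$n_generations > 0L) {
    for (g in seq_len(params$n_generations)) {
      pool <- apply(counts, c(2, 3), sum) / (D * N)
      for (d in seq_len(D)) {
        pm <- (1 - m) * (counts[d, , ] / N) + m * pool
        pi_off <- (1 - mu) * pm + (mu / 3) * (1 - pm)
        counts[d, , ] <- rmultinom_rows(N, pi_off)
      }
    }
  }

  freqs <- counts / N
  allele_frequency_panel(species, freqs,
                         depth = matrix(N, D, L),
                         hosts = sprintf("deme%03d", seq_len(D)))
}
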