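#' Prior specification for phylogenetic mixed models
#'
#' Variance components get a univariate inverse-Wishart prior (scale `V`,
#' degree of belief `nu`; equivalently inverse-gamma with shape `nu/2` and
#' rate `nu * V / 2`). The defaults `V = 1, nu = 0.002` are the
#' conventional weakly informative choice. Setting `px = TRUE` switches the
#' non-residual variance components to a parameter-expanded prior
#' (`V = 1, nu = 1`, working parameter `alpha ~ N(alpha_mu, alpha_V)` with
#' `alpha_V = 1000`), which mixes better near zero. Fixed effects are
#' `N(0, fixed_effect_variance)` with the conventional diffuse `1e10`.
#'
#' @param V,nu inverse-Wishart scale and degree of belief.
#' @param px use the parameter-expanded prior for random-effect variances.
#' @param alpha_mu,alpha_V working-parameter prior (PX only).
#' @param fixed_effect_variance prior variance of fixed effects.
#' @param fix optional named list fixing variance components to constants
#'   instead of sampling them, e.g. `list(phylo = 1e-2, resid = 1e-2)`
#'   (names among `phylo`, `resid`, `host`, `species`).
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(V = 1, nu = 0.002, px = FALSE, alpha_mu = 0,
                       alpha_V = 1000, fixed_effect_variance = 1e10,
                       fix = NULL) {
  if (nu <= 0 || V <= 0)
    stop_kc("V and nu must be > 0", class = "kincoop_parameter_error")
  structure(list(V = V, nu = nu, px = px, alpha_mu = alpha_mu,
                 alpha_V = alpha_V,
                 fixed_effect_variance = fixed_effect_variance,
                 fix = fix),
            class = "prior_spec")
}

#' MCMC chain settings
#'
#' Desk-scale defaults (50,000 iterations, burn-in 5,000, thinning 10, two
#' chains); `preset = "paper"` selects the reference long-run settings of
#' 1,000,000 iterations, burn-in 5,000, thinning 50.
#'
#' @param n_iterations,burn_in,thinning,n_chains chain bookkeeping; the
#'   number of retained draws is
#'   `n_chains * floor((n_iterations - burn_in) / thinning)`.
#' @param seed RNG seed (chain c uses `seed + c - 1`).
#' @param preset `"desk"` (default) or `"paper"`.
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iterations = 50000L, burn_in = 5000L,
                          thinning = 10L, n_chains = 2L, seed = 1L,
                          preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_iterations <- 1000000L; burn_in <- 5000L; thinning <- 50L
  }
  if (burn_in >= n_iterations)
    stop_kc("burn_in must be < n_iterations", class = "kincoop_parameter_error")
  if (thinning < 1L)
    stop_kc("thinning must be >= 1", class = "kincoop_parameter_error")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_settings")
}

n_retained <- function(mcmc) {
  mcmc$n_chains * ((mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thinning)
}

# shared: inverse-gamma variance update under IW(V, nu), or fixed value
update_variance <- function(ss, df, prior, fixed) {
  if (!is.null(fixed)) return(fixed)
  rinvgamma1((prior$nu + df) / 2, (prior$nu * prior$V + ss) / 2)
}

# group sums over 1..n groups, including empty groups
group_sum <- function(x, idx, n) {
  t <- rowsum(x, idx)
  out <- numeric(n)
  out[as.integer(rownames(t))] <- t
  out
}

check_collinear <- function(X) {
  sv <- svd(scale(X, center = FALSE, scale = FALSE), nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-8)
    warning("design matrix is (nearly) collinear; affected coefficients ",
            "are unidentifiable and their posteriors follow the prior",
            call. = FALSE)
}

summarize_fit <- function(chains, fixed_names, mcmc, prior, model) {
  all_draws <- do.call(rbind, chains)
  terms <- colnames(all_draws)
  summ <- data.frame(
    term = terms,
    post_mean = colMeans(all_draws),
    ci_lower = apply(all_draws, 2, quantile, 0.025),
    ci_upper = apply(all_draws, 2, quantile, 0.975),
    pmcmc = NA_real_, row.names = NULL)
  for (tm in fixed_names)
    summ$pmcmc[summ$term == tm] <- pmcmc(all_draws[, tm])
  psrf <- if (length(chains) >= 2L) gelman_rubin(chains) else NULL
  if (!is.null(psrf) && any(psrf > 1.1, na.rm = TRUE))
    warning("convergence suspect: PSRF > 1.1 for ",
            paste(names(psrf)[which(psrf > 1.1)], collapse = ", "),
            call. = FALSE)
  structure(list(summary = summ, draws = chains, psrf = psrf,
                 mcmc = mcmc, prior = prior, model = model,
                 fixed_names = fixed_names),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("<phylo_fit> %s model, %d chains x %d retained draws\n",
              x$model, length(x$draws), nrow(x$draws[[1]])))
  print(x$summary, digits = 3)
  if (!is.null(x$psrf))
    cat(sprintf("max PSRF: %.3f\n", max(x$psrf, na.rm = TRUE)))
  invisible(x)
}

#' Bayesian phylogenetic Poisson mixed model
#'
#' Log-link Poisson regression of per-species counts with a Brownian
#' phylogenetic random effect and an observation-level (overdispersion)
#' residual: `E[y_i] = exp(x_i' beta + u_i + e_i)`,
#' `u ~ MVN(0, s2_phylo * C)`, `e ~ N(0, s2_resid * I)`. Sampled by
#' Metropolis-within-Gibbs: adaptive univariate random-walk Metropolis on
#' each latent log-rate, conjugate normal updates for `beta` and `u`
#' (diagonalised in the eigenbasis of `C`), and inverse-gamma updates for
#' the variances.
#'
#' @param y nonnegative integer counts, one per species.
#' @param X fixed-effect design matrix (rows aligned to `y` and `C`);
#'   typically intercept, relatedness, log genome size, optional ecological
#'   covariates and gram intercept.
#' @param C phylogenetic covariance from [phylo_covariance()], rows/cols
#'   aligned to `y`.
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param scale_C scale `C` to unit diagonal before fitting (default TRUE)
#'   so `s2_phylo` is comparable across trees.
#' @return A `phylo_fit`: posterior draws per chain, summary table (term,
#'   posterior mean, equal-tailed 95% CI, PMCMC for fixed effects), PSRF
#'   per parameter when 2+ chains.
#' @export
fit_poisson_pmm <- function(y, X, C, prior = prior_spec(),
                            mcmc = mcmc_settings(), scale_C = TRUE) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (any(y < 0) || any(y != round(y)))
    stop_kc("y must be nonnegative integer counts",
            class = "kincoop_data_error")
  if (nrow(X) != n || nrow(C) != n)
    stop_kc("X and C must align with y", class = "kincoop_data_error")
  check_collinear(X)
  if (scale_C) C <- C / mean(diag(C))
  eC <- eigen(C, symmetric = TRUE)
  lam <- pmax(eC$values, 1e-10)
  Q <- eC$vectors
  fixed_names <- colnames(X) %||% paste0("b", seq_len(p))
  fix_p <- prior$fix$phylo; fix_e <- prior$fix$resid
  B <- prior$fixed_effect_variance

  run_chain <- function(chain) {
    set.seed(mcmc$seed + chain - 1L)
    eta <- log(y + 0.5)
    beta <- rep(0, p); z <- rep(0, n); u <- rep(0, n)
    sp2 <- fix_p %||% 1; se2 <- fix_e %||% 1
    step <- rep(0.5, n); acc <- rep(0, n)
    keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thinning
    draws <- matrix(NA_real_, keep,  p + 2L,
                    dimnames = list(NULL, c(fixed_names, "var_phylo",
                                            "var_resid")))
    k <- 0L
    XtX <- crossprod(X)
    for (it in seq_len(mcmc$n_iterations)) {
      mu_eta <- drop(X %*% beta) + u
      # latent log-rates: vectorised random-walk Metropolis
      prop <- eta + step * rnorm(n)
      logr <- y * (prop - eta) - (exp(prop) - exp(eta)) -
        ((prop - mu_eta)^2 - (eta - mu_eta)^2) / (2 * se2)
      ok <- log(runif(n)) < logr
      eta[ok] <- prop[ok]
      acc <- acc + ok
      if (it <= mcmc$burn_in && it %% 25L == 0L) {
        step <- step * exp(pmin(pmax(acc / 25 - 0.44, -0.5), 0.5))
        acc[] <- 0
      }
      # beta | eta, u
      prec <- XtX / se2 + diag(1 / B, p)
      ch <- chol(prec)
      mean_b <- backsolve(ch, forwardsolve(t(ch), crossprod(X, eta - u) / se2))
      beta <- drop(mean_b + backsolve(ch, rnorm(p)))
      # u | eta, beta via z = Q'u (diagonal posterior in eigenbasis)
      w <- drop(crossprod(Q, eta - X %*% beta))
      vz <- 1 / (1 / se2 + 1 / (sp2 * lam))
      z <- vz * w / se2 + sqrt(vz) * rnorm(n)
      u <- drop(Q %*% z)
      # variances
      sp2 <- update_variance(sum(z^2 / lam), n, prior, fix_p)
      se2 <- update_variance(sum((eta - X %*% beta - u)^2), n, prior, fix_e)
      if (it > mcmc$burn_in &&
          (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
        k <- k + 1L
        draws[k, ] <- c(beta, sp2, se2)
      }
    }
    draws
  }
  chains <- lapply(seq_len(mcmc$n_chains), run_chain)
  summarize_fit(chains, fixed_names, mcmc, prior, "poisson")
}

#' Bayesian Gaussian phylogenetic mixed model of within-host relatedness
#'
#' `r_obs = X beta + u_host + u_species + u_phylo + e` with iid host and
#' species effects, a Brownian phylogenetic species effect with covariance
#' `s2_phylo * C`, and iid residual. All updates are conjugate
#' (Gibbs); random-effect variances optionally use the parameter-expanded
#' prior of [prior_spec()] (`px = TRUE`), the residual always the
#' inverse-Wishart form.
#'
#' @param y observed relatedness, one per (species, host) observation.
#' @param X fixed-effect design (e.g. intercept, relative abundance,
#'   sporulation score, optionally the six cooperation counts for the
#'   reverse-causation variant).
#' @param species,host factors/character aligned to `y`; every species
#'   must be a row of `C`.
#' @param C phylogenetic covariance over the modelled species.
#' @param prior a [prior_spec()] (set `px = TRUE` for the parameter-
#'   expanded random-effect prior).
#' @param mcmc an [mcmc_settings()].
#' @param scale_C scale `C` to unit diagonal (default TRUE).
#' @return A `phylo_fit` with fixed effects plus `var_host`, `var_species`,
#'   `var_phylo`, `var_resid`.
#' @export
fit_gaussian_pmm <- function(y, X, species, host, C,
                             prior = prior_spec(px = TRUE),
                             mcmc = mcmc_settings(), scale_C = TRUE) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  species <- as.character(species); host <- as.character(host)
  if (nrow(X) != n || length(species) != n || length(host) != n)
    stop_kc("X, species, host must align with y", class = "kincoop_data_error")
  sp_levels <- rownames(C)
  if (is.null(sp_levels)) stop_kc("C needs species dimnames",
                                  class = "kincoop_data_error")
  missing_sp <- setdiff(unique(species), sp_levels)
  if (length(missing_sp))
    stop_kc("species absent from tree/covariance: ",
            paste(missing_sp, collapse = ", "), class = "kincoop_data_error")
  check_collinear(X)
  if (scale_C) C <- C / mean(diag(C))
  ho_levels <- sort(unique(host))
  si <- match(species, sp_levels); hi <- match(host, ho_levels)
  ns <- length(sp_levels); nh <- length(ho_levels)
  n_per_s <- tabulate(si, ns); n_per_h <- tabulate(hi, nh)
  Cinv <- solve(C + diag(1e-10, ns))
  fixed_names <- colnames(X) %||% paste0("b", seq_len(p))
  B <- prior$fixed_effect_variance
  XtX <- crossprod(X)
  fix <- prior$fix %||% list()

  # PX blocks: u = alpha * v; effective variance alpha^2 * phi
  px <- isTRUE(prior$px)
  nu_rand <- if (px) 1 else prior$nu

  run_chain <- function(chain) {
    set.seed(mcmc$seed + chain - 1L)
    beta <- rep(0, p)
    uh <- rep(0, nh); us <- rep(0, ns); up <- rep(0, ns)
    ah <- 1; as_ <- 1; ap <- 1                    # PX working parameters
    ph_h <- 1; ph_s <- 1; ph_p <- 1               # PX base variances
    se2 <- var(y) %||% 1
    keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thinning
    cn <- c(fixed_names, "var_host", "var_species", "var_phylo", "var_resid")
    draws <- matrix(NA_real_, keep, length(cn), dimnames = list(NULL, cn))
    k <- 0L
    for (it in seq_len(mcmc$n_iterations)) {
      xb <- drop(X %*% beta)
      # host block
      res <- y - xb - us[si] - up[si]
      s2h <- if (px) ah^2 * ph_h else ph_h
      vh <- 1 / (n_per_h / se2 + 1 / max(s2h, 1e-12))
      uh <- vh * (group_sum(res, hi, nh) / se2) + sqrt(vh) * rnorm(nh)
      # species iid block
      res <- y - xb - uh[hi] - up[si]
      s2s <- if (px) as_^2 * ph_s else ph_s
      vs <- 1 / (n_per_s / se2 + 1 / max(s2s, 1e-12))
      us <- vs * (group_sum(res, si, ns) / se2) + sqrt(vs) * rnorm(ns)
      # phylogenetic species block (dense precision, ns x ns)
      res <- y - xb - uh[hi] - us[si]
      s2p <- if (px) ap^2 * ph_p else ph_p
      prec <- diag(n_per_s / se2, ns) + Cinv / max(s2p, 1e-12)
      ch <- chol(prec)
      mean_p <- backsolve(ch, forwardsolve(t(ch), group_sum(res, si, ns) / se2))
      up <- drop(mean_p + backsolve(ch, rnorm(ns)))
      # fixed effects
      res <- y - uh[hi] - us[si] - up[si]
      precb <- XtX / se2 + diag(1 / B, p)
      chb <- chol(precb)
      mb <- backsolve(chb, forwardsolve(t(chb), crossprod(X, res) / se2))
      beta <- drop(mb + backsolve(chb, rnorm(p)))
      # variances
      if (px) {
        # working parameters: one scalar regression each
        upd_alpha <- function(v, map, resid_minus) {
          zz <- v[map]
          prec_a <- sum(zz^2) / se2 + 1 / prior$alpha_V
          ma <- (sum(zz * resid_minus) / se2 + prior$alpha_mu / prior$alpha_V) /
            prec_a
          rnorm(1, ma, sqrt(1 / prec_a))
        }
        xb <- drop(X %*% beta)
        vh_ <- uh / ah; vs_ <- us / as_; vp_ <- up / ap
        ah <- upd_alpha(vh_, hi, y - xb - us[si] - up[si])
        uh <- ah * vh_
        as_ <- upd_alpha(vs_, si, y - xb - uh[hi] - up[si])
        us <- as_ * vs_
        ap <- upd_alpha(vp_, si, y - xb - uh[hi] - us[si])
        up <- ap * vp_
        ph_h <- update_variance(sum(vh_^2), nh, prior_spec(V = 1, nu = 1),
                                fix$host)
        ph_s <- update_variance(sum(vs_^2), ns, prior_spec(V = 1, nu = 1),
                                fix$species)
        ph_p <- update_variance(drop(vp_ %*% Cinv %*% vp_), ns,
                                prior_spec(V = 1, nu = 1), fix$phylo)
        s2h <- ah^2 * ph_h; s2s <- as_^2 * ph_s; s2p <- ap^2 * ph_p
        if (!is.null(fix$host)) { s2h <- fix$host; ah <- 1; ph_h <- s2h }
        if (!is.null(fix$species)) { s2s <- fix$species; as_ <- 1; ph_s <- s2s }
        if (!is.null(fix$phylo)) { s2p <- fix$phylo; ap <- 1; ph_p <- s2p }
      } else {
        ph_h <- update_variance(sum(uh^2), nh, prior, fix$host)
        ph_s <- update_variance(sum(us^2), ns, prior, fix$species)
        ph_p <- update_variance(drop(up %*% Cinv %*% up), ns, prior,
                                fix$phylo)
        s2h <- ph_h; s2s <- ph_s; s2p <- ph_p
      }
      res <- y - drop(X %*% beta) - uh[hi] - us[si] - up[si]
      se2 <- update_variance(sum(res^2), n, prior, fix$resid)
      if (it > mcmc$burn_in &&
          (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
        k <- k + 1L
        draws[k, ] <- c(beta, s2h, s2s, s2p, se2)
      }
    }
    draws
  }
  chains <- lapply(seq_len(mcmc$n_chains), run_chain)
  summarize_fit(chains, fixed_names, mcmc, prior, "gaussian")
}

#' Posterior MCMC significance of a coefficient
#'
#' Twice the smaller posterior tail mass on either side of zero, capped at
#' one: `2 * min(Pr(draws < 0), Pr(draws > 0))`. For positive estimates
#' this equals twice the posterior probability that the estimate is
#' negative; the sign-symmetric form also behaves correctly for negative
#' estimates. Stable interpretation needs on the order of 100+ retained
#' draws.
#'
#' @param draws numeric vector of posterior draws of one coefficient.
#' @return p-value-like quantity in `[0, 1]`.
#' @export
pmcmc <- function(draws) {
  min(1, 2 * min(mean(draws < 0), mean(draws > 0)))
}

#' Gelman-Rubin potential scale-reduction factor
#'
#' Standard PSRF from 2+ equal-length chains:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B/n` the variance of chain means. Values near 1 indicate the
#' chains agree; the pipeline flags parameters above 1.1.
#'
#' @param chains list of draw matrices (iterations x parameters) or
#'   numeric vectors, equal lengths, post burn-in.
#' @return Named vector of PSRF per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop_kc("Gelman-Rubin needs >= 2 chains", class = "kincoop_diagnostic_error")
  chains <- lapply(chains, function(x) if (is.null(dim(x))) cbind(par = x) else x)
  n <- unique(vapply(chains, nrow, 0L))
  if (length(n) != 1L)
    stop_kc("chains must have equal length", class = "kincoop_diagnostic_error")
  m <- length(chains)
  params <- colnames(chains[[1]])
  vapply(setNames(params, params), function(pm) {
    x <- vapply(chains, function(ch) ch[, pm], numeric(n))
    W <- mean(apply(x, 2, var))
    Bn <- var(colMeans(x))            # = B/n
    if (W < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + Bn) / W)
  }, 0)
}
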