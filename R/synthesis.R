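#' Effect estimates for meta-analysis
#'
#' One per cooperation class: the posterior slope of log gene count on mean
#' relatedness with its standard error. When only a 95% interval is
#' printed, the SE is recovered by the symmetric normal approximation
#' `(upper - lower) / (2 * 1.959964)`.
#'
#' @param label class labels.
#' @param estimate point estimates (slopes).
#' @param se standard errors (> 0); omit to recover from the CI.
#' @param ci_lower,ci_upper 95% interval bounds (used when `se` missing).
#' @return data.frame of class `effect_estimates`.
#' @export
effect_estimates <- function(label, estimate, se = NULL, ci_lower = NULL,
                             ci_upper = NULL) {
  if (is.null(se)) {
    if (is.null(ci_lower) || is.null(ci_upper))
      stop_kc("need se or both CI bounds", class = "kincoop_data_error")
    se <- (ci_upper - ci_lower) / (2 * qnorm(0.975))
  }
  if (any(se <= 0))
    stop_kc("standard errors must be > 0", class = "kincoop_data_error")
  structure(data.frame(label = label, estimate = estimate, se = se),
            class = c("effect_estimates", "data.frame"))
}

#' Random-effects meta-analysis of per-class slopes
#'
#' Pools the per-cooperation-class slope estimates under the model
#' `y_i = mu + m_i + e_i` with measurement error `m_i` (known `se_i`) and
#' between-class heterogeneity `tau^2`, estimated by REML (default) or
#' DerSimonian-Laird. Weights are `1 / (se_i^2 + tau^2)`; the pooled mean,
#' its SE, z value, equal-tailed 95% CI and two-sided normal p-value are
#' returned.
#'
#' @param estimates an [effect_estimates()] table (or data.frame with
#'   columns `label`, `estimate`, `se`).
#' @param method tau^2 estimator: `"REML"` (default), `"DL"`
#'   (DerSimonian-Laird), or `"FE"` to fix `tau^2 = 0` (the classical
#'   inverse-variance fixed-effect pool).
#' @return List of class `meta_result`: `mu`, `se`, `z`, `ci_lower`,
#'   `ci_upper`, `p`, `tau2`, `k`, `method`.
#' @export
meta_analysis <- function(estimates, method = c("REML", "DL", "FE")) {
  method <- match.arg(method)
  if (nrow(estimates) < 1L)
    stop_kc("need at least one estimate", class = "kincoop_data_error")
  if (any(estimates$se <= 0))
    stop_kc("standard errors must be > 0", class = "kincoop_data_error")
  fit <- metafor::rma(yi = estimates$estimate, sei = estimates$se,
                      method = method)
  structure(list(mu = as.numeric(fit$beta), se = fit$se, z = fit$zval,
                 ci_lower = fit$ci.lb, ci_upper = fit$ci.ub, p = fit$pval,
                 tau2 = fit$tau2, k = fit$k, method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> mu = %.3f (SE %.3f), z = %.2f, CI95 [%.3f, %.3f], p = %.3g, tau2 = %.3g (%s, k = %d)\n",
    x$mu, x$se, x$z, x$ci_lower, x$ci_upper, x$p, x$tau2, x$method, x$k))
  invisible(x)
}

#' Joint Wald test of a coefficient block
#'
#' `W = b' V^-1 b` compared against the chi-square distribution with `df`
#' degrees of freedom; used on the posterior joint distribution of the six
#' cooperation coefficients in the reverse-causation model.
#'
#' @param b coefficient means.
#' @param V their covariance matrix (positive definite).
#' @param df degrees of freedom; default `length(b)`.
#' @return List with `W`, `df`, `p`.
#' @export
wald_joint_test <- function(b, V, df = length(b)) {
  V <- as.matrix(V)
  if (length(b) != nrow(V) || nrow(V) != ncol(V))
    stop_kc("b and V do not conform", class = "kincoop_data_error")
  kappa_v <- kappa(V, exact = TRUE)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop_kc(sprintf("V is singular (condition number %.3g)", kappa_v),
            class = "kincoop_numerical_error")
  z <- forwardsolve(t(ch), b)
  W <- sum(z^2)
  list(W = W, df = df, p = pchisq(W, df, lower.tail = FALSE))
}

#' Infinite-island equilibrium relatedness
#'
#' The classical haploid identity-by-descent equilibrium for an infinite
#' island model with deme size `N` and migration rate `m`:
#' `r = (1 - m)^2 / (N - (N - 1) * (1 - m)^2)`. Strictly decreasing in
#' both arguments; `r = 1` for closed demes (`m = 0`) and `r = 0` under
#' full mixing (`m = 1`).
#'
#' @param deme_size N >= 1.
#' @param migration m in `[0, 1]`.
#' @return Equilibrium relatedness in `[0, 1]`.
#' @export
island_equilibrium_relatedness <- function(deme_size, migration) {
  if (any(deme_size < 1)) stop_kc("deme_size must be >= 1",
                                  class = "kincoop_parameter_error")
  assert_prob(migration, "migration")
  (1 - migration)^2 / (deme_size - (deme_size - 1) * (1 - migration)^2)
}

#' Predicted proportional change in cooperative gene count
#'
#' Under the log-link count model, moving relatedness from `r_low` to
#' `r_high` at fixed genome size multiplies the expected count by
#' `exp(beta * (r_high - r_low))`; returned as a percentage increase.
#'
#' @param beta slope of log count on relatedness.
#' @param r_low,r_high relatedness endpoints.
#' @return Percent change, `100 * (exp(beta * (r_high - r_low)) - 1)`.
#' @export
predicted_count_increase <- function(beta, r_low, r_high) {
  100 * (exp(beta * (r_high - r_low)) - 1)
}

classify_pmcmc <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.10, "marginal", "absent"))
}

#' Direct/indirect path summary
#'
#' Assembles the path-analysis ledger over
#' ecology (migration via sporulation score, group size via relative
#' abundance), relatedness, and the cooperation classes:
#' * ecology -> relatedness edges from the Gaussian relatedness model;
#' * relatedness -> cooperation edges from the count models with ecological
#'   covariates (with the relative change of the slope against the
#'   ecology-free fit reported as `slope_shift`);
#' * direct ecology -> cooperation edges from the same fits;
#' * cooperation -> relatedness reverse-causation edges from the reverse
#'   fit plus the joint Wald test.
#'
#' Edges are classified `significant` (PMCMC < 0.05), `marginal`
#' (0.05 <= PMCMC < 0.10) or `absent`. An ecology -> cooperation effect is
#' labelled `indirect` when the ecology -> relatedness edge and the
#' relatedness -> cooperation edge are both significant, `direct` when its
#' own edge is, `direct+indirect` when both hold.
#'
#' @param coop_fits named list (class -> `phylo_fit`) of count models with
#'   relatedness + genome size only.
#' @param coop_fits_eco same classes, with relative abundance and
#'   sporulation score added.
#' @param rel_fit Gaussian relatedness model (abundance + sporulation).
#' @param rel_fit_reverse the reverse-causation variant with the six
#'   cooperation counts as predictors.
#' @param wald joint Wald test result for the six cooperation coefficients
#'   in `rel_fit_reverse` (from [wald_joint_test()]).
#' @param term_map names of the design columns: `relatedness`,
#'   `abundance`, `sporulation` (defaults match the pipeline design
#'   builders).
#' @return Object of class `path_summary`: list with `edges` (data.frame:
#'   from, to, estimate, pmcmc, sign, classification, role, slope_shift)
#'   and `wald`.
#' @export
path_summary <- function(coop_fits, coop_fits_eco, rel_fit, rel_fit_reverse,
                         wald,
                         term_map = c(relatedness = "relatedness",
                                      abundance = "mean_relative_abundance",
                                      sporulation = "sporulation_score")) {
  for (nm in c("coop_fits", "coop_fits_eco", "rel_fit", "rel_fit_reverse",
               "wald")) {
    if (is.null(get(nm)))
      stop_kc("path summary missing component: ", nm,
              class = "kincoop_configuration_error")
  }
  if (!setequal(names(coop_fits), names(coop_fits_eco)))
    stop_kc("coop_fits and coop_fits_eco must cover the same classes",
            class = "kincoop_configuration_error")
  get_term <- function(fit, term) {
    row <- fit$summary[fit$summary$term == term, ]
    if (nrow(row) != 1L)
      stop_kc("term not in fit: ", term,
              class = "kincoop_configuration_error")
    row
  }
  edges <- list()
  # ecology -> relatedness
  eco <- c(migration = unname(term_map["sporulation"]),
           group_size = unname(term_map["abundance"]))
  eco_sig <- c(migration = FALSE, group_size = FALSE)
  for (e in names(eco)) {
    row <- get_term(rel_fit, eco[[e]])
    eco_sig[e] <- row$pmcmc < 0.05
    edges[[length(edges) + 1L]] <- data.frame(
      from = e, to = "relatedness", estimate = row$post_mean,
      pmcmc = row$pmcmc, sign = sign(row$post_mean),
      classification = classify_pmcmc(row$pmcmc), role = "direct",
      slope_shift = NA_real_)
  }
  # relatedness -> cooperation (controlled fits), plus direct eco edges
  for (cl in names(coop_fits_eco)) {
    base <- get_term(coop_fits[[cl]], term_map["relatedness"])
    ctrl <- get_term(coop_fits_eco[[cl]], term_map["relatedness"])
    rel_sig <- ctrl$pmcmc < 0.05
    edges[[length(edges) + 1L]] <- data.frame(
      from = "relatedness", to = cl, estimate = ctrl$post_mean,
      pmcmc = ctrl$pmcmc, sign = sign(ctrl$post_mean),
      classification = classify_pmcmc(ctrl$pmcmc), role = "direct",
      slope_shift = (ctrl$post_mean - base$post_mean) /
        abs(base$post_mean))
    for (e in names(eco)) {
      row <- get_term(coop_fits_eco[[cl]], eco[[e]])
      direct <- classify_pmcmc(row$pmcmc)
      indirect <- eco_sig[e] && rel_sig
      role <- if (direct == "significant" && indirect) "direct+indirect"
      else if (direct == "significant") "direct"
      else if (indirect) "indirect"
      else "absent"
      edges[[length(edges) + 1L]] <- data.frame(
        from = e, to = cl, estimate = row$post_mean, pmcmc = row$pmcmc,
        sign = sign(row$post_mean), classification = direct, role = role,
        slope_shift = NA_real_)
    }
  }
  # cooperation -> relatedness (reverse causation)
  for (cl in names(coop_fits)) {
    term <- if (cl %in% rel_fit_reverse$summary$term) cl else
      paste0("count_", cl)
    row <- get_term(rel_fit_reverse, term)
    edges[[length(edges) + 1L]] <- data.frame(
      from = cl, to = "relatedness", estimate = row$post_mean,
      pmcmc = row$pmcmc, sign = sign(row$post_mean),
      classification = classify_pmcmc(row$pmcmc), role = "reverse",
      slope_shift = NA_real_)
  }
  structure(list(edges = do.call(rbind, edges), wald = wald),
            class = "path_summary")
}

#' @export
print.path_summary <- function(x, ...) {
  cat("<path_summary>\n")
  print(x$edges, digits = 3)
  cat(sprintf("joint reverse-causation Wald: W = %.3f, df = %d, p = %.3f\n",
              x$wald$W, x$wald$df, x$wald$p))
  invisible(x)
}
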