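#' Select core-genome sites by prevalence
#'
#' A site belongs to the core genome when it is present in strictly more
#' than `prevalence_threshold` of the hosts carrying the species (the
#' default reproduces the conventional ">90% of samples" rule; note the
#' strict inequality: 9/10 hosts at threshold 0.90 is dropped).
#'
#' @param panel an `afp` allele-frequency panel.
#' @param prevalence_threshold fraction in `[0, 1)`; default 0.90.
#' @return Logical mask over `panel$sites`.
#' @export
select_core_sites <- function(panel, prevalence_threshold = 0.90) {
  stopifnot(inherits(panel, "afp"))
  if (length(panel$hosts) < 1L)
    stop_kc("panel has no hosts", class = "kincoop_data_error")
  prev <- colMeans(panel$presence)
  prev > prevalence_threshold
}

#' Average genomic similarity from allele frequencies
#'
#' The mean over sites of the probability that two randomly drawn haploid
#' individuals are identical by state: `S = (1/k) * sum_sites sum_a p_a^2`
#' (expected homozygosity; equals one minus mean per-site genetic
#' diversity). With `correct = TRUE` the draw is without replacement,
#' removing the upward `1/n` self-pair bias when `n` sampled individuals
#' back the frequencies: `(n * sum p_a^2 - 1) / (n - 1)` per site.
#'
#' @param freqs `sites x 4` frequency matrix.
#' @param mask optional logical site mask (default all).
#' @param depth per-site number of sampled individuals; required when
#'   `correct = TRUE`.
#' @param correct apply the finite-sample (without replacement) correction.
#' @return Scalar similarity in `[0, 1]` (the corrected estimator may be
#'   slightly negative at extreme diversity and tiny depth).
#' @export
genomic_similarity <- function(freqs, mask = NULL, depth = NULL,
                               correct = FALSE) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)
  mask <- mask %||% rep(TRUE, nrow(freqs))
  if (!any(mask))
    stop_kc("no usable sites for similarity", class = "kincoop_data_error")
  s_site <- rowSums(freqs[mask, , drop = FALSE]^2)
  if (correct) {
    if (is.null(depth))
      stop_kc("depth required for the sample-size-corrected similarity",
              class = "kincoop_data_error")
    n <- rep_len(depth, nrow(freqs))[mask]
    if (any(n < 2))
      stop_kc("corrected similarity needs depth >= 2 at every site",
              class = "kincoop_data_error")
    s_site <- (n * s_site - 1) / (n - 1)
  }
  mean(s_site)
}

#' Depth-weighted pooled allele frequencies across hosts
#'
#' Per site, pooled `p_a = sum_h depth_h * p_ah / sum_h depth_h` over the
#' hosts where the site is present (mirroring pooling reads across
#' samples). `weights = "equal"` averages hosts unweighted instead.
#'
#' @param panel an `afp` panel with at least 2 hosts.
#' @param mask logical site mask (default all sites).
#' @param weights `"depth"` (default) or `"equal"`.
#' @return List with `freqs` (`sites x 4`, `NA` rows where masked out or no
#'   host present), `depth` (total depth per site) and `n_hosts` per site.
#' @export
pooled_frequencies <- function(panel, mask = NULL, weights = c("depth", "equal")) {
  stopifnot(inherits(panel, "afp"))
  weights <- match.arg(weights)
  if (length(panel$hosts) < 2L)
    stop_kc("pooling requires >= 2 hosts", class = "kincoop_data_error")
  ns <- length(panel$sites)
  mask <- mask %||% rep(TRUE, ns)
  w <- if (weights == "depth") panel$depth else (panel$presence * 1)
  w <- w * panel$presence          # absent sites carry no weight
  wsum <- colSums(w)
  if (any(mask & colSums(panel$presence) > 0 & wsum == 0))
    stop_kc("all depths zero at a present site", class = "kincoop_data_error")
  pooled <- matrix(NA_real_, ns, 4L)
  for (a in 1:4) {
    num <- colSums(w * panel$freqs[, , a])
    pooled[, a] <- ifelse(wsum > 0, num / wsum, NA_real_)
  }
  pooled[!mask, ] <- NA_real_
  list(freqs = pooled,
       depth = colSums(panel$depth * panel$presence),
       n_hosts = colSums(panel$presence))
}

#' FST-like relatedness from within and across-host similarity
#'
#' `r = (s_within - s_across) / (1 - s_across)`: the genetic similarity of
#' the host subpopulation relative to the population-wide average, i.e.
#' Hamilton's coefficient of relatedness for the within-host group. `r = 1`
#' iff the host subpopulation is fully monomorphic at the core sites.
#'
#' @param s_within,s_across similarities in `[0, 1]`; `s_across < 1`.
#' @return Relatedness (at most 1; can be negative when the host is more
#'   diverse than the pooled population).
#' @export
relatedness <- function(s_within, s_across) {
  if (any(s_across >= 1))
    stop_kc("population monomorphic at core sites (s_across = 1): ",
            "relatedness undefined", class = "kincoop_relatedness_undefined")
  (s_within - s_across) / (1 - s_across)
}

#' Per-species, per-host relatedness table
#'
#' For each species panel: select core sites by prevalence, drop species
#' seen in fewer than `min_hosts` hosts or with fewer than `min_core_sites`
#' core sites, compute within-host and pooled (across-host) similarity at
#' the core sites, and the relatedness of each host subpopulation. The
#' per-species mean is the unweighted arithmetic mean over hosts. Within-
#' host similarity for host `h` uses only the core sites present in `h`;
#' every dropped species is recorded with a reason (and messaged).
#'
#' @param panels list of `afp` panels (or a single panel).
#' @param prevalence_threshold core-site prevalence cutoff (strict >).
#' @param min_hosts minimum hosts a species must be observed in (default 2:
#'   relatedness needs at least two hosts).
#' @param min_core_sites minimum core-genome size retained (default 100).
#' @param correct use the sample-size-corrected similarity (needs depth =
#'   number of sampled individuals; appropriate for finite simulated demes,
#'   not for read-depth panels).
#' @param pool_weights `"depth"` or `"equal"` host weighting when pooling.
#' @return Object of class `relatedness_table`: list with `table` (one row
#'   per species x host: species, host, s_within, s_across, r,
#'   n_core_sites), `summary` (species, mean_r, n_hosts, n_core_sites) and
#'   `dropped` (species, reason).
#' @export
build_relatedness_table <- function(panels, prevalence_threshold = 0.90,
                                    min_hosts = 2L, min_core_sites = 100L,
                                    correct = FALSE,
                                    pool_weights = c("depth", "equal")) {
  if (inherits(panels, "afp")) panels <- list(panels)
  if (length(panels) == 0L)
    stop_kc("no panels supplied", class = "kincoop_data_error")
  pool_weights <- match.arg(pool_weights)
  rows <- list(); dropped <- list()
  for (p in panels) {
    sp <- p$species
    n_hosts <- length(p$hosts)
    if (n_hosts < min_hosts) {
      dropped[[sp]] <- sprintf("present in %d host(s) < min_hosts = %d",
                               n_hosts, min_hosts)
      next
    }
    core <- select_core_sites(p, prevalence_threshold)
    k <- sum(core)
    if (k < min_core_sites) {
      dropped[[sp]] <- sprintf("%d core sites < min_core_sites = %d",
                               k, min_core_sites)
      next
    }
    pooled <- pooled_frequencies(p, mask = core, weights = pool_weights)
    ok <- core & !is.na(pooled$freqs[, 1])
    s_across <- genomic_similarity(pooled$freqs, ok,
                                   depth = pooled$depth, correct = correct)
    if (s_across >= 1) {
      dropped[[sp]] <- "population monomorphic at core sites (s_across = 1)"
      next
    }
    host_rows <- lapply(seq_len(n_hosts), function(h) {
      use <- ok & p$presence[h, ]
      if (!any(use)) return(NULL)
      s_w <- genomic_similarity(p$freqs[h, , ], use,
                                depth = p$depth[h, ], correct = correct)
      data.frame(species = sp, host = p$hosts[h], s_within = s_w,
                 s_across = s_across, r = relatedness(s_w, s_across),
                 n_core_sites = sum(use))
    })
    rows[[sp]] <- do.call(rbind, host_rows)
  }
  for (sp in names(dropped))
    message("dropping species ", sp, ": ", dropped[[sp]])
  tab <- do.call(rbind, rows)
  summ <- if (!is.null(tab)) {
    agg <- aggregate(tab$r, by = list(species = tab$species),
                     function(z) c(mean(z), length(z)))
    data.frame(species = agg$species, mean_r = agg$x[, 1],
               n_hosts = as.integer(agg$x[, 2]),
               n_core_sites = sapply(split(tab$n_core_sites, tab$species),
                                     max)[agg$species])
  } else {
    data.frame(species = character(), mean_r = numeric(),
               n_hosts = integer(), n_core_sites = integer())
  }
  structure(list(table = tab %||% data.frame(),
                 summary = summ,
                 dropped = data.frame(species = names(dropped),
                                      reason = unlist(dropped) %||% character())),
            class = "relatedness_table")
}

#' @export
print.relatedness_table <- function(x, ...) {
  cat(sprintf("<relatedness table> %d species, %d species-host estimates, %d dropped\n",
              nrow(x$summary), nrow(x$table), nrow(x$dropped)))
  invisible(x)
}

#' Write / read a relatedness table
#'
#' Two TSVs: `<path>` holds the per species-host rows, `<path>` with suffix
#' `_summary` the per-species means.
#'
#' @param x a `relatedness_table`.
#' @param path base TSV path.
#' @return `path`, invisibly.
#' @export
write_relatedness_tsv <- function(x, path) {
  stopifnot(inherits(x, "relatedness_table"))
  write_tsv_kc(x$table, path)
  write_tsv_kc(x$summary, sub("(\\.tsv)?$", "_summary\\1", path))
  invisible(path)
}

#' @rdname write_relatedness_tsv
#' @export
read_relatedness_tsv <- function(path) {
  structure(list(table = read_tsv_kc(path),
                 summary = read_tsv_kc(sub("(\\.tsv)?$", "_summary\\1", path)),
                 dropped = data.frame(species = character(),
                                      reason = character())),
            class = "relatedness_table")
}
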