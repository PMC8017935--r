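#' Allele-frequency panel for one species
#'
#' The substrate of relatedness estimation: per-host, per-site allele
#' frequencies over the four nucleotide states, together with a presence
#' mask and sequencing depth (for simulated data, the number of haploid
#' individuals behind each frequency estimate).
#'
#' @param species single species identifier.
#' @param freqs numeric array `hosts x sites x 4` of allele frequencies;
#'   the allele dimension is ordered A, C, G, T.
#' @param presence logical `hosts x sites` matrix; `FALSE` marks sites with
#'   no data for that host. Defaults to all present.
#' @param depth numeric `hosts x sites` matrix of depths (reads or sampled
#'   haploids). Defaults to 1 everywhere a site is present.
#' @param hosts,sites identifiers; default `h01...`/`s000001...`.
#'
#' @return An object of class `afp`: a list with elements `species`,
#'   `hosts`, `sites`, `freqs`, `presence`, `depth`.
#' @export
allele_frequency_panel <- function(species, freqs, presence = NULL,
                                   depth = NULL, hosts = NULL, sites = NULL) {
  if (length(dim(freqs)) != 3L || dim(freqs)[3] != 4L)
    stop_kc("freqs must be a hosts x sites x 4 array",
            class = "kincoop_data_error")
  nh <- dim(freqs)[1]; ns <- dim(freqs)[2]
  hosts <- hosts %||% sprintf("h%02d", seq_len(nh))
  sites <- sites %||% sprintf("s%06d", seq_len(ns))
  presence <- presence %||% matrix(TRUE, nh, ns)
  depth <- depth %||% (matrix(1, nh, ns) * presence)
  tot <- apply(freqs, c(1, 2), sum)
  bad <- presence & abs(tot - 1) > 1e-9
  if (any(bad))
    stop_kc("allele frequencies must sum to 1 at every present (host, site)",
            class = "kincoop_data_error")
  structure(list(species = species, hosts = hosts, sites = sites,
                 freqs = freqs, presence = presence, depth = depth),
            class = "afp")
}

#' @export
print.afp <- function(x, ...) {
  cat(sprintf("<allele-frequency panel> %s: %d hosts x %d sites (%.1f%% present)\n",
              x$species, length(x$hosts), length(x$sites),
              100 * mean(x$presence)))
  invisible(x)
}

#' Write allele-frequency panels to a long-format TSV
#'
#' Columns: species, host, site_id, ref_allele, freq_A, freq_C, freq_G,
#' freq_T, depth. One row per present (host, site). `ref_allele` is the
#' major allele at that entry.
#'
#' @param panels a single `afp` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panels, path) {
  if (inherits(panels, "afp")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    idx <- which(p$presence, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    fr <- cbind(p$freqs[, , 1][idx], p$freqs[, , 2][idx],
                p$freqs[, , 3][idx], p$freqs[, , 4][idx])
    data.frame(species = p$species,
               host = p$hosts[idx[, 1]],
               site_id = p$sites[idx[, 2]],
               ref_allele = ALLELES[max.col(fr, ties.method = "first")],
               freq_A = fr[, 1], freq_C = fr[, 2],
               freq_G = fr[, 3], freq_T = fr[, 4],
               depth = p$depth[idx])
  })
  write_tsv_kc(do.call(rbind, rows), path)
}

#' Read allele-frequency panels from TSV
#'
#' Inverse of [write_panel_tsv()]; absent (host, site) combinations become
#' `presence = FALSE`.
#'
#' @param path TSV written by [write_panel_tsv()].
#' @return Named list of `afp` objects, one per species.
#' @export
read_panel_tsv <- function(path) {
  d <- read_tsv_kc(path)
  need <- c("species", "host", "site_id", "freq_A", "freq_C", "freq_G",
            "freq_T", "depth")
  if (!all(need %in% names(d)))
    stop_kc("panel TSV missing columns: ",
            paste(setdiff(need, names(d)), collapse = ", "),
            class = "kincoop_data_error")
  out <- lapply(split(d, d$species), function(ds) {
    hosts <- sort(unique(ds$host)); sites <- sort(unique(ds$site_id))
    nh <- length(hosts); ns <- length(sites)
    hi <- match(ds$host, hosts); si <- match(ds$site_id, sites)
    freqs <- array(0, c(nh, ns, 4))
    for (a in 1:4) freqs[, , a][cbind(hi, si)] <- ds[[paste0("freq_", ALLELES[a])]]
    presence <- matrix(FALSE, nh, ns); presence[cbind(hi, si)] <- TRUE
    depth <- matrix(0, nh, ns); depth[cbind(hi, si)] <- ds$depth
    allele_frequency_panel(ds$species[1], freqs, presence, depth, hosts, sites)
  })
  out[order(names(out))]
}
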