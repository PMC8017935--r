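#' Read a minimal ontology table
#'
#' Expects a TSV with columns `term_id`, `name`, `parent_ids` (is_a parents
#' separated by `|`; empty for roots). The graph must be acyclic over is_a
#' edges.
#'
#' @param path TSV file, or a data.frame in the same shape.
#' @return Object of class `kc_ontology`: list with `terms` (data.frame),
#'   `parents` and `children` (named lists of term-id vectors).
#' @export
read_ontology_tsv <- function(path) {
  d <- if (is.data.frame(path)) path else read_tsv_kc(path)
  need <- c("term_id", "name", "parent_ids")
  if (!all(need %in% names(d)))
    stop_kc("ontology table missing columns: ",
            paste(setdiff(need, names(d)), collapse = ", "),
            class = "kincoop_data_error")
  if (anyDuplicated(d$term_id))
    stop_kc("duplicated term ids in ontology", class = "kincoop_data_error")
  parents <- lapply(strsplit(ifelse(is.na(d$parent_ids), "", d$parent_ids),
                             "|", fixed = TRUE),
                    function(p) p[nzchar(p)])
  names(parents) <- d$term_id
  children <- vector("list", nrow(d)); names(children) <- d$term_id
  for (tid in d$term_id)
    for (p in parents[[tid]]) {
      if (!p %in% d$term_id)
        stop_kc("unknown parent term: ", p, class = "kincoop_data_error")
      children[[p]] <- c(children[[p]], tid)
    }
  ont <- structure(list(terms = d[, need], parents = parents,
                        children = children),
                   class = "kc_ontology")
  # cycle check: DFS from every root must visit each node finitely; detect
  # by depth-first colouring
  state <- new.env(parent = emptyenv())
  visit <- function(tid) {
    s <- state[[tid]] %||% 0L
    if (s == 1L) stop_kc("ontology contains a cycle through ", tid,
                         class = "kincoop_data_error")
    if (s == 2L) return(invisible())
    state[[tid]] <- 1L
    for (ch in children[[tid]] %||% character()) visit(ch)
    state[[tid]] <- 2L
  }
  for (tid in d$term_id) visit(tid)
  ont
}

descendants_of <- function(ont, ids, direct_only = FALSE) {
  out <- character(0); frontier <- ids
  repeat {
    nxt <- unique(unlist(ont$children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0L) break
    out <- c(out, nxt)
    if (direct_only) break
    frontier <- nxt
  }
  out
}

#' Build per-class social term sets from keywords
#'
#' For each cooperation class: terms whose names contain any of the class
#' keywords (case-insensitive substring match on names only), plus all
#' their descendants (transitive closure of child terms; set
#' `descendants = "direct"` for direct children only), plus the direct
#' parents of the matched terms. A curation table then forces terms in or
#' out. Provenance is recorded per retained term, and curated-out terms are
#' kept in the provenance ledger with provenance `"curated-out"`.
#'
#' Keyword specificity is the point of the curation step: a name like
#' "extracellular polysaccharide biosynthetic process" is confidently
#' social, whereas generic "polysaccharide production" is not and should
#' never be keyword-matched.
#'
#' @param ontology a `kc_ontology`.
#' @param keywords named list (class -> character vector of keywords), or a
#'   data.frame with columns `class`, `keyword`.
#' @param curation optional data.frame with columns `class`, `term_id`,
#'   `action` (`"include"`/`"exclude"`).
#' @param descendants `"all"` (default) or `"direct"`.
#' @return Object of class `social_term_sets`: list with `sets` (named list
#'   class -> term ids) and `provenance` (data.frame class, term_id,
#'   provenance in keyword-matched/child/parent/curated-in/curated-out).
#' @export
build_social_term_sets <- function(ontology, keywords, curation = NULL,
                                   descendants = c("all", "direct")) {
  stopifnot(inherits(ontology, "kc_ontology"))
  descendants <- match.arg(descendants)
  if (is.data.frame(keywords))
    keywords <- split(keywords$keyword, keywords$class)
  nm_lower <- tolower(ontology$terms$name)
  ids <- ontology$terms$term_id
  sets <- list(); prov <- list()
  for (cl in names(keywords)) {
    hit <- rep(FALSE, length(ids))
    for (kw in keywords[[cl]])
      hit <- hit | grepl(tolower(kw), nm_lower, fixed = TRUE)
    matched <- ids[hit]
    kids <- setdiff(descendants_of(ontology, matched,
                                   direct_only = descendants == "direct"),
                    matched)
    pars <- setdiff(unique(unlist(ontology$parents[matched],
                                  use.names = FALSE)),
                    c(matched, kids))
    p <- rbind(
      if (length(matched)) data.frame(class = cl, term_id = matched,
                                      provenance = "keyword-matched"),
      if (length(kids)) data.frame(class = cl, term_id = kids,
                                   provenance = "child"),
      if (length(pars)) data.frame(class = cl, term_id = pars,
                                   provenance = "parent"))
    cur <- if (!is.null(curation)) curation[curation$class == cl, ] else NULL
    if (!is.null(cur) && nrow(cur)) {
      excl <- cur$term_id[cur$action == "exclude"]
      incl <- setdiff(cur$term_id[cur$action == "include"], p$term_id)
      if (length(excl)) {
        out_rows <- p$term_id %in% excl
        if (any(out_rows)) {
          dropped <- p[out_rows, ]; dropped$provenance <- "curated-out"
          p <- rbind(p[!out_rows, ], dropped)
        }
      }
      if (length(incl))
        p <- rbind(p, data.frame(class = cl, term_id = incl,
                                 provenance = "curated-in"))
    }
    sets[[cl]] <- p$term_id[p$provenance != "curated-out"]
    prov[[cl]] <- p
  }
  structure(list(sets = sets, provenance = do.call(rbind, prov)),
            class = "social_term_sets")
}

#' Load pre-curated social term sets from a class/term table
#'
#' For runs where the curated list is already final (e.g. the shipped
#' synthetic 118-term fixture), bypass keyword expansion and read the sets
#' directly.
#'
#' @param path TSV with columns `class`, `term_id` (plus optional `name`),
#'   or a data.frame.
#' @return A `social_term_sets` with provenance `"curated-in"`.
#' @export
read_social_term_sets <- function(path) {
  d <- if (is.data.frame(path)) path else read_tsv_kc(path)
  sets <- split(d$term_id, d$class)
  structure(list(sets = sets,
                 provenance = data.frame(class = d$class, term_id = d$term_id,
                                         provenance = "curated-in")),
            class = "social_term_sets")
}

#' @export
print.social_term_sets <- function(x, ...) {
  n <- vapply(x$sets, length, 0L)
  cat("<social term sets> ", paste(names(n), n, sep = "=", collapse = ", "),
      "; union ", length(unique(unlist(x$sets))), " terms\n", sep = "")
  invisible(x)
}

#' Path to a shipped extdata fixture
#' @param file file name under `inst/extdata`.
#' @return Absolute path.
#' @export
kc_fixture <- function(file) {
  p <- system.file("extdata", file, package = "kincoop", mustWork = TRUE)
  p
}
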