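#' Brownian-motion phylogenetic covariance from an ultrametric tree
#'
#' `C[i, j]` is the depth (root-to-tip path length shared) of the most
#' recent common ancestor of tips i and j; the diagonal is the tree depth.
#' This is the covariance of a Brownian trait evolving along the tree.
#'
#' @param tree an `ape::phylo`, rooted and ultrametric (tolerance `1e-6`
#'   relative).
#' @param scale if `TRUE`, scale to unit diagonal so variance components
#'   estimated against it are comparable across trees.
#' @return Symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, scale = FALSE) {
  if (!inherits(tree, "phylo"))
    stop_kc("tree must be an ape phylo object", class = "kincoop_data_error")
  if (ape::Ntip(tree) < 2L)
    stop_kc("tree needs >= 2 tips", class = "kincoop_data_error")
  if (!ape::is.ultrametric(tree, tol = 1e-6, option = 2))
    stop_kc("tree is not ultrametric (tolerance 1e-6)",
            class = "kincoop_data_error")
  C <- ape::vcv(tree)
  if (scale) C <- C / mean(diag(C))
  C
}
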