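#' Calibrated tree-distance asymmetry of a paralog pair
#'
#' Branch lengths differ between protein families for reasons unrelated
#' to the duplication, so all distances are first calibrated: the mean
#' path length from the two calibration leaves (e.g. two pre-duplication
#' species) to their last common ancestor is set to one. The calibrated
#' path lengths from the paralogs' own last common ancestor to each
#' paralog leaf then measure how far each copy travelled since the
#' duplication; their absolute difference is the divergence asymmetry,
#' with the shorter distance belonging to the more conserved copy.
#'
#' @param tree an `ape` `phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param p1_leaf,p2_leaf tip labels of the two paralogs.
#' @param calib_a,calib_b tip labels of the two calibration leaves.
#' @return Object of class `tree_metrics`: `D_P1` (smaller calibrated
#'   LCA-to-paralog distance), `D_P2`, `delta_D = |D_P1 - D_P2|`,
#'   `calibration_factor`, and `conserved_leaf`.
#' @export
paralog_tree_metrics <- function(tree, p1_leaf, p2_leaf, calib_a, calib_b) {
  phy <- as_phylo(tree)
  tips <- c(p1_leaf, p2_leaf, calib_a, calib_b)
  missing <- setdiff(tips, phy$tip.label)
  if (length(missing))
    stop("leaf not found in tree: ", paste(missing, collapse = ", "))
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")

  d <- ape::dist.nodes(phy)
  tip_id <- match(tips, phy$tip.label)

  calib_lca <- ape::getMRCA(phy, tip_id[3:4])
  calib <- mean(c(d[calib_lca, tip_id[3]], d[calib_lca, tip_id[4]]))
  if (calib == 0) stop("zero calibration distance")

  par_lca <- ape::getMRCA(phy, tip_id[1:2])
  d1 <- d[par_lca, tip_id[1]] / calib
  d2 <- d[par_lca, tip_id[2]] / calib
  conserved <- if (d1 <= d2) p1_leaf else p2_leaf

  structure(list(D_P1 = min(d1, d2), D_P2 = max(d1, d2),
                 delta_D = abs(d1 - d2), calibration_factor = calib,
                 conserved_leaf = conserved,
                 leaf_distances = setNames(c(d1, d2), c(p1_leaf, p2_leaf))),
            class = "tree_metrics")
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1)
  if (grepl("\\(", tree)) ape::read.tree(text = tree) else ape::read.tree(tree)
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf(paste0("tree_metrics: D = %.3f / %.3f (delta %.3f),",
                     " calibration %.3f, conserved leaf %s\n"),
              x$D_P1, x$D_P2, x$delta_D, x$calibration_factor,
              x$conserved_leaf))
  invisible(x)
}
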