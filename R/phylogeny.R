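#' Read a species tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] with validation: the tree must
#' have at least two uniquely labelled tips. Polytomies are permitted and
#' preserved. Tip labels are normalized (spaces to underscores, case
#' folded) so they join deterministically against the effect-size table.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Optional Newick string instead of a file.
#' @return An [ape::phylo] tree.
#' @export
read_species_tree <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) {
    if (!file.exists(path)) stop("Tree file not found: ", path, call. = FALSE)
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tree)) stop("Could not parse Newick input.", call. = FALSE)
  if (ape::Ntip(tree) < 2) stop("Tree must have at least 2 tips.", call. = FALSE)
  tree$tip.label <- normalize_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("Duplicate tip labels after normalization: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Normalize species names for tree/table joins
#'
#' Spaces become underscores and case is folded, so "Gryllus bimaculatus"
#' and "gryllus_bimaculatus" match. No fuzzy synonym resolution is done.
#'
#' @param x Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  tolower(gsub("\\s+", "_", trimws(x)))
}

#' Grafen-calibrate a tree to unit depth
#'
#' Assigns each internal node a height of (number of descendant tips - 1)
#' raised to `rho`, scaled so the root has height 1 and tips height 0, and
#' sets each branch length to the height difference between its endpoints.
#' The result is ultrametric with root-to-tip depth exactly 1, the form
#' required for a Brownian-motion correlation matrix. Supertrees assembled
#' from topology-only sources have no meaningful branch lengths, which is
#' why depth is derived from the topology alone.
#'
#' @param tree An [ape::phylo] tree (rooted; polytomies allowed).
#' @param rho Grafen's power parameter (default 1).
#' @return The calibrated tree.
#' @export
grafen_calibrate <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"), rho > 0)
  # Newick input is interpreted as rooted at its outermost node; a basal
  # polytomy (which ape::is.rooted() reports as unrooted) is a legitimate
  # soft polytomy and is preserved.
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Brownian-motion correlation matrix of an ultrametric tree
#'
#' Under Brownian trait evolution on an ultrametric depth-1 tree, the
#' expected correlation between two species equals the depth from the root
#' to their most recent common ancestor. Returns the tip-by-tip
#' correlation matrix (unit diagonal, symmetric, positive semi-definite),
#' with rows/columns ordered and named by tip label.
#'
#' @param tree A calibrated ultrametric [ape::phylo] tree (see
#'   [grafen_calibrate()]).
#' @param tol Tolerance for the ultrametricity check.
#' @return A named square correlation matrix.
#' @export
brownian_correlation <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("Tree has no branch lengths; calibrate it first.", call. = FALSE)
  }
  if (!ape::is.ultrametric(tree, tol = tol, option = 2)) {
    stop("Tree is not ultrametric; the Brownian correlation interpretation ",
         "requires equal root-to-tip depths. Run grafen_calibrate() first.",
         call. = FALSE)
  }
  A <- ape::vcv(tree, corr = TRUE)
  A[A < 0 & A > -tol] <- 0
  A
}

#' Prune a tree to a species subset
#'
#' Drops all tips not in `keep` and, by default, re-runs Grafen calibration
#' on the induced subtree so the pruned tree is again ultrametric with
#' depth 1 (keeping variance components comparable across data subsets).
#' Set `recalibrate = FALSE` to keep the induced branch lengths instead.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Character vector of tip labels to retain (>= 2, normalized
#'   or not).
#' @param recalibrate Re-run [grafen_calibrate()] after pruning (default
#'   TRUE).
#' @param rho Grafen power used when recalibrating.
#' @return The pruned (and possibly recalibrated) tree.
#' @export
prune_tree <- function(tree, keep, recalibrate = TRUE, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(normalize_species(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("Species not found in the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) < 2) stop("Need at least 2 species to keep.", call. = FALSE)
  if (length(keep) == ape::Ntip(tree) && !recalibrate) return(tree)
  out <- ape::keep.tip(tree, keep)
  if (recalibrate) out <- grafen_calibrate(out, rho = rho) else out
}
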