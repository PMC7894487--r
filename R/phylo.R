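#' Read a Newick tree with mandatory branch lengths
#'
#' Parses a Newick string into an \code{ape::phylo} object and validates the
#' invariants the downstream analysis relies on: unique non-empty tip labels,
#' finite non-negative branch lengths on every edge, and a computable
#' root-to-tip path for every tip.
#'
#' @param text a single Newick string (must end in \code{";"}).
#' @return an object of class \code{phylo}.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable tree string", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

# Cheap pre-parse scan so malformed input is reported with a character offset,
# which ape's parser does not provide.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at character offset %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string (offset %d)",
                 depth, length(chars)), call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("malformed Newick: missing terminating ';' (offset %d)", nchar(text)),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate phylogeny invariants
#'
#' @param tree a \code{phylo} object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths are mandatory", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("missing or non-finite branch length on ",
         sum(is.na(tree$edge.length) | !is.finite(tree$edge.length)),
         " edge(s); branch lengths are mandatory", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  invisible(tree)
}

#' Write a tree to a Newick string
#'
#' @param tree a \code{phylo} object.
#' @return a Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  validate_phylogeny(tree)
  ape::write.tree(tree)
}

#' Prune a phylogeny to a set of families
#'
#' Restricts the tree to \code{keep}, preserving all pairwise path lengths
#' between retained tips (degree-2 internal nodes are collapsed with their
#' branch lengths summed).
#'
#' @param tree a \code{phylo} object.
#' @param keep character vector of tip labels to retain (>= 2).
#' @return the pruned \code{phylo} object.
#' @export
prune_phylogeny <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L) {
    stop("families not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 tips to keep", call. = FALSE)
  pruned <- ape::keep.tip(tree, keep)
  # keep the path between the original root and the MRCA of the retained
  # tips as a root edge: history shared by all retained tips survives
  # pruning, so phylo_covariance commutes with taking a submatrix
  mrca <- ape::getMRCA(tree, keep)
  stem <- ape::node.depth.edgelength(tree)[mrca]
  prior_root <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  if (stem + prior_root > 0) pruned$root.edge <- stem + prior_root
  pruned
}

#' Phylogenetic correlation matrix from a tree
#'
#' Builds the tip-by-tip matrix of shared evolutionary history (root-to-MRCA
#' path lengths) and rescales it entrywise by \code{1/sqrt(V[i,i]*V[j,j])} to
#' correlation form (unit diagonal). This is the random-effect structure of
#' the PGLMM: tips that share more history are modelled as more similar.
#'
#' @param tree a \code{phylo} object with >= 2 tips.
#' @param order optional character vector: subset/order of tip labels for the
#'   returned matrix (default: the tree's tip order).
#' @return a symmetric positive semidefinite matrix with unit diagonal,
#'   dimnames set to the family labels.
#' @export
phylo_covariance <- function(tree, order = NULL) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips", call. = FALSE)
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge) && tree$root.edge > 0) {
    V <- V + tree$root.edge   # history shared by all tips above the root
  }
  depths <- diag(V)
  if (any(depths <= 0)) {
    stop("zero root-to-tip depth for tip(s): ",
         paste(rownames(V)[depths <= 0], collapse = ", "),
         "; cannot rescale to correlation", call. = FALSE)
  }
  A <- V / sqrt(outer(depths, depths))
  A <- (A + t(A)) / 2   # exact symmetry against rounding
  if (!is.null(order)) {
    order <- as.character(order)
    missing <- setdiff(order, rownames(A))
    if (length(missing) > 0L) {
      stop("families not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    A <- A[order, order, drop = FALSE]
  }
  A
}

#' Stem ages of the tips of a time-calibrated tree
#'
#' The stem age of a family is the time since it diverged from its extant
#' sister group, i.e. the height above the present of its parent node. The
#' present is taken as the maximum root-to-tip depth, so for an ultrametric
#' tree the stem age of a tip equals its root-to-parent complement
#' (equivalently, its terminal branch length plus the tip's own offset).
#'
#' @param tree a \code{phylo} object with branch lengths in Myr.
#' @return named numeric vector of stem ages (Myr), one per tip.
#' @export
stem_ages <- function(tree) {
  validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  total <- max(depth[seq_len(ntip)])
  parent <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
  ages <- total - depth[parent]
  names(ages) <- tree$tip.label
  if (any(ages <= 0)) {
    stop("non-positive stem age for tip(s): ",
         paste(tree$tip.label[ages <= 0], collapse = ", "), call. = FALSE)
  }
  ages
}

#' Pairwise root-to-tip path lengths between tips
#'
#' Convenience wrapper around the cophenetic distance, used by the round-trip
#' and pruning identities.
#'
#' @param tree a \code{phylo} object.
#' @return symmetric matrix of patristic distances.
#' @export
tip_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
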