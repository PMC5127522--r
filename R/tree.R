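#' Read a Newick tree
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that accepts the common
#' dialect (support values in the internal-label position, branch lengths
#' after colons), collapses unary internal nodes, and validates leaf labels.
#' Trees are treated as rooted exactly as written; no rerooting is applied.
#'
#' @param file path to a Newick file (first tree is used), or \code{NULL}
#' @param text a Newick string, used when \code{file} is \code{NULL}
#' @return an \code{ape} \code{phylo} object
#' @examples
#' read_newick(text = "((A,B)95,(C,D)87);")
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) stop("supply a file or a Newick string")
  phy <- if (!is.null(file)) {
    if (!file.exists(file)) stop("file not found: ", file)
    ape::read.tree(file)
  } else ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (ape::Ntip(phy) >= 2L) phy <- ape::collapse.singles(phy)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

# children counts of every internal node (ids Ntip+1 .. Ntip+Nnode)
internal_degrees <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  deg <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  deg[deg > 0L]
}

#' Tree degeneracy
#'
#' The total excess branching of a tree: the sum over all internal nodes of
#' (number of children - 2). A fully binary tree scores 0; every polytomy
#' adds its excess degree. Equivalently (and as implemented), the closed
#' form of the recursion degeneracy(leaf) = 0, degeneracy(node) =
#' degree - 2 + sum over children. Consensus programs that emit a top-level
#' trifurcation have a floor of 1 by construction.
#'
#' @param phy a \code{phylo} tree
#' @return non-negative integer
#' @examples
#' degeneracy(read_newick(text = "(A,B,C,D,E);"))  # star: 5 - 2 = 3
#' @export
degeneracy <- function(phy) {
  deg <- internal_degrees(phy)
  if (any(deg < 2L)) stop("tree contains unary internal nodes")
  sum(deg - 2L)
}

#' Number of rooted binary topologies on k leaves
#'
#' The double factorial (2k-3)!! for k >= 2, and 1 for k = 1, as exact
#' integers. Values are exactly representable up to k = 16; beyond that the
#' count exceeds 2^53 and this function refuses (use
#' \code{\link{tree_cic}}, which works in log space, for large trees).
#'
#' @param k number of leaves (>= 1)
#' @return exact count as a numeric scalar
#' @examples
#' count_rooted_binary_trees(4)  # 15
#' @export
count_rooted_binary_trees <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be a single integer >= 1")
  if (k > 16)
    stop("(2k-3)!! exceeds 2^53 for k > 16 and is no longer exact; ",
         "use log-space (tree_cic) instead")
  if (k < 3) 1 else prod(seq(1, 2 * k - 3, by = 2))
}

# log of (2k-3)!! (natural log), valid for any k >= 1
ldf_rooted <- function(k) {
  ifelse(k < 3, 0, lgamma(2 * k - 1) - (k - 1) * log(2) - lgamma(k))
}

#' Cladistic information content of a tree
#'
#' \eqn{-\log(\mathrm{permitted}/\mathrm{possible})}: the fraction of all
#' rooted binary topologies on the tree's n leaves that are refinements of
#' the tree (i.e. resolve its polytomies without contradicting any of its
#' clades), negated in log. A star tree permits every topology and scores 0;
#' a fully binary tree permits exactly one and scores
#' \eqn{\log (2n-3)!!}, the maximum. The permitted count is the product over
#' internal nodes of the rooted binary count for each node's degree; the
#' computation is carried out in log space so arbitrarily large trees are
#' handled exactly.
#'
#' @param phy a \code{phylo} tree with at least 2 leaves
#' @param log_base base of the logarithm (default 2, for parity with dCITE
#'   bits)
#' @return non-negative numeric
#' @examples
#' tree_cic(read_newick(text = "((A,B),(C,D));"))  # log2(15)
#' @export
tree_cic <- function(phy, log_base = 2) {
  stopifnot(inherits(phy, "phylo"))
  n <- ape::Ntip(phy)
  if (n < 2L) stop("tree CIC requires at least 2 leaves")
  deg <- internal_degrees(phy)
  if (any(deg < 2L)) stop("tree contains unary internal nodes")
  (ldf_rooted(n) - sum(ldf_rooted(deg))) / log(log_base)
}

#' Minimum clade support in a tree
#'
#' The smallest numeric support value carried by the tree's internal nodes
#' (e.g. the minimum bootstrap count of any clade in a consensus tree).
#' Non-numeric or empty internal labels are ignored.
#'
#' @param phy a \code{phylo} tree
#' @return numeric minimum
#' @examples
#' min_support(read_newick(text = "((A,B)95,(C,D)87);"))  # 87
#' @export
min_support <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$node.label)) stop("tree carries no support values")
  vals <- suppressWarnings(as.numeric(phy$node.label))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("tree carries no numeric support values")
  min(vals)
}
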