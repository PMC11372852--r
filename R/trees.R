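## Tree handling: newick I/O, topology predicates, polytomy collapsing.
## Trees are stored as ape "phylo" objects throughout; unrooted semantics
## are obtained by working with bipartitions.

#' Parse a newick string
#'
#' Thin wrapper around [ape::read.tree()] that validates the parenthesis
#' structure first so that malformed input produces an error naming the
#' character offset of the problem.
#'
#' @param text A newick string (single tree, with or without branch lengths).
#' @return An object of class `"phylo"`. Missing branch lengths default to 0.
#' @examples
#' tr <- parse_newick("(S1:0.01,S2:0.01,S3:0.01,S4:0.01);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed newick: unmatched ')' at offset ", i)
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at offset ",
         length(chars))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree string")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Write a tree as a newick string
#'
#' @param tree A `"phylo"` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A newick string; `parse_newick(write_newick(t))` preserves the
#'   bipartitions and branch lengths of `t`.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

## map an ordered leaf quartet to its induced split.
## Returned levels follow the usual quartet naming relative to the
## given order (a,b,c,d): T1 = ab|cd, T2 = ac|bd, T3 = ad|bc.

#' Induced quartet topology
#'
#' Returns the unrooted topology induced by a tree on an ordered quartet of
#' leaves: `"T1"` groups the first and second label, `"T2"` the first and
#' third, `"T3"` the first and fourth, and `"star"` means the four leaves
#' meet in a single vertex (unresolved).
#'
#' @param tree A `"phylo"` object (rooted or unrooted; polytomies allowed).
#' @param leaves Character vector of 4 leaf labels, in order.
#' @return One of `"T1"`, `"T2"`, `"T3"`, `"star"`.
#' @export
quartet_topology <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) == 4L)
  if (!all(leaves %in% tree$tip.label))
    stop("leaf label(s) not in tree: ",
         paste(setdiff(leaves, tree$tip.label), collapse = ", "))
  q <- ape::keep.tip(tree, leaves)
  if (ape::Ntip(q) != 4L) stop("duplicated leaf labels in quartet")
  q <- ape::unroot(q)
  if (q$Nnode < 2L) return("star")
  part <- ape::prop.part(q)
  labs <- attr(part, "labels")
  for (p in part) {
    if (length(p) != 2L && length(p) != 3L) next
    side <- labs[p]
    if (length(side) == 3L) side <- setdiff(labs, side)
    if (length(side) != 2L) next
    if (leaves[1L] %in% side) {
      partner <- setdiff(side, leaves[1L])
      return(c("T1", "T2", "T3")[match(partner, leaves[-1L])])
    }
    ## side not containing leaves[1]: its complement pairs with leaves[1]
    comp <- setdiff(leaves, side)
    if (length(comp) == 2L && leaves[1L] %in% comp) {
      partner <- setdiff(comp, leaves[1L])
      return(c("T1", "T2", "T3")[match(partner, leaves[-1L])])
    }
  }
  "star"
}

#' Bipartition (unrooted monophyly) test
#'
#' Tests whether a label set forms one side of some edge of the tree viewed
#' as unrooted.  Symmetric in the complement: `is_monophyletic(t, s)` equals
#' `is_monophyletic(t, setdiff(labels, s))`.
#'
#' @param tree A `"phylo"` object.
#' @param labels Character vector of leaf labels, non-empty and proper
#'   subset of the leaves.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (length(labels) == 0L || length(labels) >= length(labs))
    stop("label set must be a non-empty proper subset of the leaves")
  if (!all(labels %in% labs))
    stop("unknown leaf label(s): ",
         paste(setdiff(labels, labs), collapse = ", "))
  if (length(labels) == 1L || length(labels) == length(labs) - 1L)
    return(TRUE)  # pendant edge
  tgt <- sort(match(labels, labs))
  cmp <- sort(setdiff(seq_along(labs), tgt))
  part <- ape::prop.part(ape::unroot(tree))
  for (p in part) {
    sp <- sort(p)
    if (identical(sp, tgt) || identical(sp, cmp)) return(TRUE)
  }
  FALSE
}

#' Collapse short internal branches to polytomies
#'
#' Contracts every internal edge whose length is strictly below `epsilon`;
#' pendant (leaf) edges are never contracted.  This is the remedy for
#' short-branch artifacts: estimated gene trees whose internal branches are
#' effectively zero are converted to polytomies before species-tree
#' estimation.
#'
#' @param tree A `"phylo"` object.
#' @param epsilon Length threshold (same units as the branch lengths);
#'   `epsilon = 0` returns the tree unchanged.
#' @return A `"phylo"` object, possibly with polytomies.
#' @export
collapse_short_branches <- function(tree, epsilon) {
  stopifnot(inherits(tree, "phylo"), is.numeric(epsilon), epsilon >= 0)
  if (epsilon == 0 || is.null(tree$edge.length)) return(tree)
  ape::di2multi(tree, tol = epsilon)
}

#' Canonical scenario trees
#'
#' The gene trees used throughout the simulation scenarios, as fixed named
#' constants:
#' \describe{
#'   \item{star1}{4-taxon star, two very short branches (1e-4) to S1 and S3.}
#'   \item{star2}{as star1 with the short branches lengthened to 0.1.}
#'   \item{bif3}{4-taxon bifurcating tree with a short (1e-4) internal
#'     branch and short branches to S1 and S3.}
#'   \item{bif4}{as bif3 with the S1/S3 branches lengthened to 0.1.}
#'   \item{tree8}{8-taxon tree with clades (A,S1,S2,S3) and (B,S4,S5,S6) and
#'     two short (1e-4) branches leading to A and B, separated by two short
#'     internal branches.}
#'   \item{star_equal}{4-taxon star with equal branch lengths 0.01.}
#' }
#' Branch lengths are in expected substitutions per site.
#'
#' @return Named list of `"phylo"` objects.
#' @export
sba_trees <- function() {
  lapply(list(
    star1      = "(S1:0.0001,S2:0.01,S3:0.0001,S4:0.01);",
    star2      = "(S1:0.1,S2:0.01,S3:0.1,S4:0.01);",
    bif3       = "((S1:0.0001,S2:0.01):0.0001,S3:0.0001,S4:0.01);",
    bif4       = "((S1:0.1,S2:0.01):0.0001,S3:0.1,S4:0.01);",
    tree8      = paste0("((A:0.0001,((S1:0.01,S2:0.01):0.01,S3:0.01):0.01)",
                        ":0.0001,B:0.0001,",
                        "((S4:0.01,S5:0.01):0.01,S6:0.01):0.01);"),
    star_equal = "(S1:0.01,S2:0.01,S3:0.01,S4:0.01);"
  ), parse_newick)
}
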