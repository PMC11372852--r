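## NJst species-tree estimation: average internode (topological) distances
## between taxa across gene trees, followed by neighbor joining.

#' Average internode distance matrix across gene trees
#'
#' The internode distance between two taxa in one (unrooted) gene tree is
#' the number of internal nodes on the path connecting them (edges on the
#' path minus one); a polytomy vertex counts once, which is what makes
#' collapsed gene trees informative to downstream neighbor joining.
#' Entries are averaged over the gene trees containing both taxa.
#'
#' @param gene_trees List of `"phylo"` objects (branch lengths ignored).
#' @return Symmetric matrix over the union of taxon labels.
#' @export
internode_distances <- function(gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(length(gene_trees) >= 1L)
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(taxa)
  acc <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cnt <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (gt in gene_trees) {
    tr <- if (ape::is.rooted(gt) && ape::Ntip(gt) > 2L) ape::unroot(gt) else gt
    tr$edge.length <- rep(1, nrow(tr$edge))
    dd <- ape::dist.nodes(tr)[seq_len(ape::Ntip(tr)), seq_len(ape::Ntip(tr))]
    dd <- dd - 1        # edges on path minus one = internal nodes on path
    diag(dd) <- 0
    idx <- match(tr$tip.label, taxa)
    acc[idx, idx] <- acc[idx, idx] + dd
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  off <- upper.tri(cnt) | lower.tri(cnt)
  if (any(cnt[off] == 0L))
    stop("some taxon pair never co-occurs in a gene tree")
  out <- acc / pmax(cnt, 1L)
  diag(out) <- 0
  out
}

#' Neighbor joining
#'
#' Classical NJ on a distance matrix (via [ape::nj()]); negative estimated
#' branch lengths are clamped to zero.
#'
#' @param d Symmetric distance matrix with at least 3 taxa.
#' @return Unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3L) stop("need a distance matrix of >= 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' NJst species-tree estimation
#'
#' Estimates a species tree from gene trees by neighbor joining on average
#' internode distances.  With `collapse` set, internal gene-tree branches
#' shorter than the threshold are first contracted to polytomies
#' ([collapse_short_branches()]) -- the remedy that removes the systematic
#' signal carried by artifactually resolved short branches.
#'
#' @param gene_trees List of `"phylo"` gene trees.
#' @param collapse Optional length threshold; `NULL` to use the trees as
#'   given.
#' @return Unrooted `"phylo"` species-tree estimate.
#' @export
njst <- function(gene_trees, collapse = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!is.null(collapse))
    gene_trees <- lapply(gene_trees, collapse_short_branches,
                         epsilon = collapse)
  neighbor_joining(internode_distances(gene_trees))
}
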