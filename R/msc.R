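## Multispecies coalescent simulation.
##
## Convention: branch lengths tau and population sizes theta are both in
## mutation units; a pair of lineages in a population with parameter theta
## coalesces at rate 2/theta, so k lineages coalesce at rate k(k-1)/theta.
## One allele is sampled per species.  Species trees need not be
## ultrametric: the coalescent runs per population for the duration of that
## population's branch, and a species' tip branch contributes its length
## directly to the gene-tree terminal branch.

#' Build a species tree with population-size parameters
#'
#' @param tree A rooted `"phylo"` object (or newick string) whose branch
#'   lengths are divergence times tau in mutation units.
#' @param theta Population size parameter(s) for the ancestral populations:
#'   either a single value used for every internal node including the root,
#'   or a vector named by internal node number, or a vector with elements
#'   `root` and `internal` giving the root value and a common value for all
#'   other ancestral populations.
#' @return A `"species_tree"` object.
#' @export
species_tree <- function(tree, theta) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  th <- rep(NA_real_, max(nodes))
  if (!is.null(names(theta)) && all(c("root", "internal") %in% names(theta))) {
    th[nodes] <- theta[["internal"]]
    th[ntip + 1L] <- theta[["root"]]
  } else if (!is.null(names(theta))) {
    th[as.integer(names(theta))] <- theta
  } else if (length(theta) == 1L) {
    th[nodes] <- theta
  } else if (length(theta) == tree$Nnode) {
    th[nodes] <- theta
  } else stop("theta must be scalar, per-internal-node, or c(root=, internal=)")
  if (any(!is.finite(th[nodes])) || any(th[nodes] <= 0))
    stop("theta must be positive for every ancestral population")
  structure(list(tree = tree, theta = th), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  ntip <- ape::Ntip(x$tree)
  cat("species tree with", ntip, "species\n ",
      write_newick(x$tree), "\n")
  cat("  theta (root):", x$theta[ntip + 1L], "\n")
  other <- x$theta[-(seq_len(ntip + 1L))]
  if (length(other))
    cat("  theta (other ancestral):", paste(unique(other), collapse = ", "),
        "\n")
  invisible(x)
}

#' The three scenario species trees
#'
#' Star, bifurcating and 8-taxon species trees with short branches leading
#' to the focal pair (S1/S3, or A/B), root population theta = 1e-4 and
#' (where present) other ancestral populations theta = 0.01.
#'
#' @return Named list of `"species_tree"` objects
#'   (`sp_star`, `sp_bif`, `sp_tree8`).
#' @export
sba_species_trees <- function() {
  list(
    sp_star = species_tree("(S1:0.0001,S2:0.01,S3:0.0001,S4:0.01);",
                           theta = 1e-4),
    sp_bif = species_tree(
      "(((S1:0.0001,S2:0.01):0.0001,S3:0.0001):0.0001,S4:0.01);",
      theta = c(root = 1e-4, internal = 0.01)),
    sp_tree8 = species_tree(
      paste0("(((A:0.0001,((S1:0.01,S2:0.01):0.01,S3:0.02):0.01):0.0001,",
             "B:0.0001):0.0001,((S4:0.01,S5:0.01):0.01,S6:0.02):0.01);"),
      theta = c(root = 1e-4, internal = 0.01))
  )
}

#' Probability two lineages fail to coalesce
#'
#' For two lineages spending time `tau` in a population with parameter
#' `theta`, the no-coalescence probability is `exp(-2 tau / theta)` under
#' the pairwise rate 2/theta.
#'
#' @param tau Branch duration in mutation units, `>= 0`.
#' @param theta Population size parameter, `> 0`.
#' @return Probability.
#' @export
no_coal_prob_2 <- function(tau, theta) {
  if (any(tau < 0)) stop("tau must be >= 0")
  if (any(theta <= 0)) stop("theta must be > 0")
  exp(-2 * tau / theta)
}

#' Probability three lineages fail to coalesce
#'
#' Three lineages form three pairs, so no coalescence over duration `tau`
#' has probability `exp(-6 tau / theta)`.
#'
#' @inheritParams no_coal_prob_2
#' @return Probability.
#' @export
no_coal_prob_3 <- function(tau, theta) {
  if (any(tau < 0)) stop("tau must be >= 0")
  if (any(theta <= 0)) stop("theta must be > 0")
  exp(-6 * tau / theta)
}

#' Probability that all four alleles coalesce in the root population
#'
#' For an asymmetric (caterpillar) 4-taxon species tree
#' `(((S1,S2):tau2,S3):?,S4)`-shaped with (tau1, theta1) on the S1-S2
#' ancestral branch and (tau2, theta2) on the S1-S2-S3 ancestral branch,
#' the four alleles all reach the root population with probability
#' `p = no_coal_prob_2(tau1, theta1) * no_coal_prob_3(tau2, theta2)`.
#' When this probability is near 1 the gene trees behave as if generated
#' from a star species tree, the regime in which short branch attraction
#' biases every ML gene tree the same way.
#'
#' @param stree A 4-taxon asymmetric `"species_tree"`.
#' @return Probability in `(0, 1]`.
#' @export
root_coal_scenario_prob <- function(stree) {
  stopifnot(inherits(stree, "species_tree"))
  tr <- stree$tree
  ntip <- ape::Ntip(tr)
  if (ntip != 4L || tr$Nnode != 3L)
    stop("expected a 4-taxon bifurcating (caterpillar) species tree")
  root <- ntip + 1L
  ## internal nodes other than the root, ordered deepest-first
  depth <- ape::node.depth.edgelength(tr)
  inner <- setdiff(root:(ntip + tr$Nnode), root)
  kids <- tabulate(tr$edge[, 1], nbins = max(tr$edge))
  ## n2 = ancestor of the cherry (2 tips), n3 = ancestor of three species
  tipsets <- lapply(inner, function(n) ape::extract.clade(tr, n)$tip.label)
  n2 <- inner[lengths(tipsets) == 2L]
  n3 <- inner[lengths(tipsets) == 3L]
  if (length(n2) != 1L || length(n3) != 1L)
    stop("species tree is not a caterpillar")
  elen <- function(n) tr$edge.length[tr$edge[, 2] == n]
  no_coal_prob_2(elen(n2), stree$theta[n2]) *
    no_coal_prob_3(elen(n3), stree$theta[n3])
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Standard MSC with one allele per species: within each ancestral
#' population the current lineages coalesce at pairwise rate 2/theta for
#' the duration of that population's branch; surviving lineages propagate
#' rootward, and coalescence continues in the root population until one
#' lineage remains.  Gene-tree branch lengths are accumulated durations
#' plus coalescent waiting times (mutation units); a species' tip branch
#' length is inherited by the allele sampled from it.
#'
#' @param stree A `"species_tree"`.
#' @return A rooted binary `"phylo"` gene tree with attribute
#'   `n_root_lineages`, the number of lineages that entered the root
#'   population (useful for checking the no-coalescence probabilities).
#' @export
simulate_gene_tree <- function(stree) {
  stopifnot(inherits(stree, "species_tree"))
  tr <- stats::reorder(stree$tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode_max <- 2L * ntip - 1L   # gene tree is binary
  g_edge <- matrix(0L, 0L, 2L)
  g_len <- numeric(0)
  next_g <- ntip + 1L           # next internal gene-node id (assign from top later)
  ## lineages per species-tree node: list of (gene node id, pending length)
  lin_id <- vector("list", max(tr$edge))
  lin_len <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) {
    lin_id[[i]] <- i
    lin_len[[i]] <- 0
  }
  ## gene tree edges recorded as child id + length; parents assigned on the fly
  edges <- list()
  new_node <- ntip  # counter; internal ids ntip+1, ...
  coalesce_in <- function(ids, lens, theta, duration) {
    elapsed <- 0
    while (length(ids) > 1L) {
      k <- length(ids)
      rate <- k * (k - 1) / theta        # k choose 2 pairs at rate 2/theta
      wait <- stats::rexp(1, rate)
      if (elapsed + wait > duration) break
      elapsed <- elapsed + wait
      lens <- lens + wait
      pair <- sample.int(k, 2L)
      new_node <<- new_node + 1L
      edges[[length(edges) + 1L]] <<- c(new_node, ids[pair[1]], lens[pair[1]])
      edges[[length(edges) + 1L]] <<- c(new_node, ids[pair[2]], lens[pair[2]])
      ids <- c(ids[-pair], new_node)
      lens <- c(lens[-pair], 0)
    }
    lens <- lens + (duration - elapsed)
    list(ids = ids, lens = lens)
  }
  ## walk species-tree edges in postorder: each edge (parent -> child) is the
  ## population above 'child' with duration = edge length and theta of child
  for (i in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[i, 2L]; par <- tr$edge[i, 1L]
    dur <- tr$edge.length[i]
    if (ch <= ntip) {
      ## tip branch: no coalescence possible (single allele); just add tau
      res <- list(ids = lin_id[[ch]], lens = lin_len[[ch]] + dur)
    } else {
      res <- coalesce_in(lin_id[[ch]], lin_len[[ch]], stree$theta[ch], dur)
    }
    lin_id[[par]] <- c(lin_id[[par]], res$ids)
    lin_len[[par]] <- c(lin_len[[par]], res$lens)
  }
  root <- ntip + 1L
  n_root <- length(lin_id[[root]])
  res <- coalesce_in(lin_id[[root]], lin_len[[root]], stree$theta[root], Inf)
  stopifnot(length(res$ids) == 1L)
  em <- do.call(rbind, edges)
  ## renumber internal nodes: gene root must be ntip+1 in a phylo object
  nint <- new_node - ntip
  g_root <- res$ids
  old <- c(seq_len(ntip), g_root, setdiff((ntip + 1L):new_node, g_root))
  newid <- integer(new_node)
  newid[old] <- c(seq_len(ntip), ntip + 1L, if (nint > 1L) (ntip + 2L):(ntip + nint))
  gt <- list(edge = cbind(newid[em[, 1]], newid[em[, 2]]),
             edge.length = em[, 3],
             tip.label = tr$tip.label,
             Nnode = nint)
  class(gt) <- "phylo"
  gt <- stats::reorder(gt, "cladewise")
  attr(gt, "n_root_lineages") <- n_root
  gt
}

#' Simulate many gene trees
#'
#' @param stree A `"species_tree"`.
#' @param n Number of gene trees.
#' @return List of `"phylo"` gene trees (class `"multiPhylo"`).
#' @export
simulate_gene_trees <- function(stree, n) {
  out <- replicate(n, simulate_gene_tree(stree), simplify = FALSE)
  class(out) <- "multiPhylo"
  out
}
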