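## Maximum-likelihood tree estimation.  The likelihood machinery (pruning
## algorithm, branch-length optimization, NNI rearrangement) is provided by
## phangorn's pml/optim.pml; this module wraps it behind a quartet engine
## that scores all three resolved topologies explicitly (so tie handling is
## under our control, unlike in the greedy search phases of the standard
## ML programs whose behavior this package studies) and an NJ-seeded NNI
## hill-climb for larger trees.

EDGE_MIN <- 1e-8  # optim.pml lower bound for branch lengths

.as_phyDat <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  phangorn::phyDat(m, type = "DNA")
}

.pml_model_args <- function(model) {
  ncat <- if (is.null(model$alpha)) 1L else model$ncat
  list(bf = model$bf, Q = model$rates,
       shape = if (is.null(model$alpha)) 1 else model$alpha,
       k = ncat)
}

.pml_fit <- function(tree, dat, model, ...) {
  a <- .pml_model_args(model)
  tree$edge.length[is.na(tree$edge.length) |
                     tree$edge.length < EDGE_MIN] <- EDGE_MIN
  phangorn::pml(tree, dat, bf = a$bf, Q = a$Q, shape = a$shape, k = a$k, ...)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning likelihood with the model's fixed parameters;
#' discrete-gamma categories are averaged and gap states marginalized.
#'
#' @param tree `"phylo"` with branch lengths; leaves must match the
#'   alignment's taxa.
#' @param alignment Alignment matrix.
#' @param model An `"sba_model"`.
#' @return Log-likelihood (numeric scalar).
#' @export
loglik <- function(tree, alignment, model) {
  m <- as_alignment_matrix(alignment)
  if (!setequal(rownames(m), tree$tip.label))
    stop("alignment taxa do not match tree leaves")
  as.numeric(stats::logLik(.pml_fit(tree, .as_phyDat(m), model)))
}

.new_ml_fit <- function(tree, logl, model, topology = NA_character_,
                        candidates = NULL, tie = FALSE) {
  structure(list(tree = tree, loglik = logl, model_label = model$label,
                 topology = topology, candidates = candidates, tie = tie),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("ML tree fit (", x$model_label, ")\n", sep = "")
  if (!is.na(x$topology)) cat("  quartet topology:", x$topology,
                              if (isTRUE(x$tie)) "(tie-broken)" else "", "\n")
  cat("  log-likelihood :", format(x$loglik, digits = 10), "\n")
  cat(" ", write_newick(x$tree, digits = 6), "\n")
  invisible(x)
}

#' @export
logLik.ml_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$tree$edge), class = "logLik")
}

#' @export
coef.ml_fit <- function(object, ...) object$tree$edge.length

#' @export
summary.ml_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$candidates)) {
    cat("  candidate log-likelihoods:\n")
    print(object$candidates)
  }
  invisible(object)
}

#' Optimize branch lengths on a fixed topology
#'
#' @param tree `"phylo"` topology (branch lengths used as starting values;
#'   missing/short ones floored at the optimizer's lower bound `1e-8`).
#' @param alignment Alignment matrix.
#' @param model An `"sba_model"` (parameters stay fixed; only edges move).
#' @return An `"ml_fit"`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model) {
  m <- as_alignment_matrix(alignment)
  if (!setequal(rownames(m), tree$tip.label))
    stop("alignment taxa do not match tree leaves")
  fit <- .pml_fit(tree, .as_phyDat(m), model)
  fit <- suppressWarnings(
    phangorn::optim.pml(fit, optEdge = TRUE,
                        control = phangorn::pml.control(trace = 0)))
  .new_ml_fit(fit$tree, as.numeric(stats::logLik(fit)), model)
}

## the three resolved quartet topologies for taxa in row order
.quartet_candidates <- function(taxa, init = 0.05) {
  mk <- function(a, b, c, d) parse_newick(sprintf(
    "((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
    a, init, b, init, init / 2, c, init, d, init))
  list(T1 = mk(taxa[1], taxa[2], taxa[3], taxa[4]),
       T2 = mk(taxa[1], taxa[3], taxa[2], taxa[4]),
       T3 = mk(taxa[1], taxa[4], taxa[2], taxa[3]))
}

#' Exhaustive ML quartet estimation
#'
#' Optimizes branch lengths on each of the three resolved topologies for
#' the four taxa (in alignment row order) and returns the best.  Fits
#' whose log-likelihoods are within `tie_tol` of the maximum are treated
#' as tied: with `tie_rule = "random"` one of them is chosen uniformly at
#' random (mimicking a program forced to output some bifurcation, but
#' without any systematic preference); with `tie_rule = "star"` the star
#' topology is returned.
#'
#' @param alignment Alignment matrix with exactly 4 rows.
#' @param model An `"sba_model"`.
#' @param tie_rule `"random"` or `"star"`.
#' @param tie_tol Log-likelihood tie tolerance (default `1e-9`).
#' @param leaf_order Reference order of the four taxa for the topology
#'   labels: `"T1"` groups the first with the second taxon, `"T2"` the
#'   first with the third, `"T3"` the first with the fourth.  Defaults to
#'   the sorted taxon labels (so for S1..S4, `"T2"` is the (S1,S3)
#'   grouping regardless of alignment row order).
#' @return An `"ml_fit"`; `$topology` is `"T1"`, `"T2"`, `"T3"` or
#'   `"star"`, `$candidates` the three candidate log-likelihoods, and
#'   `$internal_length` the fitted internal branch length (NA for star).
#' @export
ml_quartet <- function(alignment, model, tie_rule = c("random", "star"),
                       tie_tol = 1e-9, leaf_order = NULL) {
  tie_rule <- match.arg(tie_rule)
  m <- as_alignment_matrix(alignment)
  if (nrow(m) != 4L) stop("quartet estimation requires exactly 4 taxa")
  if (is.null(leaf_order)) leaf_order <- sort(rownames(m))
  if (!setequal(leaf_order, rownames(m)))
    stop("leaf_order must be a permutation of the alignment taxa")
  dat <- .as_phyDat(m)
  cands <- .quartet_candidates(leaf_order)
  fits <- lapply(cands, function(tt) {
    suppressWarnings(
      phangorn::optim.pml(.pml_fit(tt, dat, model), optEdge = TRUE,
                          control = phangorn::pml.control(trace = 0)))
  })
  lls <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  mx <- max(lls)
  tied <- which(lls >= mx - tie_tol)
  if (length(tied) == 1L) {
    pick <- tied; tie <- FALSE
  } else if (tie_rule == "star") {
    star <- ape::di2multi(fits[[tied[1]]]$tree, tol = 1)  # collapse internal
    out <- .new_ml_fit(star, mx, model, topology = "star",
                       candidates = lls, tie = TRUE)
    out$internal_length <- NA_real_
    return(out)
  } else {
    pick <- sample(tied, 1L); tie <- TRUE
  }
  tree <- fits[[pick]]$tree
  internal <- tree$edge.length[tree$edge[, 2] > ape::Ntip(tree)]
  out <- .new_ml_fit(tree, unname(lls[pick]), model,
                     topology = names(cands)[pick],
                     candidates = lls, tie = tie)
  out$internal_length <- internal[1]
  out
}

#' Jukes-Cantor distance between two sequences
#'
#' `-3/4 log(1 - 4/3 p)` with `p` the mismatch fraction over columns where
#' neither sequence has a gap; saturated pairs (`p >= 3/4`) are clamped to
#' `max_dist`.
#'
#' @param x,y Character vectors of equal length.
#' @param max_dist Clamp value for saturated pairs.
#' @return Distance in expected substitutions per site.
#' @export
jc_distance <- function(x, y, max_dist = 10) {
  if (length(x) != length(y)) stop("sequences differ in length")
  ok <- x != "-" & y != "-"
  if (!any(ok)) stop("no comparable (gap-free) sites")
  p <- mean(x[ok] != y[ok])
  if (p >= 0.75) return(max_dist)
  max(0, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Jukes-Cantor distance matrix
#' @param alignment Alignment matrix.
#' @param max_dist Clamp for saturated pairs.
#' @return Symmetric distance matrix.
#' @export
jc_distance_matrix <- function(alignment, max_dist = 10) {
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- jc_distance(m[i, ], m[j, ], max_dist)
  d
}

#' ML tree search (NJ starting tree + NNI hill climbing)
#'
#' For four taxa this delegates to the exhaustive [ml_quartet()].  For
#' larger trees the search starts from neighbor joining on Jukes-Cantor
#' distances and hill-climbs over nearest-neighbor interchanges, with
#' branch lengths re-optimized along the way, until no rearrangement
#' improves the likelihood -- the same greedy scheme (start tree +
#' local rearrangement with strict improvement) used by standard ML
#' programs, which resolves likelihood-flat regions in favor of the
#' starting tree.
#'
#' @param alignment Alignment matrix, `n >= 4` taxa.
#' @param model An `"sba_model"`.
#' @param tie_rule Passed to [ml_quartet()] when `n == 4`.
#' @return An `"ml_fit"`.
#' @export
ml_search <- function(alignment, model, tie_rule = c("random", "star")) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 4L) stop("need at least 4 taxa")
  if (nrow(m) == 4L) return(ml_quartet(m, model, tie_rule))
  dat <- .as_phyDat(m)
  start <- ape::nj(jc_distance_matrix(m))
  start$edge.length[start$edge.length < EDGE_MIN] <- EDGE_MIN
  fit <- .pml_fit(start, dat, model)
  fit <- suppressWarnings(
    tryCatch(
      phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                          control = phangorn::pml.control(trace = 0)),
      error = function(e)
        phangorn::optim.pml(fit, optEdge = TRUE,
                            control = phangorn::pml.control(trace = 0))))
  .new_ml_fit(fit$tree, as.numeric(stats::logLik(fit)), model)
}
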