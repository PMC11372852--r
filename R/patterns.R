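## Site-pattern probability theory for four-taxon trees under Jukes-Cantor.
##
## A column of a 4-taxon alignment falls into one of 15 classes defined by
## the equality structure of its bases (the 15 set partitions of 4 items).
## Three classes -- xxyy, xyxy, xyyx -- are parsimony-informative and map to
## the quartet topologies T1 = S1S2|S3S4, T2 = S1S3|S2S4, T3 = S1S4|S2S3.
## Class probabilities are computed by exhaustive enumeration of root and
## leaf states, which is exact and avoids transcription ambiguities in
## closed-form expressions.

PATTERN_CLASSES <- c("xxxx",
                     "xxxy", "xxyx", "xyxx", "yxxx",
                     "xxyy", "xyxy", "xyyx",
                     "xxyz", "xyxz", "xyzx", "yxxz", "yxzx", "yzxx",
                     "xyzw")

## first-occurrence partition code -> class name
PATTERN_CODE <- c("1111" = "xxxx",
                  "1112" = "xxxy", "1121" = "xxyx", "1211" = "xyxx",
                  "1222" = "yxxx",
                  "1122" = "xxyy", "1212" = "xyxy", "1221" = "xyyx",
                  "1123" = "xxyz", "1213" = "xyxz", "1231" = "xyzx",
                  "1223" = "yxxz", "1232" = "yxzx", "1233" = "yzxx",
                  "1234" = "xyzw")

INFORMATIVE <- c("xxyy", "xyxy", "xyyx")  # map to T1, T2, T3

#' The 15 site-pattern classes
#'
#' @return Character vector of the 15 class labels in canonical order
#'   (1 constant, 7 two-state, 6 three-state, 1 four-state class).
#' @export
pattern_classes <- function() PATTERN_CLASSES

## integer states 1..4 -> first-occurrence code string, vectorized over
## columns of a 4 x n matrix
.partition_codes <- function(m) {
  apply(m, 2, function(col) {
    code <- match(col, unique(col))
    paste(code, collapse = "")
  })
}

#' Classify an alignment column
#'
#' Maps 4 nucleotides (leaf order S1, S2, S3, S4) to their equality-structure
#' class, e.g. `(A,A,C,C) -> "xxyy"`, `(A,C,A,C) -> "xyxy"`.
#'
#' @param bases Character vector of 4 bases in `A/C/G/T` (case-insensitive).
#' @return A class label from [pattern_classes()].
#' @export
classify_column <- function(bases) {
  stopifnot(length(bases) == 4L)
  b <- match(tolower(bases), BASES)
  if (anyNA(b)) stop("unknown base symbol: ",
                     paste(bases[is.na(b)], collapse = ", "))
  unname(PATTERN_CODE[paste(match(b, unique(b)), collapse = "")])
}

#' Tally site-pattern classes in a 4-taxon alignment
#'
#' Columns containing gaps (`-`) or other non-ACGT symbols are skipped.
#'
#' @param alignment Character matrix with exactly 4 rows (leaf order
#'   S1..S4) or an object accepted by [as_alignment_matrix()].
#' @return An `"pattern_counts"` object: named integer vector `omega` over
#'   the 15 classes and the total `K` of classified sites.
#' @export
count_patterns <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) != 4L) stop("pattern counting requires exactly 4 sequences")
  if (ncol(m) < 1L) stop("empty alignment")
  b <- matrix(match(tolower(m), BASES), nrow = 4L)
  ok <- colSums(is.na(b)) == 0L
  codes <- .partition_codes(b[, ok, drop = FALSE])
  omega <- table(factor(unname(PATTERN_CODE[codes]),
                        levels = PATTERN_CLASSES))
  omega <- stats::setNames(as.integer(omega), PATTERN_CLASSES)
  structure(list(omega = omega, K = sum(omega)), class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("site-pattern counts over", x$K, "sites\n")
  print(x$omega)
  invisible(x)
}

## all 256 leaf-state tuples and their class, computed once
.tuples <- local({
  g <- as.matrix(expand.grid(w = 1:4, x = 1:4, y = 1:4, z = 1:4))
  codes <- .partition_codes(t(g))
  list(states = g, class = unname(PATTERN_CODE[codes]))
})

.jc_P <- function(t) {
  same <- jc_match_prob(t)
  diff <- (1 - same) / 3
  matrix(diff, 4, 4) + diag(rep(same - diff, 4))
}

.make_pattern_probs <- function(member_probs) {
  p <- vapply(split(member_probs, .tuples$class), sum, numeric(1))
  p <- p[PATTERN_CLASSES]
  structure(list(p = p, lambda = unname(sum(p[INFORMATIVE])),
                 member = member_probs),
            class = "pattern_probs")
}

#' @export
print.pattern_probs <- function(x, ...) {
  cat("site-pattern class probabilities (JC)\n")
  print(signif(x$p, 6))
  cat("lambda (informative probability):", signif(x$lambda, 6), "\n")
  invisible(x)
}

#' Site-pattern class probabilities for a 4-taxon star tree
#'
#' Exact probabilities of the 15 pattern classes for a star tree with
#' terminal branch lengths `t1..t4` under Jukes-Cantor, obtained by summing
#' the root state (uniform prior 1/4) against the four branch transition
#' probabilities over all 256 leaf-state tuples.
#'
#' @param t1,t2,t3,t4 Terminal branch lengths for S1..S4 (substitutions
#'   per site, `>= 0`).
#' @return A `"pattern_probs"` object: class probabilities `p` (summing to
#'   1) and `lambda`, the total informative probability.
#' @export
star_class_probs <- function(t1, t2, t3, t4) {
  ts <- c(t1, t2, t3, t4)
  if (any(!is.finite(ts)) || any(ts < 0))
    stop("branch lengths must be finite and >= 0")
  P <- lapply(ts, .jc_P)
  st <- .tuples$states
  member <- numeric(256)
  for (h in 1:4)
    member <- member + 0.25 * P[[1]][h, st[, 1]] * P[[2]][h, st[, 2]] *
      P[[3]][h, st[, 3]] * P[[4]][h, st[, 4]]
  .make_pattern_probs(member)
}

#' Site-pattern class probabilities for a bifurcating quartet
#'
#' Exact class probabilities for the quartet `T2 = (S1,S3 | S2,S4)` with
#' internal branch `t0` and terminal branches `t1..t4` (S1 and S3 attach to
#' one internal node, S2 and S4 to the other).  Computed as the mixture of
#' the star-tree term (internal node states identical, weight
#' `1/4 + 3/4 exp(-4 t0/3)`) and the mismatched-state term (weight equal to
#' the complement; conditional on a mismatch the second internal state is
#' uniform over the three other bases under JC).  As `t0 -> 0` this reduces
#' to [star_class_probs()]; as `t0` grows the `xyxy` class supporting the
#' true tree dominates the informative classes.
#'
#' @param t0 Internal branch length `>= 0`.
#' @param t1,t2,t3,t4 Terminal branch lengths for S1..S4.
#' @return A `"pattern_probs"` object.
#' @export
quartet_class_probs <- function(t0, t1, t2, t3, t4) {
  ts <- c(t0, t1, t2, t3, t4)
  if (any(!is.finite(ts)) || any(ts < 0))
    stop("branch lengths must be finite and >= 0")
  P <- lapply(c(t1, t2, t3, t4), .jc_P)
  st <- .tuples$states
  w_same <- jc_match_prob(t0)
  ## matched internal states: star term
  same <- numeric(256)
  for (h in 1:4)
    same <- same + 0.25 * P[[1]][h, st[, 1]] * P[[2]][h, st[, 2]] *
      P[[3]][h, st[, 3]] * P[[4]][h, st[, 4]]
  ## mismatched internal states: H serves S1,S3; L != H serves S2,S4
  diff <- numeric(256)
  for (h in 1:4) for (l in setdiff(1:4, h))
    diff <- diff + (1 / 12) * P[[1]][h, st[, 1]] * P[[3]][h, st[, 3]] *
      P[[2]][l, st[, 2]] * P[[4]][l, st[, 4]]
  .make_pattern_probs(w_same * same + (1 - w_same) * diff)
}

#' Topology favored by the informative pattern classes
#'
#' Argmax over the informative classes, mapped `xxyy -> T1`, `xyxy -> T2`,
#' `xyyx -> T3`; exact ties give `"star"`.
#'
#' @param x A `"pattern_probs"` or `"pattern_counts"` object.
#' @param tol Tie tolerance for probabilities (counts are compared
#'   exactly).
#' @return One of `"T1"`, `"T2"`, `"T3"`, `"star"`.
#' @export
favored_topology <- function(x, tol = 0) {
  v <- if (inherits(x, "pattern_probs")) x$p[INFORMATIVE]
       else if (inherits(x, "pattern_counts")) x$omega[INFORMATIVE]
       else stop("need pattern_probs or pattern_counts")
  mx <- max(v)
  w <- which(v >= mx - tol)
  if (length(w) > 1L) "star" else c("T1", "T2", "T3")[w]
}

#' Probability that an alignment contains an informative site
#'
#' `1 - (1 - lambda)^K`: the chance that at least one of `K` i.i.d. sites
#' falls in an informative class, hence that ML resolves the quartet.
#' Converges to 1 as `K` grows whenever `lambda > 0`.
#'
#' @param lambda Informative-class probability in `[0, 1]`.
#' @param K Number of sites `>= 0`.
#' @return Probability.
#' @export
prob_resolved <- function(lambda, K) {
  stopifnot(lambda >= 0, lambda <= 1, K >= 0)
  1 - (1 - lambda)^K
}

#' Exact distribution of the ML quartet topology at finite length
#'
#' For an alignment of `K` i.i.d. sites with informative class
#' probabilities taken from `probs`, enumerates all compositions of `K`
#' into counts of (xxyy, xyxy, xyyx, other) and sums the multinomial
#' probability of each, assigning a composition to the topology whose
#' informative count is strictly largest.  Compositions with a tied maximum
#' go to `"star"` (`tie_rule = "star"`) or are split evenly among the tied
#' topologies (`tie_rule = "random"`, the expected behavior of a program
#' forced to output a bifurcation with a fair random tie-break).
#'
#' @param probs A `"pattern_probs"` object.
#' @param K Number of sites (1 to `max_K`).
#' @param tie_rule `"star"` or `"random"`.
#' @param max_K Enumeration cap; the number of compositions grows as
#'   `K^3/6`, so the default cap keeps this exact computation sub-second.
#' @return Named probability vector over `T1`, `T2`, `T3`, `star`
#'   (sums to 1).
#' @export
exact_mle_distribution <- function(probs, K, tie_rule = c("star", "random"),
                                   max_K = 200) {
  stopifnot(inherits(probs, "pattern_probs"), K >= 1)
  tie_rule <- match.arg(tie_rule)
  if (K > max_K)
    stop("K exceeds the enumeration cap (", max_K,
         "); use Monte Carlo simulation for longer alignments")
  pi <- probs$p[INFORMATIVE]
  q <- max(0, 1 - sum(pi))
  ## all (a, b, c) with a + b + c <= K
  a <- unlist(lapply(0:K, function(i) rep(i, (K - i + 1) * (K - i + 2) / 2)))
  bc <- do.call(rbind, lapply(0:K, function(i) {
    b <- unlist(lapply(0:(K - i), function(j) rep(j, K - i - j + 1)))
    cc <- unlist(lapply(0:(K - i), function(j) 0:(K - i - j)))
    cbind(b, cc)
  }))
  b <- bc[, 1]; cc <- bc[, 2]
  d <- K - a - b - cc
  logp <- lgamma(K + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(cc + 1) -
    lgamma(d + 1)
  safelog <- function(p, n) ifelse(n == 0, 0, n * log(p))
  logp <- logp + safelog(pi[1], a) + safelog(pi[2], b) +
    safelog(pi[3], cc) + safelog(q, d)
  w <- exp(logp)
  mx <- pmax(a, b, cc)
  out <- c(T1 = 0, T2 = 0, T3 = 0, star = 0)
  uniq1 <- (a == mx) & (b < mx) & (cc < mx)
  uniq2 <- (b == mx) & (a < mx) & (cc < mx)
  uniq3 <- (cc == mx) & (a < mx) & (b < mx)
  tied <- !(uniq1 | uniq2 | uniq3)
  out["T1"] <- sum(w[uniq1])
  out["T2"] <- sum(w[uniq2])
  out["T3"] <- sum(w[uniq3])
  if (tie_rule == "star") {
    out["star"] <- sum(w[tied])
  } else {
    ntied <- (a == mx) + (b == mx) + (cc == mx)
    out["T1"] <- out["T1"] + sum(w[tied & a == mx] / ntied[tied & a == mx])
    out["T2"] <- out["T2"] + sum(w[tied & b == mx] / ntied[tied & b == mx])
    out["T3"] <- out["T3"] + sum(w[tied & cc == mx] / ntied[tied & cc == mx])
  }
  out
}

#' Check the star-tree pattern-probability orderings
#'
#' Evaluates, from [star_class_probs()], the two orderings that drive
#' short branch attraction on star trees:
#' \enumerate{
#'   \item the 12 uninformative classes together outweigh the 3
#'     informative ones (so the unresolved tree is the single most probable
#'     ML outcome at K = 1);
#'   \item when the two shortest branches are `t1` and `t2`
#'     (`max(t1, t2) < min(t3, t4)`), `xxyy` is the strictly largest
#'     informative class, so forced bifurcation favors grouping the two
#'     short branches.
#' }
#'
#' @param t1,t2,t3,t4 Star-tree branch lengths.
#' @return List with both truth values and their margins.
#' @export
check_sd1_inequalities <- function(t1, t2, t3, t4) {
  pr <- star_class_probs(t1, t2, t3, t4)
  lam <- pr$lambda
  uninf <- 1 - lam
  inf <- pr$p[INFORMATIVE]
  short_pair_first <- max(t1, t2) < min(t3, t4)
  list(
    uninformative_exceeds_informative = uninf > lam,
    uninformative_margin = uninf - lam,
    short_pair_is_first = short_pair_first,
    xxyy_strictly_largest = inf["xxyy"] > inf["xyxy"] &&
      inf["xxyy"] > inf["xyyx"],
    xxyy_margins = unname(c(inf["xxyy"] - inf["xyxy"],
                            inf["xxyy"] - inf["xyyx"]))
  )
}
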