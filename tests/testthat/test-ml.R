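test_that("pruning likelihood agrees with the analytic pattern theory", {
  # constant column on a zero-length tree: only the root prior remains
  aln1 <- matrix("a", 4, 1, dimnames = list(quartet_labels, NULL))
  tr0 <- t2_tree(0, 0, 0, 0, 0)
  expect_equal(loglik(tr0, aln1, jc), log(0.25), tolerance = 1e-5)

  # single columns on a JC quartet: exp(loglik) equals the per-member
  # probability from the exact class-probability enumeration
  pars <- c(0.02, 0.01, 0.03, 0.015, 0.025)
  qp <- do.call(quartet_class_probs, as.list(pars))
  tr <- t2_tree(pars[1], pars[2], pars[3], pars[4], pars[5])
  tup <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  set.seed(3)
  for (i in sample(256, 12)) {
    col <- matrix(c("a", "c", "g", "t")[tup[i, ]], 4, 1,
                  dimnames = list(quartet_labels, NULL))
    expect_equal(exp(loglik(tr, col, jc)), qp$member[i],
                 tolerance = 1e-10)
  }

  # doubling every column doubles the log-likelihood exactly
  set.seed(33)
  aln <- simulate_alignment(tr, jc, 80)
  expect_equal(loglik(tr, cbind(aln, aln), jc), 2 * loglik(tr, aln, jc),
               tolerance = 1e-9)
  expect_error(loglik(tr, rbind(aln, X = aln[1, ]), jc), "match")
})

test_that("branch-length optimization recovers the generating lengths", {
  set.seed(41)
  tr <- t2_tree(0.1, 0.05, 0.08, 0.06, 0.12)
  aln <- simulate_alignment(tr, jc, 100000)
  fit <- optimize_branch_lengths(tr, aln, jc)
  expect_s3_class(fit, "ml_fit")
  expect_equal(sort(coef(fit)), sort(tr$edge.length), tolerance = 0.1)
  # the optimum cannot be worse than the truth
  expect_gte(fit$loglik, loglik(tr, aln, jc))
  # identical sequences drive every branch to the lower bound
  set.seed(42)
  ident <- make_identical_alignment(500)
  flat <- optimize_branch_lengths(t2_tree(0.05), ident, jc)
  expect_true(all(coef(flat) <= 1e-7))
})

test_that("exhaustive quartet ML resolves by data and ties fairly", {
  # a single xxyy column supports T1 under JC
  col <- matrix(c("a", "a", "c", "c"), 4, 1,
                dimnames = list(quartet_labels, NULL))
  fit <- ml_quartet(col, jc)
  expect_equal(fit$topology, "T1")
  expect_length(fit$candidates, 3)
  expect_equal(fit$loglik, max(fit$candidates))

  # identical sequences with the star tie rule return the star
  set.seed(51)
  ident <- make_identical_alignment(200)
  expect_equal(ml_quartet(ident, jc, tie_rule = "star")$topology, "star")

  # a long internal branch is recovered consistently
  set.seed(52)
  hits <- 0
  for (r in 1:30) {
    aln <- simulate_alignment(t2_tree(0.1), jc, 1000)
    hits <- hits + (ml_quartet(aln, jc)$topology == "T2")
  }
  expect_gte(hits, 27)
})

test_that("tied likelihoods are broken uniformly (fair-engine contract)", {
  set.seed(61)
  tops <- replicate(1000, {
    ml_quartet(make_identical_alignment(60), jc, tie_rule = "random")$topology
  })
  props <- table(factor(tops, levels = c("T1", "T2", "T3"))) / 1000
  expect_true(all(abs(props - 1 / 3) < tol3se(1 / 3, 1000)))
})

test_that("JC distances follow the correction formula with gap handling", {
  x <- rep("a", 100)
  expect_equal(jc_distance(x, x), 0)
  y <- x; y[1:10] <- "c"
  expect_equal(jc_distance(x, y), -0.75 * log(1 - 4 * 0.1 / 3))
  z <- rep(c("a", "c"), 50)  # p = 0.5 still below saturation
  expect_lt(jc_distance(x, z), 10)
  w <- rep("c", 100)
  expect_equal(jc_distance(x, w), 10)   # saturated, clamped
  y[1:50] <- "-"
  expect_equal(jc_distance(x, y), 0)    # gapped mismatch sites skipped
  expect_error(jc_distance(rep("-", 5), rep("a", 5)), "comparable")
})

test_that("NJ+NNI search recovers informative trees and is order-invariant", {
  # tree8 variant with informative internal branches everywhere
  tr <- parse_newick(paste0(
    "((A:0.0001,((S1:0.01,S2:0.01):0.01,S3:0.01):0.01):0.01,B:0.0001,",
    "((S4:0.01,S5:0.01):0.01,S6:0.01):0.01);"))
  set.seed(71)
  hits <- 0
  for (r in 1:15) {
    aln <- simulate_alignment(tr, jc, 5000)
    fit <- ml_search(aln, jc)
    hits <- hits + (ape::dist.topo(ape::unroot(fit$tree),
                                   ape::unroot(tr)) == 0)
  }
  expect_gte(hits, 13)

  set.seed(72)
  aln <- simulate_alignment(tr, jc, 2000)
  f1 <- ml_search(aln, jc)
  f2 <- ml_search(aln[sample(nrow(aln)), ], jc)
  expect_equal(ape::dist.topo(ape::unroot(f1$tree), ape::unroot(f2$tree)),
               0, ignore_attr = TRUE)

  # n = 4 delegates to the exhaustive quartet engine
  set.seed(73)
  for (r in 1:10) {
    aln4 <- simulate_alignment(t2_tree(0.1), jc, 800)
    expect_equal(ml_search(aln4, jc)$topology,
                 ml_quartet(aln4, jc)$topology)
  }
})
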