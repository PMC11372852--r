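# independent oracle: class probabilities by explicit summation over root
# (and internal) states using transition_matrix(), classified per tuple
brute_star_probs <- function(t1, t2, t3, t4) {
  tup <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  P <- lapply(c(t1, t2, t3, t4), function(t) transition_matrix(jc, t))
  member <- numeric(256)
  for (h in 1:4)
    member <- member + 0.25 * P[[1]][h, tup[, 1]] * P[[2]][h, tup[, 2]] *
      P[[3]][h, tup[, 3]] * P[[4]][h, tup[, 4]]
  cls <- apply(tup, 1, function(b)
    classify_column(c("a", "c", "g", "t")[b]))
  vapply(split(member, cls), sum, numeric(1))[pattern_classes()]
}

brute_quartet_probs <- function(t0, t1, t2, t3, t4) {
  tup <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  P <- lapply(c(t0, t1, t2, t3, t4), function(t) transition_matrix(jc, t))
  member <- numeric(256)
  for (h in 1:4) for (l in 1:4)
    member <- member + 0.25 * P[[1]][h, l] *
      P[[2]][h, tup[, 1]] * P[[4]][h, tup[, 3]] *   # S1, S3 on node with H
      P[[3]][l, tup[, 2]] * P[[5]][l, tup[, 4]]     # S2, S4 on node with L
  cls <- apply(tup, 1, function(b)
    classify_column(c("a", "c", "g", "t")[b]))
  vapply(split(member, cls), sum, numeric(1))[pattern_classes()]
}

test_that("column classification follows the equality structure", {
  expect_equal(classify_column(c("A", "A", "A", "A")), "xxxx")
  expect_equal(classify_column(c("A", "A", "C", "C")), "xxyy")
  expect_equal(classify_column(c("A", "C", "A", "C")), "xyxy")
  expect_equal(classify_column(c("A", "C", "C", "A")), "xyyx")
  expect_equal(classify_column(c("C", "A", "A", "A")), "yxxx")
  expect_equal(classify_column(c("A", "C", "G", "T")), "xyzw")
  expect_equal(classify_column(c("G", "A", "G", "T")), "xyxz")
  expect_error(classify_column(c("A", "N", "C", "C")), "unknown base")
  # every tuple maps to a class; member counts are 4 / 12x7 / 24x6 / 24
  tup <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  cls <- apply(tup, 1, function(b)
    classify_column(c("a", "c", "g", "t")[b]))
  counts <- table(cls)[pattern_classes()]
  expect_equal(unname(as.integer(counts)),
               c(4, rep(12, 7), rep(24, 6), 24))
})

test_that("pattern counting tallies columns and ignores order and gaps", {
  m <- rbind(S1 = c("a", "a", "c"), S2 = c("a", "a", "c"),
             S3 = c("a", "c", "a"), S4 = c("a", "c", "a"))
  pc <- count_patterns(m)
  expect_equal(pc$K, 3)
  expect_equal(unname(pc$omega[c("xxxx", "xxyy")]), c(1L, 2L))
  expect_equal(count_patterns(m[, c(3, 1, 2)])$omega, pc$omega)

  set.seed(2)
  ident <- make_identical_alignment(50)
  expect_equal(unname(count_patterns(ident)$omega["xxxx"]), 50L)

  m[1, 2] <- "-"
  expect_equal(count_patterns(m)$K, 2)
})

test_that("star-tree class probabilities match exhaustive enumeration", {
  pr <- star_class_probs(0, 0, 0, 0)
  expect_equal(unname(pr$p["xxxx"]), 1)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)

  pr <- star_class_probs(0.05, 0.05, 0.05, 0.05)
  inf <- pr$p[c("xxyy", "xyxy", "xyyx")]
  expect_equal(max(inf) - min(inf), 0, tolerance = 1e-15)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)

  # members of a class are equiprobable under JC
  tup <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  cls <- apply(tup, 1, function(b)
    classify_column(c("a", "c", "g", "t")[b]))
  pr <- star_class_probs(0.03, 0.11, 0.02, 0.27)
  spread <- vapply(split(pr$member, cls),
                   function(v) diff(range(v)), numeric(1))
  expect_lt(max(spread), 1e-15)

  expect_equal(unname(star_class_probs(0.02, 0.13, 0.07, 0.31)$p),
               unname(brute_star_probs(0.02, 0.13, 0.07, 0.31)),
               tolerance = 1e-12)
  expect_error(star_class_probs(-0.1, 0, 0, 0), ">= 0")
})

test_that("short branches make their grouping pattern dominate (star)", {
  pr <- star_class_probs(1e-4, 1e-4, 0.01, 0.01)   # t1 <= t2 < t3 <= t4
  expect_gt(pr$p["xxyy"], pr$p["xyxy"])
  expect_gt(pr$p["xxyy"], pr$p["xyyx"])
  expect_equal(favored_topology(pr), "T1")
  expect_equal(favored_topology(star_class_probs(0.01, 0.01, 0.01, 0.01),
                                tol = 1e-14), "star")
})

test_that("bifurcating quartet probabilities: mixture equals enumeration", {
  for (pars in list(c(0.05, 0.01, 0.02, 0.03, 0.04),
                    c(0.3, 0.2, 0.01, 0.15, 0.08))) {
    got <- do.call(quartet_class_probs, as.list(pars))
    expect_equal(unname(got$p), unname(do.call(brute_quartet_probs,
                                               as.list(pars))),
                 tolerance = 1e-12)
    expect_equal(sum(got$p), 1, tolerance = 1e-12)
  }
})

test_that("quartet probabilities reduce to the star tree as t0 -> 0 and
           favor the true tree as t0 grows", {
  st <- star_class_probs(0.01, 0.02, 0.03, 0.04)
  qu <- quartet_class_probs(0, 0.01, 0.02, 0.03, 0.04)
  expect_equal(qu$p, st$p, tolerance = 1e-12)

  long <- quartet_class_probs(10, 0.05, 0.05, 0.05, 0.05)
  expect_gt(long$p["xyxy"], long$p["xxyy"])
  expect_gt(long$p["xyxy"], long$p["xyyx"])
  expect_equal(favored_topology(long), "T2")
})

test_that("probability of a resolved quartet follows 1-(1-lambda)^K", {
  expect_equal(prob_resolved(0, 1000), 0)
  expect_equal(prob_resolved(0.37, 1), 0.37)
  expect_equal(prob_resolved(0.01, 1000), 1 - 0.99^1000)
  expect_gte(prob_resolved(0.01, 1000), 0.9999)
  # monotone in both arguments
  expect_gt(prob_resolved(0.01, 200), prob_resolved(0.01, 100))
  expect_gt(prob_resolved(0.02, 100), prob_resolved(0.01, 100))
})

test_that("exact finite-K ML distribution: K = 1 case and symmetry", {
  pr <- star_class_probs(1e-4, 0.01, 1e-4, 0.01)
  d1 <- exact_mle_distribution(pr, 1)
  expect_equal(unname(d1["T1"]), unname(pr$p["xxyy"]), tolerance = 1e-12)
  expect_equal(unname(d1["T2"]), unname(pr$p["xyxy"]), tolerance = 1e-12)
  expect_equal(unname(d1["T3"]), unname(pr$p["xyyx"]), tolerance = 1e-12)
  expect_equal(unname(d1["star"]), 1 - pr$lambda, tolerance = 1e-12)

  eq <- exact_mle_distribution(star_class_probs(0.01, 0.01, 0.01, 0.01), 37)
  expect_equal(unname(eq["T1"]), unname(eq["T2"]), tolerance = 1e-12)
  expect_equal(unname(eq["T2"]), unname(eq["T3"]), tolerance = 1e-12)
  expect_equal(sum(eq), 1, tolerance = 1e-12)

  expect_error(exact_mle_distribution(pr, 500), "Monte Carlo")
})

test_that("exact finite-K ML distribution matches a Monte Carlo oracle", {
  pr <- star_class_probs(1e-4, 0.01, 1e-4, 0.01)
  K <- 50
  ex <- exact_mle_distribution(pr, K, tie_rule = "star")
  # oracle: multinomial draws + count-argmax rule
  set.seed(31)
  nmc <- 200000
  pi4 <- c(pr$p[c("xxyy", "xyxy", "xyyx")], 1 - pr$lambda)
  draws <- stats::rmultinom(nmc, K, pi4)[1:3, ]
  mx <- apply(draws, 2, max)
  unique_max <- colSums(draws == rep(mx, each = 3)) == 1L
  winner <- apply(draws, 2, which.max)
  mc <- c(T1 = mean(winner == 1 & unique_max),
          T2 = mean(winner == 2 & unique_max),
          T3 = mean(winner == 3 & unique_max),
          star = mean(!unique_max))
  for (k in names(mc)) {
    se <- sqrt(max(ex[k] * (1 - ex[k]), 1e-8) / nmc)
    expect_lt(abs(mc[k] - ex[k]), 3 * se + 1e-4)
  }
  # random tie rule redistributes exactly the star mass
  exr <- exact_mle_distribution(pr, K, tie_rule = "random")
  expect_equal(unname(exr["star"]), 0)
  expect_equal(sum(exr), 1, tolerance = 1e-12)
  expect_gte(exr["T2"], ex["T2"])
})

test_that("finite-K bias toward the short-pair grouping grows with K", {
  pr <- star_class_probs(1e-4, 0.01, 1e-4, 0.01)  # short pair = S1,S3 -> T2
  p1 <- exact_mle_distribution(pr, 1)["T2"]
  p10 <- exact_mle_distribution(pr, 10)["T2"]
  p100 <- exact_mle_distribution(pr, 100)["T2"]
  expect_gt(p10, p1)
  expect_gt(p100, p10)
})

test_that("star-tree pattern inequalities hold over random branch lengths", {
  set.seed(17)
  for (i in 1:1000) {
    ts <- sort(stats::runif(4, 1e-4, 1))
    chk <- check_sd1_inequalities(ts[1], ts[2], ts[3], ts[4])
    expect_true(chk$uninformative_exceeds_informative)
    expect_true(chk$xxyy_strictly_largest)
  }
  eq <- check_sd1_inequalities(0.01, 0.01, 0.01, 0.01)
  expect_lt(max(abs(eq$xxyy_margins)), 1e-14)
})
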