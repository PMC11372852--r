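## Scenario runners: end-to-end simulation experiments quantifying short
## branch attraction in gene trees and species trees, plus the exact
## multinomial goodness-of-fit test used to compare topology frequencies
## with the uniform expectation.

.binom_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Exact multinomial goodness-of-fit test
#'
#' Exact p-value for observed counts against expected category
#' probabilities: the total probability of all outcomes whose probability
#' does not exceed that of the observed outcome.  Exact enumeration is
#' used up to `n = 500` (3 categories); larger totals fall back to the
#' chi-squared approximation.
#'
#' @param counts Vector of 3 non-negative integer counts.
#' @param expected Vector of 3 probabilities summing to 1 (default
#'   uniform).
#' @return p-value.
#' @export
multinomial_gof <- function(counts, expected = rep(1 / 3, 3)) {
  stopifnot(length(counts) == 3L, length(expected) == 3L,
            all(counts >= 0), abs(sum(expected) - 1) < 1e-8)
  n <- sum(counts)
  if (n == 0L) stop("zero total count")
  if (n > 500L)
    return(suppressWarnings(
      stats::chisq.test(counts, p = expected)$p.value))
  a <- unlist(lapply(0:n, function(i) rep(i, n - i + 1L)))
  b <- unlist(lapply(0:n, function(i) 0:(n - i)))
  cc <- n - a - b
  lp <- lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(cc + 1)
  addl <- function(p, k) ifelse(k == 0, 0, k * log(p))
  lp <- lp + addl(expected[1], a) + addl(expected[2], b) + addl(expected[3], cc)
  obs <- lgamma(n + 1) - sum(lgamma(counts + 1)) +
    sum(ifelse(counts == 0, 0, counts * log(expected)))
  sum(exp(lp[lp <= obs + 1e-10]))
}

#' Scenario configuration
#'
#' @param name Scenario name: one of the gene-tree scenarios
#'   (`"star1"`, `"star2"`, `"bif3"`, `"bif4"`, `"tree8"`), species-tree
#'   scenarios (`"sp_star"`, `"sp_bif"`, `"sp_tree8"`) or noninformative
#'   scenarios (`"identical"`, `"saturated"`, `"saturated_missing"`,
#'   `"star_equal"`).
#' @param lengths Sequence lengths to run.
#' @param nrep Replicates per length (gene-tree and noninformative
#'   scenarios) or number of gene trees (species-tree scenarios).
#' @param seed Master seed; every run is fully determined by
#'   `(config, seed)`.
#' @param tie_rule Quartet tie rule.
#' @param collapse Optional collapse threshold for the species-tree
#'   pipeline.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(name, lengths = c(100, 500, 1000), nrep = 100,
                            seed = 1, tie_rule = "random", collapse = NULL) {
  stopifnot(nrep >= 1, all(lengths >= 1))
  structure(list(name = name, lengths = lengths, nrep = nrep, seed = seed,
                 tie_rule = tie_rule, collapse = collapse),
            class = "scenario_config")
}

## per-replicate model sampling policy shared by all scenarios
.scenario_model <- function() sample_gtr_params()

#' Run a gene-tree SBA scenario
#'
#' For each sequence length and replicate: sample a GTR+Gamma model,
#' simulate an alignment from the scenario's fixed gene tree, estimate the
#' ML tree (exhaustive quartet engine for 4 taxa, NJ+NNI search for more),
#' and record either the quartet topology (4 taxa; `"T2"` is the
#' (S1,S3)-grouping artifact) or whether A and B are grouped (8 taxa).
#'
#' @param config A `"scenario_config"` whose `name` is a gene-tree
#'   scenario or a `"phylo"` tree to use directly.
#' @return A `"scenario_result"`: data frame of per-length category
#'   proportions with binomial standard errors, plus per-replicate records.
#' @export
run_gene_tree_scenario <- function(config) {
  tree <- if (inherits(config$name, "phylo")) config$name
          else sba_trees()[[config$name]]
  if (is.null(tree)) stop("unknown scenario tree: ", config$name)
  ntip <- ape::Ntip(tree)
  set.seed(config$seed)
  recs <- list()
  for (K in config$lengths) {
    for (r in seq_len(config$nrep)) {
      model <- .scenario_model()
      aln <- simulate_alignment(tree, model, K)
      if (ntip == 4L) {
        fit <- ml_quartet(aln, model, tie_rule = config$tie_rule)
        recs[[length(recs) + 1L]] <- data.frame(
          K = K, rep = r, category = fit$topology,
          internal = if (is.na(fit$internal_length)) NA_real_
                     else fit$internal_length)
      } else {
        fit <- ml_search(aln, model)
        recs[[length(recs) + 1L]] <- data.frame(
          K = K, rep = r,
          category = if (is_monophyletic(fit$tree, c("A", "B")))
            "AB_grouped" else "AB_apart",
          internal = NA_real_)
      }
    }
  }
  records <- do.call(rbind, recs)
  .summarize_scenario(config, records)
}

.summarize_scenario <- function(config, records) {
  tab <- do.call(rbind, lapply(split(records, records$K), function(d) {
    t <- table(d$category)
    data.frame(K = d$K[1], category = names(t),
               count = as.integer(t),
               proportion = as.numeric(t) / nrow(d),
               se = .binom_se(as.numeric(t) / nrow(d), nrow(d)))
  }))
  rownames(tab) <- NULL
  structure(list(config = config, summary = tab, records = records),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  nm <- if (inherits(x$config$name, "phylo")) "custom tree" else x$config$name
  cat("scenario:", nm, " (seed", x$config$seed, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run a noninformative-data scenario
#'
#' Identical, saturated (optionally with missing data) or equal-branch
#' star-tree alignments, analyzed with the exhaustive quartet engine and a
#' fair random tie-break.  A fair engine must return the three resolved
#' topologies with equal probability 1/3; the exact multinomial test
#' p-value quantifies any deviation.
#'
#' @param config A `"scenario_config"` with `name` in `"identical"`,
#'   `"saturated"`, `"saturated_missing"`, `"star_equal"`.
#' @return A `"scenario_result"` with a `pvalues` element (exact
#'   multinomial test against uniform, per length).
#' @export
run_noninformative_scenario <- function(config) {
  gen <- switch(config$name,
    identical = function(K, model) make_identical_alignment(K),
    saturated = function(K, model) make_saturated_alignment(K),
    saturated_missing = function(K, model)
      apply_missing(make_saturated_alignment(K), 0.1, c("S1", "S2")),
    star_equal = function(K, model)
      simulate_alignment(sba_trees()$star_equal, model, K),
    stop("unknown noninformative scenario: ", config$name))
  set.seed(config$seed)
  recs <- list()
  for (K in config$lengths) {
    for (r in seq_len(config$nrep)) {
      model <- .scenario_model()
      aln <- gen(K, model)
      fit <- ml_quartet(aln, model, tie_rule = "random")
      recs[[length(recs) + 1L]] <- data.frame(K = K, rep = r,
                                              category = fit$topology,
                                              internal = NA_real_)
    }
  }
  records <- do.call(rbind, recs)
  out <- .summarize_scenario(config, records)
  out$pvalues <- vapply(split(records, records$K), function(d) {
    counts <- as.integer(table(factor(d$category,
                                      levels = c("T1", "T2", "T3"))))
    multinomial_gof(counts)
  }, numeric(1))
  out
}

#' Run a species-tree SBA pipeline
#'
#' Simulates gene trees from a species tree under the multispecies
#' coalescent, simulates an alignment per gene tree (fresh GTR+Gamma model
#' each), estimates each ML gene tree, and feeds the estimates to NJst.
#' Reports (a) topology/grouping proportions among true and estimated gene
#' trees, (b) the NJst species tree from the estimated gene trees (with
#' and without collapsing short internal branches when `config$collapse`
#' is set), and (c) among wrong-topology ML gene trees, the fraction whose
#' estimated internal branch is below `1e-5` -- the diagnostic motivating
#' the polytomy-collapse remedy.
#'
#' @param config A `"scenario_config"`; `name` one of `"sp_star"`,
#'   `"sp_bif"`, `"sp_tree8"` (or a `"species_tree"` object); `nrep` is
#'   the number of gene trees; the first element of `lengths` is the
#'   sequence length used.
#' @return A `"species_scenario_result"` list.
#' @export
run_species_tree_scenario <- function(config) {
  stree <- if (inherits(config$name, "species_tree")) config$name
           else sba_species_trees()[[config$name]]
  if (is.null(stree)) stop("unknown species-tree scenario: ", config$name)
  K <- config$lengths[1]
  ngene <- config$nrep
  ntip <- ape::Ntip(stree$tree)
  focal4 <- ntip == 4L
  set.seed(config$seed)
  true_trees <- vector("list", ngene)
  est_trees <- vector("list", ngene)
  rec <- data.frame(gene = seq_len(ngene),
                    true_cat = NA_character_, est_cat = NA_character_,
                    internal = NA_real_)
  qlabs <- paste0("S", 1:4)
  for (g in seq_len(ngene)) {
    gt <- simulate_gene_tree(stree)
    true_trees[[g]] <- gt
    model <- .scenario_model()
    aln <- simulate_alignment(gt, model, K)
    if (focal4) {
      fit <- ml_quartet(aln, model, tie_rule = config$tie_rule)
      rec$true_cat[g] <- quartet_topology(gt, qlabs)
      rec$est_cat[g] <- fit$topology
      rec$internal[g] <- fit$internal_length
      est_trees[[g]] <- fit$tree
    } else {
      fit <- ml_search(aln, model)
      rec$true_cat[g] <- if (is_monophyletic(gt, c("A", "B")))
        "AB_grouped" else "AB_apart"
      rec$est_cat[g] <- if (is_monophyletic(fit$tree, c("A", "B")))
        "AB_grouped" else "AB_apart"
      est_trees[[g]] <- fit$tree
    }
  }
  sp_est <- njst(est_trees)
  sp_est_collapsed <- if (!is.null(config$collapse))
    njst(est_trees, collapse = config$collapse) else NULL
  sp_from_true <- njst(true_trees)
  wrong <- if (focal4) rec$est_cat != rec$true_cat & rec$est_cat != "star"
           else rec$est_cat == "AB_grouped" & rec$true_cat != "AB_grouped"
  short_internal <- if (focal4)
    mean(rec$internal[wrong] < 1e-5, na.rm = TRUE) else NA_real_
  structure(list(
    config = config, K = K, n_genes = ngene, records = rec,
    true_proportions = prop.table(table(rec$true_cat)),
    est_proportions = prop.table(table(rec$est_cat)),
    species_tree_estimate = sp_est,
    species_tree_estimate_collapsed = sp_est_collapsed,
    species_tree_from_true = sp_from_true,
    wrong_fraction = mean(wrong),
    wrong_short_internal_fraction = short_internal,
    est_trees = est_trees, true_trees = true_trees),
    class = "species_scenario_result")
}

#' @export
print.species_scenario_result <- function(x, ...) {
  nm <- if (inherits(x$config$name, "species_tree")) "custom species tree"
        else x$config$name
  cat("species-tree scenario:", nm, " K =", x$K, ", genes =", x$n_genes, "\n")
  cat("true gene-tree proportions:\n"); print(round(x$true_proportions, 3))
  cat("estimated ML gene-tree proportions:\n")
  print(round(x$est_proportions, 3))
  cat("NJst species tree:", write_newick(x$species_tree_estimate, 4), "\n")
  if (!is.null(x$species_tree_estimate_collapsed))
    cat("NJst after collapsing:",
        write_newick(x$species_tree_estimate_collapsed, 4), "\n")
  if (!is.na(x$wrong_short_internal_fraction))
    cat("wrong ML gene trees with internal branch < 1e-5:",
        round(100 * x$wrong_short_internal_fraction, 1), "%\n")
  invisible(x)
}
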