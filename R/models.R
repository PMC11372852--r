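## Nucleotide substitution models.  Bases are ordered (A, C, G, T);
## exchangeability rates follow the usual (AC, AG, AT, CG, CT, GT) order.
## All rate matrices are normalized to one expected substitution per site
## per unit branch length at stationarity.

BASES <- c("a", "c", "g", "t")

#' Jukes-Cantor model
#'
#' @return An `"sba_model"` with equal base frequencies and exchange rates
#'   and no rate heterogeneity.
#' @export
jc_model <- function() {
  gtr_gamma_model(bf = rep(0.25, 4), rates = rep(1, 6),
                  alpha = NULL, label = "JC")
}

#' GTR(+Gamma) model
#'
#' General time-reversible model with optional discrete-gamma rate
#' variation across sites.
#'
#' @param bf Base frequencies (A, C, G, T), positive, summing to 1.
#' @param rates Six exchangeability rates (AC, AG, AT, CG, CT, GT),
#'   positive.
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for a
#'   single rate class.
#' @param ncat Number of discrete gamma categories (default 4, the usual
#'   GTRGAMMA setting).
#' @param label Model name used for printing.
#' @return An `"sba_model"` holding the normalized rate matrix and its
#'   eigendecomposition.
#' @export
gtr_gamma_model <- function(bf, rates, alpha = NULL, ncat = 4,
                            label = "GTR+G") {
  stopifnot(length(bf) == 4, length(rates) == 6)
  if (!all(is.finite(bf)) || !all(is.finite(rates)))
    stop("non-finite model parameters")
  if (any(bf <= 0) || abs(sum(bf) - 1) > 1e-8)
    stop("base frequencies must be positive and sum to 1")
  if (any(rates <= 0)) stop("exchangeability rates must be positive")
  if (!is.null(alpha) && (!is.finite(alpha) || alpha <= 0))
    stop("gamma shape must be positive")
  bf <- bf / sum(bf)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  Q[lower.tri(Q)] <- rates  # column-major lower triangle = (AC,AG,AT,CG,CT,GT)
  Q <- Q + t(Q)
  Q <- Q * rep(bf, each = 4)          # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))            # mean rate at stationarity
  Q <- Q / mu
  eig <- eigen(Q)
  structure(list(label = label, bf = bf, rates = rates, alpha = alpha,
                 ncat = as.integer(ncat), Q = Q,
                 U = eig$vectors, Uinv = solve(eig$vectors),
                 lambda = eig$values),
            class = "sba_model")
}

#' @export
print.sba_model <- function(x, ...) {
  cat(x$label, "substitution model\n")
  cat("  base frequencies:", format(round(x$bf, 4)), "\n")
  cat("  exchange rates  :", format(round(x$rates, 4)), "\n")
  if (!is.null(x$alpha))
    cat("  gamma shape     :", format(round(x$alpha, 4)),
        sprintf("(%d categories)\n", x$ncat))
  invisible(x)
}

#' Probability that two ends of a branch carry the same nucleotide (JC)
#'
#' Under Jukes-Cantor the chance that the states at the two ends of a
#' branch of length `t` match is `1/4 + 3/4 exp(-4t/3)`; the complement is
#' split equally among the three other bases.
#'
#' @param t Branch length(s) in expected substitutions per site, `>= 0`.
#' @return Match probability in `(1/4, 1]`.
#' @export
jc_match_prob <- function(t) {
  if (any(t < 0)) stop("branch length must be non-negative")
  0.25 + 0.75 * exp(-4 * t / 3)
}

#' Transition probability matrix
#'
#' @param model An `"sba_model"`.
#' @param t Branch length `>= 0`.
#' @param rate Site-rate multiplier `> 0` (gamma category rate).
#' @return 4x4 stochastic matrix `P(t)` with rows/columns in (A, C, G, T)
#'   order; satisfies Chapman-Kolmogorov `P(s) P(t) = P(s + t)`.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "sba_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (!is.finite(rate) || rate <= 0) stop("rate multiplier must be positive")
  P <- Re(model$U %*% (exp(model$lambda * t * rate) * model$Uinv))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Discrete-gamma category rates
#'
#' Mean rates of `ncat` equal-probability discrete gamma categories,
#' normalized to mean 1 (via [phangorn::discrete.gamma()]).
#'
#' @param alpha Gamma shape `> 0`.
#' @param ncat Number of categories.
#' @return Numeric vector of length `ncat` with mean 1.
#' @export
gamma_rates <- function(alpha, ncat = 4) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(1)
  phangorn::discrete.gamma(alpha, ncat)
}

#' Sample a random GTR+Gamma model
#'
#' Draws the per-replicate substitution model used by the simulation
#' scenarios: base frequencies from Dirichlet(1,1,1,1), exchangeability
#' rates i.i.d. log-normal(0, 1) rescaled so the G-T rate equals 1, and a
#' gamma shape from Normal(mean 0.5, sd 0.1) truncated to positive values.
#'
#' Uses the current R random number generator stream; call `set.seed()`
#' beforehand for reproducibility.
#'
#' @param ncat Number of discrete gamma categories.
#' @return An `"sba_model"`.
#' @export
sample_gtr_params <- function(ncat = 4) {
  bf <- stats::rgamma(4, 1)
  bf <- bf / sum(bf)
  rates <- stats::rlnorm(6, 0, 1)
  rates <- rates / rates[6]
  alpha <- -1
  while (alpha <= 0) alpha <- stats::rnorm(1, 0.5, 0.1)
  gtr_gamma_model(bf = bf, rates = rates, alpha = alpha, ncat = ncat,
                  label = "GTR+G (sampled)")
}
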