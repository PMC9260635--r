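#' rootphylo: outgroup-free rooting with nonreversible substitution models
#'
#' Maximum-likelihood root placement on a fixed topology under
#' unrestricted (nonreversible) Markov substitution models, with rootstrap
#' support, root-error metrics, AU confidence sets of root branches,
#' site-/gene-wise log-likelihood diagnostics, symmetry-based locus
#' filtering, and a synthetic-data generator.
#'
#' @useDynLib rootphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

## off-diagonal index order for the rate vector: row-major over (i, j), i != j.
## For DNA (a,c,g,t) this is ac, ag, at, ca, cg, ct, ga, gc, gt, ta, tc, tg —
## the 12 free parameters of the UNREST model.
offdiag_index <- function(K) {
  idx <- which(matrix(TRUE, K, K) & !diag(K), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

rate_names <- function(alphabet) {
  idx <- offdiag_index(length(alphabet))
  paste0(alphabet[idx[, 1]], alphabet[idx[, 2]])
}

#' Build a nonreversible (UNREST-style) substitution model
#'
#' Assembles the K x K rate matrix Q from its K(K-1) free off-diagonal
#' rates (12 for DNA), computes the stationary distribution pi as the null
#' left vector of Q, and normalizes Q so that the expected number of
#' substitutions per unit branch length at stationarity is one
#' (-sum_i pi_i Q_ii = 1), keeping branch lengths interpretable as
#' substitutions per site. Root-state frequencies default to pi
#' (stationarity at the root); supplying `root_freqs` decouples them.
#'
#' @param rates nonnegative numeric vector of length K(K-1), row-major over
#'   the off-diagonal entries (DNA order: ac, ag, at, ca, cg, ct, ga, gc,
#'   gt, ta, tc, tg).
#' @param root_freqs optional probability vector of length K; default the
#'   stationary distribution.
#' @param alphabet state alphabet; its length sets K.
#' @return object of class `nonrev_model`: `Q` (normalized), `pi`
#'   (stationary), `root_freqs`, `rates` (normalized scale), `alphabet`.
#' @export
build_model <- function(rates, root_freqs = NULL, alphabet = DNA_ALPHABET) {
  K <- length(alphabet)
  if (length(rates) != K * (K - 1))
    stop("need ", K * (K - 1), " off-diagonal rates for a ", K, "-state model")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (all(rates == 0)) stop("degenerate model: all rates are zero")
  Q <- matrix(0, K, K, dimnames = list(alphabet, alphabet))
  Q[offdiag_index(K)] <- rates
  diag(Q) <- -rowSums(Q)
  pi <- stationary_distribution(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate model: zero expected substitution rate at stationarity")
  Q <- Q / mu
  if (is.null(root_freqs)) {
    root_freqs <- pi
  } else {
    if (length(root_freqs) != K || any(root_freqs < 0))
      stop("root_freqs must be ", K, " nonnegative values")
    root_freqs <- root_freqs / sum(root_freqs)
  }
  structure(list(Q = Q, pi = pi, root_freqs = root_freqs,
                 rates = Q[offdiag_index(K)], alphabet = alphabet),
            class = "nonrev_model")
}

#' @export
print.nonrev_model <- function(x, ...) {
  K <- length(x$alphabet)
  cat("<nonreversible model> ", K, " states, ", K * (K - 1),
      " free rates\n", sep = "")
  cat("Q (normalized to 1 expected substitution/site at stationarity):\n")
  print(round(x$Q, 4))
  cat("stationary pi:  ", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  cat("root freqs:     ", paste(sprintf("%.4f", x$root_freqs), collapse = " "), "\n")
  invisible(x)
}

## stationary distribution: solve pi Q = 0, sum(pi) = 1 (least squares on the
## augmented system; unique for an irreducible state graph)
stationary_distribution <- function(Q) {
  K <- nrow(Q)
  A <- rbind(t(Q), rep(1, K))
  pi <- tryCatch(qr.solve(A, c(rep(0, K), 1)),
                 error = function(e) stop("cannot solve for the stationary distribution: ",
                                          conditionMessage(e)))
  if (min(pi) < -1e-8)
    warning("stationary distribution has negative entries; the rate graph may be reducible")
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Is the model time-reversible?
#'
#' Checks detailed balance pi_i Q_ij = pi_j Q_ji at the model's stationary
#' distribution.
#' @param model a `nonrev_model`.
#' @param tol tolerance on the maximum detailed-balance residual.
#' @export
is_reversible <- function(model, tol = 1e-8) {
  F <- model$pi * model$Q            # row-scales Q by pi
  max(abs(F - t(F))) <= tol
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of Q, falling back to scaling-and-squaring
#' (Pade) when the eigenbasis is ill-conditioned — nonreversible rate
#' matrices can have complex or near-defective spectra. Tiny negative
#' entries from roundoff are clipped to 0.
#'
#' @param model a `nonrev_model`.
#' @param t branch length (substitutions/site), `t >= 0`.
#' @return K x K stochastic matrix (rows sum to 1).
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be nonnegative")
  Q <- model$Q
  K <- nrow(Q)
  if (t == 0) return(diag(K))
  P <- NULL
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    V <- eg$vectors
    cond <- tryCatch(1 / rcond(abs(V)), error = function(e) Inf)
    if (is.finite(cond) && cond < 1e12) {
      P <- Re(V %*% diag(exp(eg$values * t), K) %*% solve(V))
    }
  }
  if (is.null(P)) P <- expmat_cpp(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Sample a nonreversible rate matrix
#'
#' Off-diagonal rates are drawn log-uniformly over `range` (two orders of
#' magnitude by default), giving models with a pronounced nonreversible
#' signal; a `reversibility` weight interpolates the rates linearly between
#' an independently sampled detailed-balance (GTR-style) matrix and the
#' nonreversible draw.
#'
#' @param nonrev_strength in `[0, 1]`: 0 gives an exactly reversible model,
#'   1 a free nonreversible draw.
#' @param range rate range for the log-uniform sampler.
#' @param alphabet state alphabet.
#' @return a `nonrev_model`.
#' @export
sample_model <- function(nonrev_strength = 1, range = c(0.1, 10),
                         alphabet = DNA_ALPHABET) {
  K <- length(alphabet)
  idx <- offdiag_index(K)
  logu <- function(n) exp(stats::runif(n, log(range[1]), log(range[2])))
  free <- logu(K * (K - 1))
  ## detailed-balance component: Q0_ij = s_ij * pi_j with symmetric s
  s <- matrix(0, K, K)
  s[upper.tri(s)] <- logu(K * (K - 1) / 2)
  s <- s + t(s)
  pi0 <- stats::rgamma(K, 5, 5); pi0 <- pi0 / sum(pi0)
  rev_rates <- (s %*% diag(pi0))[idx]
  rates <- (1 - nonrev_strength) * rev_rates + nonrev_strength * free
  build_model(rates, alphabet = alphabet)
}
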