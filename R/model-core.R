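# Core SRH pairwise model: rate matrix, transition matrix, joint probability
# matrix, log-likelihood, and closed-form estimation from a divergence matrix.
#
# Internal workhorses operate on bare numeric vectors/matrices so that the
# bootstrap and optimisation loops avoid S4 dispatch; exported functions wrap
# them with validation.

# Unordered-pair index for a q-state alphabet, rows (i, j) with i < j,
# in lexicographic order. For q = 4 this reproduces PAIR_INDEX.
.pair_index <- function(q) {
  idx <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# Full symmetric S matrix (including the derived diagonal) from (pi, s).
.s_matrix <- function(pi, s) {
  q <- length(pi)
  idx <- if (q == 4L) PAIR_INDEX else .pair_index(q)
  S <- matrix(0, q, q)
  S[idx] <- s
  S[idx[, c(2L, 1L), drop = FALSE]] <- s
  diag(S) <- -as.vector(S %*% pi) / pi
  S
}

# Symmetric eigendecomposition of Pi^{1/2} S Pi^{1/2} with a reproducible
# sign convention: eigenvalues descending (eigen()'s order), each
# eigenvector's largest-magnitude component made positive (first on ties).
.spectral <- function(pi, s) {
  sq <- sqrt(pi)
  B <- .s_matrix(pi, s) * tcrossprod(sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  L <- e$vectors
  for (k in seq_len(ncol(L))) {
    m <- which.max(abs(L[, k]))
    if (L[m, k] < 0) L[, k] <- -L[, k]
  }
  list(values = e$values, vectors = L, sq = sq)
}

# P(t) = Pi^{-1/2} L e^{Lambda t} L^T Pi^{1/2}
.transition <- function(pi, s, t) {
  sp <- .spectral(pi, s)
  P <- (sp$vectors %*% (exp(sp$values * t) * t(sp$vectors)))
  P <- P * tcrossprod(1 / sp$sq, sp$sq)
  P
}

# F(t) = Pi^{1/2} L e^{2 Lambda t} L^T Pi^{1/2}
.joint <- function(pi, s, t = 1) {
  sp <- .spectral(pi, s)
  Fm <- (sp$vectors %*% (exp(2 * sp$values * t) * t(sp$vectors)))
  Fm * tcrossprod(sp$sq, sp$sq)
}

# Multinomial log-likelihood of a divergence matrix under (pi, s) at t = 1.
# Returns -Inf when a positive count sits on a non-positive joint probability.
.loglik <- function(N, pi, s) {
  Fm <- .joint(pi, s, 1)
  pos <- N > 0
  if (any(Fm[pos] <= 0)) return(-Inf)
  sum(N[pos] * log(Fm[pos]))
}

# Closed-form estimation from a (possibly q x q, possibly non-integer)
# divergence matrix. Returns pi, s, the symmetrized relative-frequency
# matrix Fhat, and the log-likelihood at the estimate.
.estimate <- function(N, clamp = FALSE, eps = 1e-10) {
  n <- sum(N)
  if (n <= 0) stop("divergence matrix has no observations")
  q <- nrow(N)
  Fh <- (N + t(N)) / (2 * n)
  pih <- rowSums(Fh)
  if (any(pih <= 0)) {
    bad <- paste(rownames(N)[pih <= 0], collapse = ", ")
    if (!nzchar(bad)) bad <- paste(which(pih <= 0), collapse = ", ")
    stop("state(s) ", bad, " unobserved in the divergence matrix; ",
         "the stationary distribution cannot be estimated")
  }
  sq <- sqrt(pih)
  B <- Fh / tcrossprod(sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev <= 0)) {
    if (!clamp)
      stop("non-positive eigenvalue in the symmetrized divergence matrix: ",
           "the sequences are saturated for this model (longer sequences ",
           "may help); set clamp = TRUE to clip eigenvalues at ", eps)
    ev <- pmax(ev, eps)
  }
  L <- e$vectors
  for (k in seq_len(ncol(L))) {
    m <- which.max(abs(L[, k]))
    if (L[m, k] < 0) L[, k] <- -L[, k]
  }
  lam <- 0.5 * log(ev)
  S <- (L %*% (lam * t(L))) / tcrossprod(sq)
  idx <- if (q == 4L) PAIR_INDEX else .pair_index(q)
  sh <- S[idx]
  pos <- N > 0
  ll <- if (any(Fh[pos] <= 0)) -Inf else sum(N[pos] * log(Fh[pos]))
  list(pi = pih, s = sh, Fhat = Fh, logLik = ll)
}

.check_divergence <- function(N, q = NULL) {
  if (!is.matrix(N) || nrow(N) != ncol(N))
    stop("'N' must be a square divergence matrix")
  if (!is.null(q) && nrow(N) != q)
    stop("'N' must be ", q, " x ", q)
  if (any(N < 0)) stop("divergence counts must be non-negative")
  if (sum(N) <= 0) stop("divergence matrix has no observations")
  invisible(N)
}

#' Rate matrix of an SRH substitution model
#'
#' Builds the instantaneous rate matrix \eqn{R = S\Pi} of a reversible
#' substitution model, with the diagonal set so that rows sum to zero. The
#' result satisfies stationarity (\eqn{\pi^T R = 0}) and detailed balance
#' (\eqn{\pi_i R_{ij} = \pi_j R_{ji}}).
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @return A 4x4 rate matrix with dimnames A, C, G, T (substitutions per unit
#'   time).
#' @examples
#' m <- substitutionModel(rep(0.25, 4), rep(1, 6))
#' rateMatrix(m)  # Jukes-Cantor: off-diagonals 0.25, diagonal -0.75
#' @export
rateMatrix <- function(model) {
  stopifnot(is(model, "SubstitutionModel"))
  R <- .s_matrix(model@pi, model@s) %*% diag(model@pi)
  dimnames(R) <- list(NUCLEOTIDES, NUCLEOTIDES)
  R
}

#' Transition probability matrix P(t)
#'
#' Evaluates \eqn{P(t) = \Pi^{-1/2} L e^{\Lambda t} L^T \Pi^{1/2}}, the
#' spectral form of the matrix exponential \eqn{e^{Rt}}.
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param t elapsed time, \eqn{t \ge 0}. Defaults to 1, the convention under
#'   which divergence matrices are modelled.
#' @return A 4x4 stochastic matrix.
#' @export
transitionMatrix <- function(model, t = 1) {
  stopifnot(is(model, "SubstitutionModel"))
  if (t < 0) stop("'t' must be non-negative")
  P <- .transition(model@pi, model@s, t)
  dimnames(P) <- list(NUCLEOTIDES, NUCLEOTIDES)
  P
}

#' Joint probability matrix F(t) of a homologous sequence pair
#'
#' \eqn{F(t) = \Pi^{1/2} L e^{2\Lambda t} L^T \Pi^{1/2} = P(t)^T \Pi P(t)}:
#' the probability that a site is in state i in one sequence and j in the
#' other, for two sequences that diverged from a common ancestor t time units
#' ago along each lineage. Symmetric under the SRH assumptions; its row sums
#' equal \eqn{\pi}.
#'
#' @inheritParams transitionMatrix
#' @return A symmetric 4x4 probability matrix summing to 1.
#' @export
jointProbabilityMatrix <- function(model, t = 1) {
  stopifnot(is(model, "SubstitutionModel"))
  if (t < 0) stop("'t' must be non-negative")
  Fm <- .joint(model@pi, model@s, t)
  dimnames(Fm) <- list(NUCLEOTIDES, NUCLEOTIDES)
  Fm
}

#' Log-likelihood of a divergence matrix under an SRH model
#'
#' \eqn{L(\pi, s) = \sum_{ij} n_{ij} \log f_{ij}(\pi, s)}, the multinomial
#' log-likelihood of the observed site-pattern counts under the joint
#' probability matrix at t = 1.
#'
#' @param N a 4x4 divergence (site-pattern count) matrix.
#' @param model a \linkS4class{SubstitutionModel}.
#' @return The log-likelihood (finite unless a positive count falls on a zero
#'   model probability, which raises an error).
#' @export
divergenceLogLik <- function(N, model) {
  stopifnot(is(model, "SubstitutionModel"))
  .check_divergence(N, 4L)
  ll <- .loglik(N, model@pi, model@s)
  if (!is.finite(ll))
    stop("degenerate likelihood: a positive count falls on a zero joint ",
         "probability")
  ll
}

#' Closed-form estimation of the SRH model from a divergence matrix
#'
#' Maximum-likelihood estimation of the nine free parameters (three in
#' \eqn{\pi}, six in \eqn{s}) from the symmetrized relative divergence matrix
#' \eqn{\hat F = (N + N^T) / 2n}: \eqn{\hat\pi} is the vector of row sums of
#' \eqn{\hat F}, and \eqn{\hat S} is recovered spectrally from
#' \eqn{\hat\Pi^{-1/2} \hat F \hat\Pi^{-1/2} = \hat L e^{2\hat\Lambda}
#' \hat L^T}.
#'
#' @param N a 4x4 divergence matrix (counts; non-integer totals are accepted,
#'   e.g. expected counts).
#' @param clamp if TRUE, eigenvalues of the symmetrized matrix that are not
#'   strictly positive are clipped at \code{eps} instead of raising a
#'   saturation error. Off by default.
#' @param eps clipping floor used when \code{clamp = TRUE}.
#' @return A list with components \code{pi}, \code{s}, \code{logLik},
#'   \code{Fhat}, and \code{model}: the fitted \linkS4class{SubstitutionModel}
#'   when the estimates form a valid model, otherwise NULL (fitted
#'   exchangeabilities can dip below zero in noisy data, and lumped q-state
#'   fits are not 4-state models; \code{pi} and \code{s} are always returned
#'   as estimated).
#' @examples
#' m <- substitutionModel(c(0.1, 0.2, 0.3, 0.4),
#'                        c(0.2, 0.25, 0.2, 0.2, 0.15, 0.2))
#' N <- round(1e6 * jointProbabilityMatrix(m))
#' estimateSRH(N)$model
#' @export
estimateSRH <- function(N, clamp = FALSE, eps = 1e-10) {
  .check_divergence(N)
  est <- .estimate(N, clamp = clamp, eps = eps)
  q <- nrow(N)
  states <- rownames(N) %||% if (q == 4L) NUCLEOTIDES else as.character(seq_len(q))
  pih <- setNames(est$pi, states)
  sh <- est$s
  if (q == 4L) names(sh) <- PAIR_NAMES
  model <- if (q == 4L)
    tryCatch(substitutionModel(pih, sh), error = function(e) NULL)
  list(pi = pih, s = sh, logLik = est$logLik, Fhat = est$Fhat, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
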