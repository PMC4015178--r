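# The three lumpability tests (index/bootstrap, Markov-chain chi-squared,
# likelihood-ratio with constrained MLE) plus the Bowker matched-pairs test
# of symmetry used for SRH screening.

# Orthogonal 6x6 basis whose first two rows span the row space of C;
# remaining rows complete the basis from coordinate vectors in order.
.constraint_basis <- function(C) {
  rows <- list()
  for (r in seq_len(nrow(C))) {
    v <- C[r, ]
    for (b in rows) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("lumpability constraints are rank-deficient")
    rows[[length(rows) + 1L]] <- v / nv
  }
  for (k in 1:6) {
    v <- numeric(6)
    v[k] <- 1
    for (b in rows) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) rows[[length(rows) + 1L]] <- v / nv
    if (length(rows) == 6L) break
  }
  do.call(rbind, rows)
}

.softmax4 <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

# Alternating constrained maximisation of the log-likelihood over H0:
# s-step in the rotated coordinates y = A s with the two constraint
# coordinates pinned at zero (non-negativity of s kept by a smooth penalty),
# then a pi-step on the softmax-parameterized simplex. For 2:2 schemes the
# constraint matrix, and hence A, is rebuilt after every pi update.
.constrained_mle <- function(N, scheme, tol = 1e-8, max_iter = 500L) {
  blocks <- .blocks_idx(scheme)
  est <- .estimate(N)
  pi <- est$pi
  C <- .constraints(blocks, pi)
  s <- .project_lumpable(est$s, C)
  pi_dep <- any(vapply(blocks, length, 1L) == 2L) && scheme@q == 2L  # {2:2}

  negll_y <- function(yfree, At, pi) {
    s <- as.vector(At %*% c(0, 0, yfree))
    pen <- sum(pmin(s, 0)^2)
    ll <- .loglik(N, pi, s)
    if (!is.finite(ll)) return(1e10 + 1e8 * pen)
    -ll + 1e7 * pen
  }
  negll_z <- function(z, s) {
    p <- .softmax4(z)
    ll <- .loglik(N, p, s)
    if (!is.finite(ll)) 1e10 else -ll
  }

  ll_old <- .loglik(N, pi, s)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    A <- .constraint_basis(C)
    At <- t(A)
    y <- as.vector(A %*% s)
    opt <- optim(y[3:6], negll_y, At = At, pi = pi, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500))
    s <- as.vector(At %*% c(0, 0, opt$par))
    z <- log(pi[1:3] / pi[4])
    opt2 <- optim(z, negll_z, s = s, method = "BFGS",
                  control = list(reltol = 1e-12, maxit = 500))
    pi <- .softmax4(opt2$par)
    if (pi_dep) C <- .constraints(blocks, pi)
    ll_new <- -opt2$value
    if (it > 1L && abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # enforce the constraints exactly at the final pi (no-op unless 2:2, where
  # the last pi update perturbed C(pi) s away from zero)
  A <- .constraint_basis(C)
  y <- as.vector(A %*% s)
  y[1:2] <- 0
  s <- pmax(as.vector(t(A) %*% y), 0)
  s <- .project_lumpable(s, C)
  list(pi = pi, s = s, logLik = .loglik(N, pi, s),
       converged = converged, iterations = iters)
}

#' Constrained maximum likelihood under the lumpability null
#'
#' Maximizes the divergence-matrix log-likelihood over the null hypothesis
#' \eqn{H_0: C(\pi) s = 0} of lumpability for a scheme, by the alternating
#' scheme: the free coordinates of \eqn{y = A s} (an orthogonal rotation
#' whose two pinned coordinates encode the constraints) are optimized given
#' \eqn{\pi}, then \eqn{\pi} is optimized given \eqn{s}, repeating until the
#' log-likelihood improvement falls below \code{tol}. For 2:2 schemes A
#' depends on \eqn{\pi} and is rebuilt after every \eqn{\pi} update. The
#' starting point is the Euclidean projection of the unconstrained fit, so
#' the constrained optimum is never worse than the projection.
#'
#' @param N a 4x4 divergence matrix.
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @param tol convergence tolerance on the log-likelihood improvement per
#'   cycle.
#' @param max.iter maximum number of alternation cycles.
#' @return list with \code{pi}, \code{s} (satisfying the constraints to
#'   1e-10), \code{logLik}, \code{converged}, \code{iterations}.
#' @export
constrainedMLE <- function(N, scheme, tol = 1e-8, max.iter = 500L) {
  .check_divergence(N, 4L)
  scheme <- recodingScheme(scheme)
  out <- .constrained_mle(N, scheme, tol = tol, max_iter = max.iter)
  names(out$pi) <- NUCLEOTIDES
  names(out$s) <- PAIR_NAMES
  if (!out$converged)
    warning("constrained optimisation did not converge in ", max.iter,
            " cycles")
  out
}

#' Likelihood-ratio test for lumpability
#'
#' Compares the unconstrained SRH fit (nine free parameters, closed form)
#' with the constrained fit under the lumpability null (seven free
#' parameters). Twice the log likelihood-ratio is referred to a chi-squared
#' distribution with 2 degrees of freedom -- the two equality constraints
#' imposed by every recoding scheme.
#'
#' @inheritParams constrainedMLE
#' @return A \linkS4class{LumpabilityTest} with \code{statistic = 2 LR},
#'   \code{df = 2}, the upper-tail p-value, and both fits in
#'   \code{estimates}.
#' @export
likelihoodRatioTest <- function(N, scheme, tol = 1e-8, max.iter = 500L) {
  .check_divergence(N, 4L)
  scheme <- recodingScheme(scheme)
  fit <- .estimate(N)
  Mhat <- .defect(fit$pi, fit$s, .membership(scheme), t = 1)
  cm <- .constrained_mle(N, scheme, tol = tol, max_iter = max.iter)
  stat <- 2 * (fit$logLik - cm$logLik)
  if (stat < 0) {
    if (stat >= -1e-6) stat <- 0
    else stop("constrained optimisation exceeded the unconstrained maximum ",
              "(2LR = ", signif(stat, 4), "); optimisation failure")
  }
  df <- 2
  .new_test_result(
    method = "lrt", statistic = stat, parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE),
    estimates = list(pi.hat = setNames(fit$pi, NUCLEOTIDES),
                     s.hat = setNames(fit$s, PAIR_NAMES),
                     logLik.hat = fit$logLik,
                     pi.tilde = setNames(cm$pi, NUCLEOTIDES),
                     s.tilde = setNames(cm$s, PAIR_NAMES),
                     logLik.tilde = cm$logLik),
    scheme = scheme,
    details = list(eta.hat = sqrt(sum(Mhat * Mhat)),
                   converged = cm$converged, iterations = cm$iterations))
}

#' Parametric-bootstrap test of the lumpability index
#'
#' Computes \eqn{\hat\eta}, the Frobenius norm of the estimated defect matrix
#' \eqn{\hat M = VU\hat P(1)V - \hat P(1)V}, then approximates its null
#' distribution by a parametric bootstrap: the unconstrained fit is projected
#' onto the lumpable subspace, B divergence matrices are drawn from
#' Multinomial(n, \eqn{\tilde F(1)}), and \eqn{\eta^*_b} is recomputed from
#' each. The p-value is the proportion of \eqn{\eta^*_b \ge \hat\eta}.
#'
#' @inheritParams constrainedMLE
#' @param B number of bootstrap replicates (default 500).
#' @param seed optional integer seed for the bootstrap stream.
#' @param add.one if TRUE, report the add-one p-value
#'   \eqn{(1 + \#\{\eta^* \ge \hat\eta\})/(B + 1)}, which is always positive.
#' @param max.failure.rate abort when more than this fraction of bootstrap
#'   replicates fails estimation (each replicate is resampled up to 5 times
#'   first).
#' @return A \linkS4class{LumpabilityTest}; \code{details} carries
#'   \code{eta.hat}, the bootstrap replicates \code{eta.star}, and the
#'   failure count.
#' @export
indexTest <- function(N, scheme, B = 500L, seed = NULL, add.one = FALSE,
                      max.failure.rate = 0.1) {
  .check_divergence(N, 4L)
  scheme <- recodingScheme(scheme)
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  V <- .membership(scheme)
  fit <- .estimate(N)
  M <- .defect(fit$pi, fit$s, V, t = 1)
  eta_hat <- sqrt(sum(M * M))
  C <- .constraints(.blocks_idx(scheme), fit$pi)
  s_t <- .project_lumpable(fit$s, C)
  Ft <- .joint(fit$pi, s_t, 1)
  probs <- as.vector(pmax(Ft, 0))
  probs <- probs / sum(probs)
  n <- sum(N)
  eta_star <- rep(NA_real_, B)
  failures <- 0L
  for (b in seq_len(B)) {
    for (attempt in 1:5) {
      Nb <- matrix(rmultinom(1L, n, probs), 4L, 4L)
      eb <- tryCatch({
        fb <- .estimate(Nb)
        Mb <- .defect(fb$pi, fb$s, V, t = 1)
        sqrt(sum(Mb * Mb))
      }, error = function(e) NULL)
      if (!is.null(eb)) break
    }
    if (is.null(eb)) failures <- failures + 1L else eta_star[b] <- eb
  }
  if (failures > max.failure.rate * B)
    stop("index test aborted: ", failures, " of ", B,
         " bootstrap replicates failed estimation")
  ok <- !is.na(eta_star)
  hits <- sum(eta_star[ok] >= eta_hat)
  p <- if (add.one) (1 + hits) / (sum(ok) + 1) else hits / sum(ok)
  .new_test_result(
    method = "index", statistic = eta_hat, parameter = c(B = B),
    p.value = p,
    estimates = list(pi.hat = setNames(fit$pi, NUCLEOTIDES),
                     s.hat = setNames(fit$s, PAIR_NAMES),
                     pi.tilde = setNames(fit$pi, NUCLEOTIDES),
                     s.tilde = setNames(s_t, PAIR_NAMES)),
    scheme = scheme,
    details = list(eta.hat = eta_hat, eta.star = eta_star[ok],
                   failures = failures))
}

#' Markov-chain chi-squared test for lumpability
#'
#' Treats sequence A (the rows of N) as the ancestral sequence, so that N has
#' the properties of a transition count matrix, and compares the observed
#' block-aggregated transition counts \eqn{o_{il} = \sum_{j \in S_l} n_{ij}}
#' with their expectations under lumpability, \eqn{e_{il} = n_{i\cdot}
#' n'_{kl} / n'_{k\cdot}} (k the block of i). The statistic \eqn{T = \sum
#' (o - e)^2 / e} is referred to chi-squared with \eqn{(q - 1)\sum_k
#' (\gamma_k - 1)} degrees of freedom, which equals 2 for every recoding
#' scheme.
#'
#' @inheritParams constrainedMLE
#' @param swap if TRUE, use the transpose of N (sequence B ancestral) for
#'   sensitivity analysis.
#' @param min.count if positive, error when any observed aggregated cell
#'   falls below this count.
#' @return A \linkS4class{LumpabilityTest}.
#' @export
markovChainTest <- function(N, scheme, swap = FALSE, min.count = 0L) {
  .check_divergence(N, 4L)
  scheme <- recodingScheme(scheme)
  if (swap) N <- t(N)
  V <- .membership(scheme)
  o <- N %*% V
  Nq <- t(V) %*% N %*% V
  block_of <- as.vector(V %*% seq_len(scheme@q))
  e <- (rowSums(N)) * (Nq / rowSums(Nq))[block_of, , drop = FALSE]
  if (any(e <= 0)) {
    bad <- which(e <= 0, arr.ind = TRUE)[1L, ]
    stop("untestable cell: expected count is zero for state ",
         NUCLEOTIDES[bad[1L]], " into block ", colnames(V)[bad[2L]])
  }
  if (min.count > 0 && any(o < min.count))
    stop("observed aggregated counts below min.count = ", min.count)
  stat <- sum((o - e)^2 / e)
  df <- (scheme@q - 1) * sum(scheme@gamma - 1)
  .new_test_result(
    method = "markov_chain", statistic = stat, parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE),
    scheme = scheme)
}

#' Matched-pairs test of symmetry (Bowker)
#'
#' Screens a divergence matrix for consistency with SRH evolution: under
#' stationarity and reversibility E(N) is symmetric, so \eqn{\sum_{i<j}
#' (n_{ij} - n_{ji})^2 / (n_{ij} + n_{ji})} (pairs with \eqn{n_{ij} + n_{ji}
#' > 0}) is chi-squared with one degree of freedom per included pair.
#' Rejection indicates violation of the SRH assumptions, in which case the
#' lumpability tests are not applicable.
#'
#' @param N a 4x4 divergence matrix.
#' @return A \linkS4class{LumpabilityTest} with method "bowker".
#' @export
bowkerTest <- function(N) {
  .check_divergence(N, 4L)
  tot <- N + t(N)
  up <- upper.tri(N)
  keep <- up & tot > 0
  if (!any(keep))
    stop("untestable: all off-diagonal pairs of the divergence matrix are zero")
  stat <- sum(((N - t(N))[keep])^2 / tot[keep])
  df <- sum(keep)
  .new_test_result(
    method = "bowker", statistic = stat, parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Run a lumpability test by name
#'
#' Dispatcher over the three lumpability tests.
#'
#' @inheritParams constrainedMLE
#' @param method "lrt", "index" or "mc" (alias "markov_chain").
#' @param B bootstrap replicates, used by the index test only.
#' @param ... passed to the selected test (e.g. \code{seed} for the index
#'   test).
#' @return A \linkS4class{LumpabilityTest}.
#' @export
lumpabilityTest <- function(N, scheme, method = c("lrt", "index", "mc"),
                            B = 500L, ...) {
  method <- match.arg(method[1L], c("lrt", "index", "mc", "markov_chain"))
  switch(method,
         lrt = likelihoodRatioTest(N, scheme, ...),
         index = indexTest(N, scheme, B = B, ...),
         markovChainTest(N, scheme, ...))
}
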