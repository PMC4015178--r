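# Recoding schemes, lumping operators, the lumpability defect and index,
# rate-level lumpability constraints, projection onto the lumpable subspace,
# and the lumped / conditional q-state processes.

# The 13 partitions of {A,C,G,T} into 2 or 3 blocks, keyed by IUPAC label.
.SCHEME_BLOCKS <- list(
  R  = list(c("A", "G"), "C", "T"),
  Y  = list("A", "G", c("C", "T")),
  S  = list("A", c("C", "G"), "T"),
  W  = list("C", "G", c("A", "T")),
  M  = list(c("A", "C"), "G", "T"),
  K  = list("A", "C", c("G", "T")),
  B  = list("A", c("C", "G", "T")),
  D  = list("C", c("A", "G", "T")),
  H  = list("G", c("A", "C", "T")),
  V  = list("T", c("A", "C", "G")),
  RY = list(c("A", "G"), c("C", "T")),
  SW = list(c("A", "T"), c("C", "G")),
  KM = list(c("A", "C"), c("G", "T"))
)

.make_scheme <- function(name, blocks) {
  gamma <- vapply(blocks, length, 1L)
  new("RecodingScheme", name = name, blocks = blocks,
      q = length(blocks), category = paste(sort(gamma, decreasing = TRUE),
                                           collapse = ":"),
      gamma = gamma)
}

#' The catalogue of the 13 recoding schemes
#'
#' All partitions of \{A, C, G, T\} into 2 or 3 blocks, under IUPAC naming:
#' one-pair merges R=\{A,G\}, Y=\{C,T\}, S=\{C,G\}, W=\{A,T\}, M=\{A,C\},
#' K=\{G,T\} (category 2:1:1); triplet merges B, D, H, V (3:1); and the
#' two-pair merges RY, SW, KM (2:2).
#'
#' @return A named list of 13 \linkS4class{RecodingScheme} objects.
#' @examples
#' length(listSchemes())  # 13
#' listSchemes()$RY
#' @export
listSchemes <- function() {
  lapply(setNames(names(.SCHEME_BLOCKS), names(.SCHEME_BLOCKS)),
         function(nm) .make_scheme(nm, .SCHEME_BLOCKS[[nm]]))
}

#' Look up or construct a recoding scheme
#'
#' @param x an IUPAC-style scheme name (case-insensitive, e.g. "RY"), an
#'   explicit partition string such as "AG|CT" or "AG|C|T", or a
#'   \linkS4class{RecodingScheme} (returned unchanged).
#' @return A \linkS4class{RecodingScheme}.
#' @export
recodingScheme <- function(x) {
  if (is(x, "RecodingScheme")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  cat <- listSchemes()
  hit <- match(toupper(x), toupper(names(cat)))
  if (!is.na(hit)) return(cat[[hit]])
  if (grepl("|", x, fixed = TRUE)) {
    blocks <- lapply(strsplit(toupper(x), "|", fixed = TRUE)[[1L]],
                     function(b) strsplit(b, "")[[1L]])
    key <- paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ""),
                             "")), collapse = "/")
    for (s in cat) {
      skey <- paste(sort(vapply(s@blocks,
                                function(b) paste(sort(b), collapse = ""), "")),
                    collapse = "/")
      if (identical(key, skey)) return(s)
    }
    stop("'", x, "' is not a partition of {A,C,G,T} into 2 or 3 blocks")
  }
  stop("unknown recoding scheme '", x, "'; see listSchemes()")
}

# 0/1 membership matrix V (4 x q); column l marks the states of block l.
.membership <- function(scheme) {
  V <- matrix(0, 4L, scheme@q,
              dimnames = list(NUCLEOTIDES,
                              vapply(scheme@blocks, paste, "", collapse = "")))
  for (l in seq_len(scheme@q))
    V[match(scheme@blocks[[l]], NUCLEOTIDES), l] <- 1
  V
}

#' Lumping operators V and U for a recoding scheme
#'
#' V is the 4 x q 0/1 membership matrix of the partition; U =
#' \eqn{(V^T \Pi V)^{-1} V^T \Pi} is the q x 4 matrix whose k-th row is
#' \eqn{\pi} restricted to block k and renormalized. They satisfy
#' \eqn{U V = I_q}.
#'
#' @param scheme a \linkS4class{RecodingScheme} or name accepted by
#'   \code{\link{recodingScheme}}.
#' @param pi stationary base frequencies (numeric(4)) or a
#'   \linkS4class{SubstitutionModel}.
#' @return list with components \code{V} (4 x q) and \code{U} (q x 4).
#' @export
lumpingOperators <- function(scheme, pi) {
  scheme <- recodingScheme(scheme)
  if (is(pi, "SubstitutionModel")) pi <- pi@pi
  V <- .membership(scheme)
  U <- solve(t(V) %*% (pi * V)) %*% t(V * pi)
  dimnames(U) <- rev(dimnames(V))
  list(V = V, U = U)
}

# eta and defect matrix from bare (pi, s); P1 optionally precomputed.
.defect <- function(pi, s, V, t = 1, P = NULL) {
  if (is.null(P)) P <- .transition(pi, s, t)
  piq <- as.vector(crossprod(V, pi))
  U <- t(V * pi) / piq          # q x 4, rows renormalized pi
  PV <- P %*% V
  M <- V %*% (U %*% PV) - PV
  M
}

#' Lumpability defect matrix M and index eta
#'
#' A process is (strongly) lumpable for a partition exactly when
#' \eqn{V U P(t) V = P(t) V}. The defect \eqn{M = VUP(t)V - P(t)V} collects
#' the departures from that condition and \eqn{\eta = (\sum_{ij}
#' m_{ij}^2)^{1/2}} is its Frobenius norm; \eqn{\eta = 0} if and only if the
#' process is lumpable (at every t; lumpability does not depend on t).
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @param t evaluation time (default 1).
#' @return list with the 4 x q defect matrix \code{M} and scalar \code{eta}.
#' @examples
#' m <- substitutionModel(c(0.2, 0.3, 0.2, 0.3),
#'                        c(0.2, 0.1, 0.3, 0.3, 1.0, 0.2))
#' lumpabilityDefect(m, "RY")$eta   # ~0: lumpable
#' lumpabilityDefect(m, "KM")$eta   # > 0: not lumpable
#' @export
lumpabilityDefect <- function(model, scheme, t = 1) {
  stopifnot(is(model, "SubstitutionModel"))
  scheme <- recodingScheme(scheme)
  M <- .defect(model@pi, model@s, .membership(scheme), t)
  list(M = M, eta = sqrt(sum(M * M)))
}

#' Is a model lumpable for a scheme?
#'
#' @inheritParams lumpabilityDefect
#' @param tol eta threshold below which the model counts as lumpable.
#' @param multi.t if TRUE, eta is additionally checked at t = 0.5 and t = 2
#'   to guard against accidental cancellation at a single time point.
#' @return logical.
#' @export
isLumpable <- function(model, scheme, tol = TOL_LUMPABLE, multi.t = FALSE) {
  times <- if (multi.t) c(0.5, 1, 2) else 1
  all(vapply(times, function(t) lumpabilityDefect(model, scheme, t)$eta <= tol,
             TRUE))
}

# Index of the pair (i, j), i != j, in the 6-long s vector.
.SIDX <- local({
  m <- matrix(0L, 4L, 4L)
  for (k in 1:6) {
    m[PAIR_INDEX[k, 1L], PAIR_INDEX[k, 2L]] <- k
    m[PAIR_INDEX[k, 2L], PAIR_INDEX[k, 1L]] <- k
  }
  m
})

# Constraint rows on s from the rate-level lumpability criterion: within each
# block S_k (size >= 2, reference state i0), and for every other block S_l,
# sum_{j in S_l} s_{i0 j} pi_j  -  sum_{j in S_l} s_{i j} pi_j = 0.
# Every scheme yields exactly 2 rows. Bare-vector version for hot loops.
.constraints <- function(blocks_idx, pi) {
  rows <- vector("list", 2L)
  r <- 0L
  for (k in seq_along(blocks_idx)) {
    bk <- blocks_idx[[k]]
    if (length(bk) < 2L) next
    i0 <- bk[1L]
    for (i in bk[-1L]) {
      for (l in seq_along(blocks_idx)) {
        if (l == k) next
        row <- numeric(6L)
        for (j in blocks_idx[[l]]) {
          row[.SIDX[i0, j]] <- row[.SIDX[i0, j]] + pi[j]
          row[.SIDX[i, j]] <- row[.SIDX[i, j]] - pi[j]
        }
        r <- r + 1L
        rows[[r]] <- row
      }
    }
  }
  do.call(rbind, rows[seq_len(r)])
}

.blocks_idx <- function(scheme) {
  lapply(scheme@blocks, match, NUCLEOTIDES)
}

#' Linear lumpability constraints on the exchangeabilities
#'
#' Derives, from the rate-level lumpability criterion (block-row sums of
#' \eqn{R = S\Pi} constant within each block), the two linear equality
#' constraints \eqn{C(\pi) s = 0} that characterize lumpability of the SRH
#' model for a scheme. For 2:1:1 and 3:1 schemes the rows reduce to
#' frequency-free equalities between exchangeabilities (e.g. scheme Y:
#' \eqn{s_{AC} = s_{AT}} and \eqn{s_{CG} = s_{GT}}); for 2:2 schemes the
#' coefficients involve \eqn{\pi}.
#'
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @param pi stationary frequencies (numeric(4)) or a
#'   \linkS4class{SubstitutionModel}.
#' @return A 2 x 6 constraint matrix with columns named AC, AG, AT, CG, CT,
#'   GT; \code{C \%*\% s == 0} iff the process (\eqn{\pi}, s) is lumpable for
#'   the scheme.
#' @export
lumpabilityConstraints <- function(scheme, pi) {
  scheme <- recodingScheme(scheme)
  if (is(pi, "SubstitutionModel")) pi <- pi@pi
  C <- .constraints(.blocks_idx(scheme), pi)
  colnames(C) <- PAIR_NAMES
  C
}

# Euclidean projection of s onto {x : C x = 0}; rows of C need not be
# orthogonal.
.null_project <- function(s, C) {
  as.vector(s - crossprod(C, solve(tcrossprod(C), C %*% s)))
}

# Projection onto {x : C x = 0, x >= 0} by Dykstra's alternating projections
# (affine subspace vs. non-negative orthant); exact for this pair of convex
# sets.
.project_lumpable <- function(s, C, tol = 1e-12, max_iter = 10000L) {
  x <- .null_project(s, C)
  if (all(x >= 0)) return(x)
  p <- q <- numeric(length(s))
  y <- s
  for (it in seq_len(max_iter)) {
    x <- .null_project(y + p, C)
    p <- y + p - x
    y <- pmax(x + q, 0)
    q <- x + q - y
    if (max(abs(x - y)) < tol) break
  }
  x <- pmax(.null_project(y, C), 0)
  involved <- colSums(abs(C)) > 0
  if (max(abs(C %*% x)) > 1e-8 || all(x[involved] == 0))
    stop("degenerate projection: no non-negative exchangeability vector ",
         "satisfies the lumpability constraints near the estimate")
  x
}

#' Project a fitted model onto the lumpable subspace
#'
#' Keeps \eqn{\pi} fixed and replaces s by its Euclidean least-squares
#' projection onto \{s : C(\eqn{\pi})s = 0\}, clipped at zero (and
#' re-projected) if any entry goes negative. For 2:1:1 and 3:1 schemes this
#' reproduces the natural averaging rules (entries tied by a constraint are
#' replaced by their mean); for 2:2 schemes the projection depends on
#' \eqn{\pi}. Idempotent, and its output always passes
#' \code{\link{isLumpable}}.
#'
#' @param model a \linkS4class{SubstitutionModel} (e.g. an unconstrained fit).
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @return A lumpable \linkS4class{SubstitutionModel}.
#' @export
projectToLumpable <- function(model, scheme) {
  stopifnot(is(model, "SubstitutionModel"))
  scheme <- recodingScheme(scheme)
  C <- .constraints(.blocks_idx(scheme), model@pi)
  st <- .project_lumpable(model@s, C)
  substitutionModel(model@pi, st)
}

#' Recode a divergence matrix
#'
#' Aggregates the 4x4 site-pattern counts by the blocks of a scheme:
#' \eqn{n'_{kl} = \sum_{i \in S_k} \sum_{j \in S_l} n_{ij}}. Totals are
#' preserved.
#'
#' @param N a 4x4 divergence matrix.
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @return The q x q recoded divergence matrix.
#' @export
recodeCounts <- function(N, scheme) {
  .check_divergence(N, 4L)
  scheme <- recodingScheme(scheme)
  V <- .membership(scheme)
  Nq <- t(V) %*% N %*% V
  dimnames(Nq) <- list(colnames(V), colnames(V))
  Nq
}

#' The lumped q-state process
#'
#' Aggregates the joint distribution, \eqn{F_q(t) = V^T F(t) V}, and the
#' stationary distribution, \eqn{\pi_q = V^T \pi}, and reconstructs the
#' q-state analogue of the SRH model from them spectrally, giving the
#' transition matrix \eqn{P_q(t)} and rate matrix \eqn{R_q}. When the
#' process is lumpable, \eqn{P_q(t)} equals the conditional matrix
#' \eqn{P'(t) = U P(t) V}; when it is not, \eqn{P_q(t)} is still defined but
#' is not the transition matrix of the (non-Markovian) recoded process.
#'
#' @inheritParams lumpabilityDefect
#' @return list with \code{Fq} (q x q joint matrix), \code{Pq} (q x q
#'   transition matrix), \code{piq}, and \code{Rq} (the lumped rate matrix,
#'   scaled so that \code{Pq} at the given t corresponds to t = 1 of the
#'   reconstruction).
#' @export
lumpedChain <- function(model, scheme, t = 1) {
  stopifnot(is(model, "SubstitutionModel"))
  scheme <- recodingScheme(scheme)
  V <- .membership(scheme)
  Fq <- t(V) %*% .joint(model@pi, model@s, t) %*% V
  piq <- as.vector(crossprod(V, model@pi))
  sq <- sqrt(piq)
  Bq <- Fq / tcrossprod(sq)
  e <- eigen((Bq + t(Bq)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("saturation: the lumped joint matrix has a non-positive eigenvalue")
  lam <- 0.5 * log(e$values)
  L <- e$vectors
  Pq <- (L %*% (exp(lam) * t(L))) * tcrossprod(1 / sq, sq)
  Rq <- (L %*% (lam * t(L))) * tcrossprod(1 / sq, sq)
  labs <- colnames(V)
  dimnames(Fq) <- dimnames(Pq) <- dimnames(Rq) <- list(labs, labs)
  list(Fq = Fq, Pq = Pq, piq = setNames(piq, labs), Rq = Rq)
}

#' Conditional probability matrix of the recoded states
#'
#' \eqn{P'(t) = U P(t) V}: the conditional distribution of the recoded state
#' at time t given the recoded state at time 0, always a valid stochastic
#' matrix. It equals the lumped transition matrix \eqn{P_q(t)} exactly when
#' the process is lumpable.
#'
#' @inheritParams lumpabilityDefect
#' @return The q x q stochastic matrix P'(t).
#' @export
conditionalLumpedMatrix <- function(model, scheme, t = 1) {
  stopifnot(is(model, "SubstitutionModel"))
  scheme <- recodingScheme(scheme)
  ops <- lumpingOperators(scheme, model@pi)
  P <- ops$U %*% .transition(model@pi, model@s, t) %*% ops$V
  dimnames(P) <- list(colnames(ops$V), colnames(ops$V))
  P
}

#' Scale factor between original and lumped substitution rates
#'
#' \eqn{\rho = (-\sum_i \pi_i r_{ii}) / (-\sum_k \pi_{q,k} r_{q,kk})}: the
#' ratio of the expected substitution rate of the 4-state process to that of
#' the lumped q-state process. For a lumpable scheme, every edge length
#' estimated from recoded data equals the original edge length divided by
#' \eqn{\rho} (recoding hides within-block substitutions, so \eqn{\rho \ge
#' 1}).
#'
#' @inheritParams lumpabilityDefect
#' @return The scalar \eqn{\rho}, with attribute \code{lumpable} (logical).
#'   A warning is issued when the model is not lumpable for the scheme, in
#'   which case \eqn{\rho} has no uniform edge-scaling interpretation.
#' @examples
#' jc <- substitutionModel(rep(0.25, 4), rep(1, 6))
#' expectedSubstitutionScale(jc, "RY")  # 1.5
#' @export
expectedSubstitutionScale <- function(model, scheme) {
  stopifnot(is(model, "SubstitutionModel"))
  scheme <- recodingScheme(scheme)
  R <- rateMatrix(model)
  rate4 <- -sum(model@pi * diag(R))
  lc <- lumpedChain(model, scheme, t = 1)
  rateq <- -sum(lc$piq * diag(lc$Rq))
  lump <- isLumpable(model, scheme)
  if (!lump)
    warning("model is not lumpable for scheme ", scheme@name,
            "; rho does not describe a uniform edge-length rescaling")
  structure(rate4 / rateq, lumpable = lump)
}
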