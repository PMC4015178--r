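#' SubstitutionModel: a reversible 4-state substitution model
#'
#' Holds the stationary base frequencies \eqn{\pi} (order A, C, G, T) and the
#' six exchangeabilities \eqn{s} (order AC, AG, AT, CG, CT, GT) of a
#' stationary, reversible, homogeneous nucleotide substitution process with
#' rate matrix \eqn{R = S\Pi}. Time is measured so that the divergence time
#' between two homologous sequences is fixed at 1; rescaling time is
#' equivalent to rescaling \eqn{s}.
#'
#' @slot pi numeric(4), strictly positive, summing to 1.
#' @slot s numeric(6), non-negative, not all zero.
#' @export
setClass("SubstitutionModel",
         representation(pi = "numeric", s = "numeric"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  if (length(object@pi) != 4L)
    msg <- c(msg, "'pi' must have length 4 (A, C, G, T)")
  else {
    if (any(object@pi <= 0))
      msg <- c(msg, "all base frequencies must be strictly positive")
    if (abs(sum(object@pi) - 1) > 1e-12)
      msg <- c(msg, "base frequencies must sum to 1 (tolerance 1e-12)")
  }
  if (length(object@s) != 6L)
    msg <- c(msg, "'s' must have length 6 (AC, AG, AT, CG, CT, GT)")
  else {
    if (any(object@s < 0))
      msg <- c(msg, "exchangeabilities must be non-negative")
    if (all(object@s == 0))
      msg <- c(msg, "at least one exchangeability must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a substitution model
#'
#' @param pi numeric(4) stationary base frequencies in A, C, G, T order.
#' @param s numeric(6) exchangeabilities in AC, AG, AT, CG, CT, GT order.
#' @return A \linkS4class{SubstitutionModel}.
#' @examples
#' substitutionModel(pi = c(0.1, 0.2, 0.3, 0.4),
#'                   s  = c(0.2, 0.25, 0.2, 0.2, 0.15, 0.2))
#' @export
substitutionModel <- function(pi, s) {
  new("SubstitutionModel",
      pi = setNames(as.numeric(pi), NUCLEOTIDES),
      s  = setNames(as.numeric(s), PAIR_NAMES))
}

#' @describeIn substitutionModel stationary base frequencies
#' @param object a \code{SubstitutionModel}
#' @export
baseFreqs <- function(object) object@pi

#' @describeIn substitutionModel exchangeability vector
#' @export
exchangeabilities <- function(object) object@s

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel (SRH, reversible; R = S*Pi)\n")
  cat("  pi:", paste0(NUCLEOTIDES, "=", signif(object@pi, 4), collapse = " "), "\n")
  cat("  s: ", paste0(PAIR_NAMES, "=", signif(object@s, 4), collapse = " "), "\n")
})

#' RecodingScheme: a partition of the nucleotide alphabet
#'
#' A partition of \{A, C, G, T\} into q = 2 or 3 blocks, identified by its
#' IUPAC-style label. There are exactly 13 such schemes: six of category
#' 2:1:1 (one pair merged), four of 3:1 (a triplet merged), and three of 2:2
#' (two pairs merged).
#'
#' @slot name character, e.g. "RY" or "B".
#' @slot blocks list of character vectors partitioning the four nucleotides.
#' @slot q integer, number of lumped states (2 or 3).
#' @slot category character, one of "2:1:1", "3:1", "2:2".
#' @slot gamma integer vector of block sizes.
#' @export
setClass("RecodingScheme",
         representation(name = "character", blocks = "list",
                        q = "integer", category = "character",
                        gamma = "integer"))

setValidity("RecodingScheme", function(object) {
  msg <- character()
  states <- sort(unlist(object@blocks))
  if (!identical(states, sort(NUCLEOTIDES)))
    msg <- c(msg, "blocks must partition {A, C, G, T}")
  if (object@q != length(object@blocks) || !(object@q %in% 2:3))
    msg <- c(msg, "'q' must equal the number of blocks and be 2 or 3")
  if (!identical(object@gamma, vapply(object@blocks, length, 1L)))
    msg <- c(msg, "'gamma' must give the block sizes")
  cat_expected <- paste(sort(object@gamma, decreasing = TRUE), collapse = ":")
  if (!identical(object@category, cat_expected))
    msg <- c(msg, sprintf("category '%s' inconsistent with block sizes (%s)",
                          object@category, cat_expected))
  if (length(msg)) msg else TRUE
})

setMethod("show", "RecodingScheme", function(object) {
  cat(sprintf("RecodingScheme '%s' [%s]: %s\n", object@name, object@category,
              paste(vapply(object@blocks, paste, "", collapse = ""),
                    collapse = " | ")))
})

#' Accessors for RecodingScheme
#'
#' @param object a \linkS4class{RecodingScheme}
#' @return \code{schemeName}: the IUPAC-style label; \code{schemeBlocks}: the
#'   list of blocks; \code{numStates}: q, the number of lumped states;
#'   \code{blockSizes}: the vector \eqn{\gamma} of block sizes.
#' @name scheme-accessors
NULL

#' @rdname scheme-accessors
#' @export
schemeName <- function(object) object@name
#' @rdname scheme-accessors
#' @export
schemeBlocks <- function(object) object@blocks
#' @rdname scheme-accessors
#' @export
numStates <- function(object) object@q
#' @rdname scheme-accessors
#' @export
blockSizes <- function(object) object@gamma

#' LumpabilityTest: result of a lumpability (or symmetry) test
#'
#' @slot method character: "index", "markov_chain", "lrt" or "bowker".
#' @slot statistic numeric test statistic.
#' @slot parameter named numeric: degrees of freedom ("df") or bootstrap
#'   replicate count ("B").
#' @slot p.value numeric in [0, 1].
#' @slot estimates list of fitted parameters (unconstrained and, where
#'   applicable, constrained).
#' @slot scheme the \linkS4class{RecodingScheme} tested (may be empty for the
#'   symmetry test).
#' @slot details list of method-specific diagnostics (eta, convergence,
#'   bootstrap failure count, ...).
#' @export
setClass("LumpabilityTest",
         representation(method = "character", statistic = "numeric",
                        parameter = "numeric", p.value = "numeric",
                        estimates = "list", scheme = "list",
                        details = "list"))

setValidity("LumpabilityTest", function(object) {
  msg <- character()
  if (!is.na(object@p.value) &&
      (object@p.value < 0 || object@p.value > 1))
    msg <- c(msg, "p.value must lie in [0, 1]")
  if (!is.na(object@statistic) && object@statistic < 0)
    msg <- c(msg, "statistic must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LumpabilityTest", function(object) {
  label <- switch(object@method,
                  index = "Lumpability index test (parametric bootstrap)",
                  markov_chain = "Markov-chain chi-squared test for lumpability",
                  lrt = "Likelihood-ratio test for lumpability",
                  bowker = "Matched-pairs test of symmetry (Bowker)",
                  object@method)
  cat(label, "\n")
  if (length(object@scheme))
    cat(sprintf("  scheme: %s\n", object@scheme[[1L]]@name))
  par <- paste(names(object@parameter), "=", signif(object@parameter, 6),
               collapse = ", ")
  cat(sprintf("  statistic = %.6g, %s, p-value = %.4g\n",
              object@statistic, par, object@p.value))
  if (!is.null(object@details$eta.hat))
    cat(sprintf("  eta.hat = %.6g\n", object@details$eta.hat))
  if (!is.null(object@details$converged) && !object@details$converged)
    cat("  warning: constrained optimisation did not converge\n")
})

#' @describeIn LumpabilityTest-class the test's p-value
#' @param object a \code{LumpabilityTest}
#' @export
pValue <- function(object) object@p.value

#' @describeIn LumpabilityTest-class the test statistic
#' @export
testStatistic <- function(object) object@statistic

.new_test_result <- function(method, statistic, parameter, p.value,
                             estimates = list(), scheme = NULL,
                             details = list()) {
  new("LumpabilityTest", method = method, statistic = statistic,
      parameter = parameter, p.value = p.value, estimates = estimates,
      scheme = if (is.null(scheme)) list() else list(scheme),
      details = details)
}
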