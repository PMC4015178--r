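# End-to-end workflow for alignments: FASTA ingestion and column cleaning,
# pairwise divergence counting, SRH screening, all-pairs lumpability testing,
# and PP-plot data.

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "DNAStringSet") || is(aln, "BStringSet"))
    return(as.matrix(aln))
  stop("'aln' must be a DNAStringSet (see readAlignment)")
}

.count_pair <- function(m, i, j) {
  N <- table(factor(m[i, ], levels = NUCLEOTIDES),
             factor(m[j, ], levels = NUCLEOTIDES))
  matrix(as.numeric(N), 4L, 4L, dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
}

#' Read and clean a FASTA alignment
#'
#' Reads a multiple sequence alignment, uppercases it, and (by default)
#' removes every column containing any character outside \{A, C, G, T\} --
#' gaps and IUPAC ambiguity codes -- so that downstream divergence matrices
#' are counted over fully resolved columns.
#'
#' @param path path to a FASTA file.
#' @param clean drop columns with non-ACGT characters (default TRUE). The
#'   number of removed columns is reported via \code{message}.
#' @return A \code{Biostrings::DNAStringSet} with equal-width sequences, in
#'   input order.
#' @export
readAlignment <- function(path, clean = TRUE) {
  if (!file.exists(path)) stop("cannot read alignment: '", path, "' not found")
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) < 2L) stop("alignment must contain at least 2 sequences")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("sequences have unequal lengths; input is not an alignment")
  seqs <- toupper(as.character(aln))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(aln)
  if (clean) {
    keep <- colSums(!matrix(m %in% NUCLEOTIDES, nrow(m))) == 0L
    removed <- sum(!keep)
    if (removed > 0)
      message("removed ", removed, " column(s) containing gaps or ",
              "ambiguous characters (", ncol(m) - removed, " retained)")
    if (removed > 0.5 * ncol(m))
      warning("more than half of the alignment columns were removed")
    m <- m[, keep, drop = FALSE]
  } else if (any(!(m %in% NUCLEOTIDES))) {
    stop("alignment contains non-ACGT characters; use clean = TRUE")
  }
  if (ncol(m) == 0L) stop("no fully resolved columns remain after cleaning")
  Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
}

#' Divergence matrix of one sequence pair
#'
#' Counts the 4x4 site-pattern table for sequences i and j of an alignment:
#' entry (a, b) is the number of columns showing nucleotide a in sequence i
#' and b in sequence j.
#'
#' @param aln a \code{DNAStringSet} (e.g. from \code{\link{readAlignment}}).
#' @param i,j sequence indices or names.
#' @return A 4x4 divergence matrix.
#' @export
pairDivergenceMatrix <- function(aln, i, j) {
  m <- .aln_matrix(aln)
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, rownames(m))
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > nrow(m) || j > nrow(m))
    stop("invalid sequence selection")
  .count_pair(m, i, j)
}

.result_row <- function(i, j, scheme_name, method, res) {
  if (inherits(res, "error"))
    return(data.frame(taxon.i = i, taxon.j = j, scheme = scheme_name,
                      method = method, statistic = NA_real_,
                      df.or.B = NA_real_, p.value = NA_real_,
                      eta.hat = NA_real_, converged = NA,
                      error = conditionMessage(res),
                      stringsAsFactors = FALSE))
  data.frame(taxon.i = i, taxon.j = j, scheme = scheme_name, method = method,
             statistic = res@statistic,
             df.or.B = unname(res@parameter[1L]),
             p.value = res@p.value,
             eta.hat = res@details$eta.hat %||% NA_real_,
             converged = res@details$converged %||% NA,
             error = NA_character_, stringsAsFactors = FALSE)
}

#' Lumpability tests over all sequence pairs
#'
#' Applies a lumpability test to every unordered pair of sequences in an
#' alignment (m sequences give m(m-1)/2 p-values per scheme and method).
#' Per-pair failures are recorded in the output rather than aborting the run.
#' Note that pairs sharing lineages give dependent p-values; interpret the
#' collection through a PP-plot (\code{\link{ppPlotData}}) rather than with
#' multiplicity corrections.
#'
#' @param aln a \code{DNAStringSet}.
#' @param scheme scheme name(s) or \linkS4class{RecodingScheme}(s).
#' @param method one or more of "lrt", "index", "mc".
#' @param B index-test bootstrap size.
#' @param seed optional integer seed (pair p gets seed + p for its bootstrap
#'   stream).
#' @param ... further arguments passed to the tests.
#' @return data.frame with one row per pair x scheme x method: taxon.i,
#'   taxon.j, scheme, method, statistic, df.or.B, p.value, eta.hat,
#'   converged, error.
#' @export
allPairsTests <- function(aln, scheme = "RY", method = "lrt", B = 500L,
                          seed = NULL, ...) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  schemes <- if (is(scheme, "RecodingScheme")) list(scheme)
             else lapply(scheme, recodingScheme)
  pairs <- t(combn(nrow(m), 2L))
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    N <- .count_pair(m, i, j)
    for (sc in schemes) {
      for (meth in method) {
        if (!is.null(seed) && meth == "index") set.seed(seed + p)
        res <- tryCatch(
          switch(meth,
                 index = indexTest(N, sc, B = B, ...),
                 lrt = likelihoodRatioTest(N, sc, ...),
                 markovChainTest(N, sc, ...)),
          error = function(e) e)
        rows[[length(rows) + 1L]] <-
          .result_row(labels[i], labels[j], sc@name, meth, res)
      }
    }
  }
  do.call(rbind, rows)
}

#' Screen an alignment for SRH consistency
#'
#' Applies the matched-pairs test of symmetry (\code{\link{bowkerTest}}) to
#' every sequence pair. The lumpability tests assume globally SRH evolution;
#' a PP-plot of these symmetry p-values close to the diagonal supports that
#' assumption.
#'
#' @param aln a \code{DNAStringSet}.
#' @param ks.level level of the Kolmogorov-Smirnov uniformity check used for
#'   the summary flag (default 0.01).
#' @return list with \code{table} (per-pair results), \code{pp} (PP-plot
#'   data of the p-values), \code{ks.p.value}, and \code{consistent}
#'   (TRUE when uniformity is not rejected at \code{ks.level}).
#' @export
srhScreen <- function(aln, ks.level = 0.01) {
  m <- .aln_matrix(aln)
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  pairs <- t(combn(nrow(m), 2L))
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    res <- tryCatch(bowkerTest(.count_pair(m, i, j)), error = function(e) e)
    .result_row(labels[i], labels[j], NA_character_, "bowker", res)
  })
  tab <- do.call(rbind, rows)
  p <- tab$p.value[!is.na(tab$p.value)]
  pp <- ppPlotData(p)
  ksp <- attr(pp, "ks.p.value")
  list(table = tab, pp = pp, ks.p.value = ksp,
       consistent = !is.na(ksp) && ksp > ks.level)
}

#' PP-plot data for a set of p-values
#'
#' Pairs the sorted observed p-values with uniform plotting positions
#' k/(K+1). Under the null all p-values are Uniform(0,1) and the points lie
#' on the diagonal; an excess of small p-values bends the curve above it.
#' A Kolmogorov-Smirnov test against the uniform distribution is attached as
#' attributes \code{ks.statistic} and \code{ks.p.value}.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return data.frame with columns \code{expected} and \code{observed}.
#' @export
ppPlotData <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 1L) stop("need at least one p-value")
  K <- length(pvalues)
  out <- data.frame(expected = seq_len(K) / (K + 1),
                    observed = sort(pvalues))
  ks <- suppressWarnings(ks.test(pvalues, "punif"))
  attr(out, "ks.statistic") <- unname(ks$statistic)
  attr(out, "ks.p.value") <- ks$p.value
  out
}
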