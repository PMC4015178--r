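# Monte Carlo engines: multinomial divergence matrices, sequence simulation
# on trees, and the calibration / power / recoding-bias experiment drivers.
#
# Reproducibility convention: every driver takes one integer seed; replicate
# r uses seed + r so that experiments can be re-run or split
# deterministically. Bootstrap draws inside a replicate consume that
# replicate's stream.

#' Sample a divergence matrix from the SRH model
#'
#' Draws N ~ Multinomial(n, F(1)), the sampling distribution of the
#' site-pattern counts of two homologous sequences of length n under the
#' model.
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param n number of sites.
#' @param seed optional integer seed.
#' @return A 4x4 integer divergence matrix summing to \code{n}.
#' @export
sampleDivergenceMatrix <- function(model, n, seed = NULL) {
  stopifnot(is(model, "SubstitutionModel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- as.vector(pmax(.joint(model@pi, model@s, 1), 0))
  N <- matrix(rmultinom(1L, n, probs / sum(probs)), 4L, 4L,
              dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
  N
}

#' Simulate sequences on a tree under the SRH model
#'
#' Root states are drawn from \eqn{\pi}; each site then evolves independently
#' down the tree, each edge applying the transition matrix P(edge length).
#'
#' @param tree an \code{ape::phylo} tree with edge lengths (time units), or a
#'   Newick string / file path readable by \code{ape::read.tree}.
#' @param model a \linkS4class{SubstitutionModel}.
#' @param n.sites number of sites to simulate.
#' @param seed optional integer seed.
#' @return A \code{Biostrings::DNAStringSet} of tip sequences, named by tip
#'   labels.
#' @export
simulateAlignment <- function(tree, model, n.sites, seed = NULL) {
  stopifnot(is(model, "SubstitutionModel"), n.sites >= 1)
  tree <- .as_phylo(tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative edge lengths")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- vector("list", nnode)
  root <- ntip + 1L
  states[[root]] <- sample.int(4L, n.sites, replace = TRUE, prob = model@pi)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    P <- .transition(model@pi, model@s, tree$edge.length[e])
    P <- pmax(P, 0)
    ps <- states[[parent]]
    cs <- integer(n.sites)
    for (i in 1:4) {
      w <- which(ps == i)
      if (length(w))
        cs[w] <- sample.int(4L, length(w), replace = TRUE, prob = P[i, ])
    }
    states[[child]] <- cs
  }
  seqs <- vapply(seq_len(ntip),
                 function(k) paste(NUCLEOTIDES[states[[k]]], collapse = ""),
                 "")
  Biostrings::DNAStringSet(setNames(seqs, tree$tip.label))
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    tr <- suppressWarnings(
      if (file.exists(tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree))
    if (is.null(tr)) stop("could not parse tree")
    return(tr)
  }
  stop("'tree' must be a phylo object, a Newick string, or a file path")
}

#' Calibration / rejection-rate experiment for the lumpability tests
#'
#' Repeatedly draws divergence matrices from the model, applies the selected
#' tests for a scheme, and tabulates p-values and rejection rates. Run with a
#' lumpable model to measure type-I error; with a non-lumpable model the
#' rejection rate is the empirical power.
#'
#' @param model the true \linkS4class{SubstitutionModel} generating the data.
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @param n sites per replicate (default 1500).
#' @param replicates number of Monte Carlo replicates.
#' @param methods subset of c("index", "markov_chain", "lrt").
#' @param B bootstrap replicates for the index test.
#' @param seed integer seed; replicate r is reseeded with seed + r.
#' @param levels rejection levels to tabulate.
#' @return list with \code{pvalues} (one row per replicate x method, columns
#'   replicate, method, statistic, p.value, error), \code{summary} (rejection
#'   rate per method and level), and \code{pp} (per-method PP-plot data, see
#'   \code{\link{ppPlotData}}).
#' @export
calibrationExperiment <- function(model, scheme, n = 1500L,
                                  replicates = 1000L,
                                  methods = c("index", "markov_chain", "lrt"),
                                  B = 500L, seed = 1L, levels = 0.05) {
  stopifnot(is(model, "SubstitutionModel"), replicates >= 1L, n >= 1L)
  scheme <- recodingScheme(scheme)
  methods <- match.arg(methods, c("index", "markov_chain", "lrt"),
                       several.ok = TRUE)
  probs <- as.vector(pmax(.joint(model@pi, model@s, 1), 0))
  probs <- probs / sum(probs)
  rows <- vector("list", replicates * length(methods))
  k <- 0L
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    N <- matrix(rmultinom(1L, n, probs), 4L, 4L)
    for (m in methods) {
      res <- tryCatch(
        switch(m,
               index = indexTest(N, scheme, B = B),
               markov_chain = markovChainTest(N, scheme),
               lrt = likelihoodRatioTest(N, scheme)),
        error = function(e) e)
      k <- k + 1L
      rows[[k]] <- if (inherits(res, "error"))
        data.frame(replicate = r, method = m, statistic = NA_real_,
                   p.value = NA_real_, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      else
        data.frame(replicate = r, method = m, statistic = res@statistic,
                   p.value = res@p.value, error = NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  pvals <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    p <- pvals$p.value[pvals$method == m]
    failed <- sum(is.na(p))
    p <- p[!is.na(p)]
    data.frame(method = m,
               level = levels,
               rejection.rate = vapply(levels,
                                       function(a) mean(p < a), 0),
               replicates = length(p), failed = failed,
               stringsAsFactors = FALSE)
  }))
  pp <- lapply(setNames(methods, methods), function(m) {
    p <- pvals$p.value[pvals$method == m]
    ppPlotData(p[!is.na(p)])
  })
  list(pvalues = pvals, summary = summ, pp = pp)
}

#' Power curve over increasing departure from lumpability
#'
#' For each exchangeability vector in \code{s.list}, computes the true
#' departure index eta and the empirical power of the selected tests at the
#' given level.
#'
#' @param pi stationary base frequencies shared by all points.
#' @param s.list list of exchangeability vectors, ideally ordered by
#'   increasing eta.
#' @param scheme a \linkS4class{RecodingScheme} or scheme name.
#' @param n sites per replicate.
#' @param replicates Monte Carlo replicates per point.
#' @param methods tests to run.
#' @param B index-test bootstrap size.
#' @param seed integer seed (each point r reuses seed + point offset).
#' @param level rejection level (default 0.05).
#' @return data.frame with columns eta, method, power, replicates.
#' @export
powerCurve <- function(pi, s.list, scheme, n = 1500L, replicates = 300L,
                       methods = c("index", "markov_chain", "lrt"),
                       B = 500L, seed = 1L, level = 0.05) {
  scheme <- recodingScheme(scheme)
  out <- vector("list", length(s.list))
  for (k in seq_along(s.list)) {
    model <- substitutionModel(pi, s.list[[k]])
    eta <- lumpabilityDefect(model, scheme)$eta
    exp_k <- calibrationExperiment(model, scheme, n = n,
                                   replicates = replicates,
                                   methods = methods, B = B,
                                   seed = seed + (k - 1L) * (replicates + 1L),
                                   levels = level)
    out[[k]] <- cbind(eta = eta,
                      exp_k$summary[, c("method", "rejection.rate",
                                        "replicates")])
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "rejection.rate"] <- "power"
  res
}

# Expected substitutions per site of a fitted (pi, s) at t = 1:
# -sum_i pi_i r_ii of R = S Pi.
.expected_subs <- function(pi, s) {
  R <- .s_matrix(pi, s) %*% diag(pi)
  -sum(pi * diag(R))
}

#' Branch-length bias of recoding: original vs recoded pairwise distances
#'
#' For every pair of leaves, estimates the expected-substitution distance
#' twice: from the 4-state fit of the pairwise divergence matrix and from the
#' q-state fit of the recoded matrix. For a lumpable scheme the ratio
#' original/recoded is the same constant rho for every pair (recoded branch
#' lengths are uniformly shorter by 1/rho); for a non-lumpable scheme the
#' ratios differ across pairs, i.e. recoding distorts the tree shape, not
#' just its scale.
#'
#' @param tree \code{ape::phylo} (or Newick) with edge lengths.
#' @param model the generating \linkS4class{SubstitutionModel}.
#' @param schemes character vector of scheme names (default RY and KM).
#' @param n.sites number of sites to simulate; NULL (default) uses exact
#'   expected counts F(t) for each pair -- the infinite-data analogue.
#' @param seed integer seed (used only when simulating).
#' @return list with \code{table} (pair, scheme, d.original, d.recoded,
#'   ratio) and \code{rho} (named vector of the analytic scale factor per
#'   scheme, NA-attributed warnings suppressed for non-lumpable schemes).
#' @export
recodingBiasExperiment <- function(tree, model, schemes = c("RY", "KM"),
                                   n.sites = NULL, seed = NULL) {
  stopifnot(is(model, "SubstitutionModel"))
  tree <- .as_phylo(tree)
  dists <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  aln_mat <- NULL
  if (!is.null(n.sites)) {
    aln <- simulateAlignment(tree, model, n.sites, seed = seed)
    aln_mat <- .aln_matrix(aln)
  }
  pairs <- t(combn(length(tips), 2L))
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    N <- if (is.null(n.sites)) {
      .joint(model@pi, model@s, dists[tips[i], tips[j]] / 2)
    } else {
      .count_pair(aln_mat, i, j)
    }
    fit4 <- .estimate(N)
    d4 <- .expected_subs(fit4$pi, fit4$s)
    for (sc in schemes) {
      scheme <- recodingScheme(sc)
      V <- .membership(scheme)
      Nq <- t(V) %*% N %*% V
      fitq <- .estimate(Nq)
      dq <- .expected_subs(fitq$pi, fitq$s)
      rows[[length(rows) + 1L]] <-
        data.frame(taxon.i = tips[i], taxon.j = tips[j], scheme = sc,
                   d.original = d4, d.recoded = dq, ratio = d4 / dq,
                   stringsAsFactors = FALSE)
    }
  }
  rho <- vapply(schemes, function(sc)
    suppressWarnings(as.numeric(expectedSubstitutionScale(model, sc))), 0)
  list(table = do.call(rbind, rows), rho = rho)
}
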