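test_that("Markov-chain test statistic matches a loop-based oracle", {
  set.seed(301)
  nuc <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    N <- matrix(rpois(16, 80) + 1, 4, 4)
    for (s in listSchemes()) {
      res <- markovChainTest(N, s)
      # brute force: o_il and e_il summed in explicit loops
      blocks <- lapply(schemeBlocks(s), match, nuc)
      block_of <- integer(4)
      for (k in seq_along(blocks)) block_of[blocks[[k]]] <- k
      Tstat <- 0
      for (i in 1:4) for (l in seq_along(blocks)) {
        o <- sum(N[i, blocks[[l]]])
        k <- block_of[i]
        nk <- sum(N[unlist(blocks[k]), ])
        nkl <- sum(N[blocks[[k]], blocks[[l]]])
        e <- sum(N[i, ]) * nkl / nk
        Tstat <- Tstat + (o - e)^2 / e
      }
      expect_equal(testStatistic(res), Tstat, tolerance = 1e-10)
      expect_equal(unname(res@parameter["df"]), 2)
      expect_equal(pValue(res), pchisq(Tstat, 2, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("Markov-chain df formula gives 2 for every scheme", {
  for (s in listSchemes()) {
    df <- (numStates(s) - 1L) * sum(blockSizes(s) - 1L)
    expect_identical(df, 2L)
  }
})

test_that("Markov-chain test is exactly zero when block rows are proportional", {
  # rows within each block identical => o_il / n_i. constant within block
  row_ag <- c(40, 10, 30, 20)
  row_ct <- c(5, 50, 10, 35)
  N <- rbind(row_ag, row_ct, row_ag, row_ct)  # A,G identical; C,T identical
  res <- markovChainTest(N, "RY")
  expect_equal(testStatistic(res), 0, tolerance = 1e-12)
  expect_equal(pValue(res), 1)
})

test_that("Markov-chain test flags untestable cells and honours swap", {
  N <- matrix(5, 4, 4)
  N[, 3] <- 0; N[, 4] <- 0  # no transitions into block {G,T}
  expect_error(markovChainTest(N, "KM"), "untestable cell")
  set.seed(302)
  N <- matrix(rpois(16, 50) + 1, 4, 4)
  expect_equal(testStatistic(markovChainTest(N, "RY", swap = TRUE)),
               testStatistic(markovChainTest(t(N), "RY")))
  expect_error(markovChainTest(N, "RY", min.count = 1e6), "min.count")
})

test_that("Bowker symmetry test: arithmetic, df adjustment, degenerate input", {
  N <- matrix(8, 4, 4)
  res <- bowkerTest(N)
  expect_equal(testStatistic(res), 0)
  expect_equal(pValue(res), 1)
  # single asymmetric pair (3, 1): (3-1)^2/4 = 1 on 1 df
  N <- diag(c(10, 10, 10, 10)); N[1, 2] <- 3; N[2, 1] <- 1
  res <- bowkerTest(N)
  expect_equal(testStatistic(res), 1)
  expect_equal(unname(res@parameter["df"]), 1)
  expect_error(bowkerTest(diag(5, 4)), "untestable")
})

test_that("Bowker p-values are calibrated under the symmetric SRH model", {
  set.seed(303)
  p <- replicate(200, pValue(bowkerTest(
    sampleDivergenceMatrix(null_model(), 800))))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("index test is deterministic given a seed and sane at the null limit", {
  N <- sampleDivergenceMatrix(null_model(), 1500, seed = 9)
  r1 <- indexTest(N, "RY", B = 100, seed = 42)
  r2 <- indexTest(N, "RY", B = 100, seed = 42)
  expect_identical(pValue(r1), pValue(r2))
  expect_identical(r1@details$eta.star, r2@details$eta.star)
  # exact expected counts under a lumpable model: eta-hat ~ 0, p ~ 1
  Nexact <- 1e6 * jointProbabilityMatrix(null_model())
  res <- indexTest(Nexact, "RY", B = 50, seed = 1)
  expect_lt(res@details$eta.hat, 1e-6)
  expect_gt(pValue(res), 0.9)
  # add-one variant is always positive
  res1 <- indexTest(sampleDivergenceMatrix(alt_model(), 1500, seed = 2),
                    "RY", B = 50, seed = 3, add.one = TRUE)
  expect_gt(pValue(res1), 0)
})

test_that("constrained MLE respects the constraints and never beats the MLE", {
  set.seed(304)
  for (rep in 1:5) {
    N <- sampleDivergenceMatrix(alt_model(), 1000)
    fit <- estimateSRH(N)
    for (sc in c("RY", "R", "B")) {
      cm <- constrainedMLE(N, sc)
      C <- lumpabilityConstraints(sc, cm$pi)
      expect_lt(max(abs(C %*% cm$s)), 1e-10)
      expect_lte(cm$logLik, fit$logLik + 1e-8)
      # optimization can only improve on the plain projection
      pr <- projectToLumpable(
        substitutionModel(fit$pi, pmax(fit$s, 0)), sc)
      expect_gte(cm$logLik,
                 divergenceLogLik(N, pr) - 1e-8)
    }
  }
})

test_that("constrained MLE agrees with an independent optimizer (scheme R)", {
  # oracle: direct 7-parameter maximization of the tied parameterization
  # s_AC = s_CG, s_AT = s_GT (pi-free constraints), positivity via log scale
  oracle_loglik <- function(N) {
    nll <- function(par) {
      p <- exp(c(par[1:3], 0)); p <- p / sum(p)
      sf <- exp(par[4:7])
      s <- c(sf[1], sf[2], sf[3], sf[1], sf[4], sf[3])
      m <- tryCatch(substitutionModel(p, s), error = function(e) NULL)
      if (is.null(m)) return(1e10)
      Fm <- jointProbabilityMatrix(m)
      if (any(Fm[N > 0] <= 0)) return(1e10)
      -sum(N[N > 0] * log(Fm[N > 0]))
    }
    best <- Inf
    for (r in 1:3) {
      st <- c(rnorm(3, 0, 0.5), log(runif(4, 0.05, 0.5)))
      o <- optim(st, nll, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
      o <- optim(o$par, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    -best
  }
  set.seed(305)
  for (rep in 1:3) {
    N <- sampleDivergenceMatrix(null_model(), 300)
    cm <- constrainedMLE(N, "R")
    expect_equal(cm$logLik, oracle_loglik(N), tolerance = 1e-4)
  }
})

test_that("likelihood-ratio test: df 2 for every scheme, zero at exact null", {
  N <- sampleDivergenceMatrix(null_model(), 2000, seed = 7)
  for (s in listSchemes()) {
    res <- likelihoodRatioTest(N, s)
    expect_equal(unname(res@parameter["df"]), 2)
    expect_gte(testStatistic(res), 0)
  }
  # exact lumpable expected counts: statistic collapses to zero
  Nexact <- 1e6 * jointProbabilityMatrix(null_model())
  res <- likelihoodRatioTest(Nexact, "RY")
  expect_lt(testStatistic(res), 1e-3)
  expect_gt(pValue(res), 0.99)
})

test_that("LRT null self-consistency at large n: constrained fit tracks the MLE", {
  N <- sampleDivergenceMatrix(null_model(), 2e5, seed = 11)
  res <- likelihoodRatioTest(N, "RY")
  est <- res@estimates
  expect_lt(max(abs(est$pi.hat - est$pi.tilde)), 5e-3)
  expect_lt(max(abs(est$s.hat - est$s.tilde)), 5e-3)
  expect_true(res@details$converged)
})

test_that("the dispatcher routes to the right method", {
  N <- sampleDivergenceMatrix(null_model(), 1500, seed = 5)
  expect_equal(lumpabilityTest(N, "RY", "mc")@method, "markov_chain")
  expect_equal(lumpabilityTest(N, "RY", "lrt")@method, "lrt")
  expect_equal(lumpabilityTest(N, "RY", "index", B = 20, seed = 1)@method,
               "index")
})
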