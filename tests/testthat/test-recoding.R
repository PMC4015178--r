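test_that("the catalogue holds exactly the 13 partitions into 2 or 3 blocks", {
  schemes <- listSchemes()
  expect_length(schemes, 13L)
  cats <- table(vapply(schemes, function(s) s@category, ""))
  expect_equal(unname(cats[c("2:1:1", "3:1", "2:2")]), c(6L, 4L, 3L),
               ignore_attr = TRUE)
  # brute-force enumeration of all set partitions (Stirling 7 + 6 = 13)
  keys <- brute_force_partitions()
  expect_length(keys, 13L)
  expect_setequal(vapply(schemes, scheme_key, ""), keys)
  # IUPAC semantics
  expect_setequal(schemeBlocks(schemes$RY), list(c("A", "G"), c("C", "T")))
  expect_equal(schemes$RY@category, "2:2")
  expect_setequal(schemeBlocks(schemes$B), list("A", c("C", "G", "T")))
  expect_setequal(schemeBlocks(schemes$W), list("C", "G", c("A", "T")))
})

test_that("schemes resolve by name (case-insensitive) and partition syntax", {
  expect_equal(schemeName(recodingScheme("ry")), "RY")
  expect_equal(schemeName(recodingScheme("AG|CT")), "RY")
  expect_equal(schemeName(recodingScheme("CT|AG")), "RY")
  expect_equal(schemeName(recodingScheme("A|CGT")), "B")
  expect_equal(schemeName(recodingScheme("AG|C|T")), "R")
  expect_error(recodingScheme("XYZ"), "unknown")
  expect_error(recodingScheme("AG|C"), "partition")
})

test_that("lumping operators satisfy U V = I and pi-weighted structure", {
  set.seed(201)
  for (i in 1:20) {
    pi <- rgamma(4, 5); pi <- pi / sum(pi)
    for (s in listSchemes()) {
      ops <- lumpingOperators(s, pi)
      expect_equal(unname(ops$U %*% ops$V), diag(s@q), tolerance = 1e-12)
      expect_true(all(rowSums(ops$V) == 1))
      # VᵀΠV is the diagonal of block probabilities
      blockp <- vapply(schemeBlocks(s),
                       function(b) sum(pi[match(b, c("A","C","G","T"))]), 0)
      expect_equal(unname(t(ops$V) %*% (pi * ops$V)), diag(blockp, s@q),
                   tolerance = 1e-12)
      # each U row is pi restricted to the block, renormalized
      expect_equal(unname(rowSums(ops$U)), rep(1, s@q), tolerance = 1e-12)
    }
  }
})

test_that("eta classifies the reference parameter sets as the theory says", {
  # under Jukes-Cantor symmetry every recoding is lumpable
  for (s in listSchemes())
    expect_lt(lumpabilityDefect(jc_model(), s)$eta, 1e-12)
  # RY-lumpable, KM-non-lumpable bias model
  expect_lt(lumpabilityDefect(bias_model(), "RY")$eta, 1e-10)
  expect_gt(lumpabilityDefect(bias_model(), "KM")$eta, 1e-3)
  # calibration null is RY-lumpable, its s_AC = 0.5 alternative is not
  expect_lt(lumpabilityDefect(null_model(), "RY")$eta, 1e-10)
  expect_gt(lumpabilityDefect(alt_model(), "RY")$eta, 1e-3)
})

test_that("eta does not depend on the evaluation time", {
  set.seed(202)
  for (i in 1:10) {
    m <- rand_model()
    for (s in c("RY", "Y", "B")) {
      etas <- vapply(c(0.5, 1, 2),
                     function(t) lumpabilityDefect(m, s, t)$eta, 0)
      expect_equal(etas > 1e-10, rep(etas[2] > 1e-10, 3))
    }
  }
  expect_true(isLumpable(bias_model(), "RY", multi.t = TRUE))
})

test_that("constraint rows encode the frequency-free equalities for 2:1:1 and 3:1", {
  pi <- baseFreqs(null_model())
  # scheme Y = {A, G, {C,T}}: s_AC = s_AT and s_CG = s_GT
  C <- lumpabilityConstraints("Y", pi)
  expect_equal(dim(C), c(2L, 6L))
  dirs <- t(apply(C, 1, function(r) r / max(abs(r))))
  expect_equal(sort(colnames(C)[apply(abs(dirs) > 1e-12, 2, any)]),
               c("AC", "AT", "CG", "GT"))
  expect_equal(unname(dirs[1, c("AC", "AT")]), c(1, -1))
  expect_equal(unname(dirs[2, c("CG", "GT")]), c(1, -1))
  # scheme B = {A, {C,G,T}}: ties s_AC = s_AG = s_AT
  CB <- lumpabilityConstraints("B", pi)
  expect_true(all(abs(CB[, c("CG", "CT", "GT")]) < 1e-12))
  # RY constraints hold at the calibration null
  CRY <- lumpabilityConstraints("RY", pi)
  expect_lt(max(abs(CRY %*% exchangeabilities(null_model()))), 1e-12)
})

test_that("C(pi) s = 0 is equivalent to eta = 0 across schemes", {
  set.seed(203)
  for (i in 1:15) {
    m <- rand_model()
    for (s in listSchemes()) {
      C <- lumpabilityConstraints(s, baseFreqs(m))
      alg <- max(abs(C %*% exchangeabilities(m))) < 1e-10
      expect_equal(lumpabilityDefect(m, s)$eta <= 1e-10, alg)
    }
  }
})

test_that("projection reproduces the averaging rules and is optimal", {
  set.seed(204)
  m <- rand_model()
  s <- exchangeabilities(m)
  # 3:1 scheme B: the three tied entries are replaced by their mean
  pr <- projectToLumpable(m, "B")
  expect_equal(unname(exchangeabilities(pr)[c("AC", "AG", "AT")]),
               rep(mean(s[c("AC", "AG", "AT")]), 3), tolerance = 1e-12)
  expect_equal(exchangeabilities(pr)[c("CG", "CT", "GT")],
               s[c("CG", "CT", "GT")], tolerance = 1e-12)
  # 2:1:1 scheme R: pairwise means
  prR <- projectToLumpable(m, "R")
  expect_equal(unname(exchangeabilities(prR)["AC"]),
               unname(mean(s[c("AC", "CG")])), tolerance = 1e-12)
  # idempotence and feasibility everywhere
  for (sc in listSchemes()) {
    p1 <- projectToLumpable(m, sc)
    expect_true(isLumpable(p1, sc, tol = 1e-9))
    p2 <- projectToLumpable(p1, sc)
    expect_equal(exchangeabilities(p2), exchangeabilities(p1),
                 tolerance = 1e-9)
  }
  # lumpable input returned unchanged
  pb <- projectToLumpable(bias_model(), "RY")
  expect_equal(exchangeabilities(pb), exchangeabilities(bias_model()),
               tolerance = 1e-10)
  # least-squares optimality for RY: no feasible candidate is closer
  C <- lumpabilityConstraints("RY", baseFreqs(m))
  st <- exchangeabilities(projectToLumpable(m, "RY"))
  d0 <- sum((st - s)^2)
  for (k in 1:200) {
    cand <- rgamma(6, 2, 4)
    cand <- cand - as.vector(crossprod(C, solve(tcrossprod(C), C %*% cand)))
    if (any(cand < 0)) next
    expect_gte(sum((cand - s)^2) + 1e-12, d0)
  }
})

test_that("recoded counts aggregate by blocks and preserve totals", {
  N <- diag(7, 4)
  expect_equal(unname(recodeCounts(N, "RY")), diag(14, 2))
  # hand-computed example
  N <- matrix(1:16, 4, 4, dimnames = list(c("A","C","G","T"),
                                          c("A","C","G","T")))
  Nq <- recodeCounts(N, "RY")
  expect_equal(unname(Nq["AG", "AG"]), N["A","A"] + N["A","G"] +
                 N["G","A"] + N["G","G"], ignore_attr = TRUE)
  expect_equal(unname(Nq["AG", "CT"]), N["A","C"] + N["A","T"] +
                 N["G","C"] + N["G","T"], ignore_attr = TRUE)
  for (s in listSchemes())
    expect_equal(sum(recodeCounts(N, s)), sum(N))
})

test_that("lumped chain equals the conditional chain exactly when lumpable", {
  lc <- lumpedChain(bias_model(), "RY")
  Pp <- conditionalLumpedMatrix(bias_model(), "RY")
  expect_lt(max(abs(lc$Pq - Pp)), 1e-10)
  expect_equal(sum(lc$piq), 1, tolerance = 1e-12)
  expect_equal(sum(lc$Fq), 1, tolerance = 1e-12)
  # non-lumpable: the reconstructed Pq is not the conditional matrix
  lcKM <- lumpedChain(bias_model(), "KM")
  PpKM <- conditionalLumpedMatrix(bias_model(), "KM")
  expect_gt(max(abs(lcKM$Pq - PpKM)), 1e-4)
})

test_that("conditional lumped matrix is stochastic and matches brute force", {
  set.seed(205)
  m <- rand_model()
  for (s in listSchemes()) {
    Pp <- conditionalLumpedMatrix(m, s, t = 0.7)
    expect_equal(unname(rowSums(Pp)), rep(1, s@q), tolerance = 1e-12)
    expect_equal(unname(conditionalLumpedMatrix(m, s, 0)), diag(s@q),
                 tolerance = 1e-12)
    # brute force: P'_kl = sum_{i in Sk} pi_i / pi(Sk) * sum_{j in Sl} P_ij
    P <- transitionMatrix(m, 0.7)
    pi <- baseFreqs(m)
    nuc <- c("A","C","G","T")
    for (k in seq_len(s@q)) for (l in seq_len(s@q)) {
      bk <- match(schemeBlocks(s)[[k]], nuc)
      bl <- match(schemeBlocks(s)[[l]], nuc)
      val <- sum(vapply(bk, function(i)
        pi[i] / sum(pi[bk]) * sum(P[i, bl]), 0))
      expect_equal(unname(Pp[k, l]), unname(val), tolerance = 1e-12)
    }
  }
})

test_that("rho is the closed-form 1.5 for Jukes-Cantor RY and >= 1 when lumpable", {
  expect_equal(as.numeric(expectedSubstitutionScale(jc_model(), "RY")), 1.5,
               tolerance = 1e-12)
  rho <- expectedSubstitutionScale(bias_model(), "RY")
  expect_true(attr(rho, "lumpable"))
  expect_gte(as.numeric(rho), 1)
  expect_warning(expectedSubstitutionScale(bias_model(), "KM"),
                 "not lumpable")
})
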