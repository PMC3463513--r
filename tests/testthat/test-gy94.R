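# GY94 rate matrix, pruning likelihood, ML estimation and bootstrap.

test_that("the rate matrix satisfies its structural invariants", {
  set.seed(5)
  pi <- runif(61, 0.5, 2); pi <- pi / sum(pi)
  p <- gy94Params(kappa = 3, omega = 0.3, pi = pi)
  M <- buildGY94Matrix(p)
  expect_lt(max(abs(rowSums(M$Q))), 1e-12)
  expect_equal(-sum(pi * diag(M$Q)), 1, tolerance = 1e-12)  # unit mean flux
  # stationarity: pi Q = 0
  expect_lt(max(abs(pi %*% M$Q)), 1e-10)

  # omega = 0 kills every nonsynonymous entry
  M0 <- buildGY94Matrix(gy94Params(kappa = 2, omega = 0, pi = rep(1/61, 61)))
  aa <- codonAminoAcids()
  nonsyn <- outer(aa, aa, "!=")
  diag(nonsyn) <- FALSE
  expect_true(all(M0$Q[nonsyn] == 0))

  # omega = kappa = 1, uniform pi: detailed balance gives a symmetric matrix
  M1 <- buildGY94Matrix(gy94Params(1, 1, rep(1 / 61, 61)))
  expect_equal(M1$Q, t(M1$Q), tolerance = 1e-12)

  expect_error(gy94Params(pi = rep(1, 61)), "sum")
})

test_that("pruning equals the dense matrix-exponential oracle", {
  set.seed(11)
  pi <- runif(61, 0.5, 2); pi <- pi / sum(pi)
  p <- gy94Params(kappa = 2.5, omega = 0.4, pi = pi)
  tr <- ape::read.tree(text = "(a:0.07,b:0.12);")
  aln <- codonAlignment(c(a = "TTTGAAATTCTG", b = "TTCGACATACTG"))
  expect_equal(treeLogLikelihood(aln, tr, p),
               bruteLogLik2Taxon(aln, tr, p), tolerance = 1e-11)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  s <- simConstAlign(40, 0.3, seed = 2)
  p <- gy94Params(2, 0.3, rep(1 / 61, 61))
  ll <- treeLogLikelihood(s$aln, s$tree, p)
  for (out in c("a", "c", "d")) {
    tr2 <- ape::unroot(ape::root(s$tree, out, resolve.root = TRUE))
    expect_equal(treeLogLikelihood(s$aln, tr2, p), ll, tolerance = 1e-10)
  }
})

test_that("zero branch lengths with identical sequences give sum(log pi)", {
  tr <- yeastTree(bl = rep(0, 5))
  cm <- matrix(rep(c("TTT", "GAA"), each = 4), nrow = 4)
  rownames(cm) <- tr$tip.label
  pi <- rep(1 / 61, 61)
  ll <- treeLogLikelihood(codonAlignment(cm), tr, gy94Params(2, 0.5, pi))
  expect_equal(ll, 2 * log(1 / 61), tolerance = 1e-12)
})

test_that("stop codons and gaps in estimation input are rejected", {
  cm <- matrix(rep(c("TAA", "GAA", "GAA", "GAA")), ncol = 1)
  rownames(cm) <- yeastTree()$tip.label
  expect_error(treeLogLikelihood(codonAlignment(cm), yeastTree(),
                                 gy94Params()), "stop codon")
})

test_that("identical sequences give zero rates and undefined dN/dS", {
  cm <- matrix(rep(c("TTT", "GAA", "CCA"), 4), nrow = 4, byrow = TRUE)
  rownames(cm) <- yeastTree()$tip.label
  expect_warning(est <- estimateRatesML(codonAlignment(cm), yeastTree()),
                 "undefined")
  expect_false(est@defined)
  expect_true(is.na(dNdS(est)))
  expect_equal(est@dn, 0)
  expect_equal(est@ds, 0)
})

test_that("estimates are invariant to column permutation and concatenation", {
  s <- simConstAlign(250, 0.25, seed = 14)
  est <- estimateRatesML(s$aln, s$tree)
  shuf <- codonAlignment(codons(s$aln)[, sample(250)])
  estS <- estimateRatesML(shuf, s$tree)
  expect_equal(dNdS(estS), dNdS(est), tolerance = 1e-6)

  doubled <- codonAlignment(cbind(codons(s$aln), codons(s$aln)))
  estD <- estimateRatesML(doubled, s$tree)
  expect_equal(dNdS(estD), dNdS(est), tolerance = 1e-3)
  expect_equal(estD@nCodons, 2L * est@nCodons)
})

test_that("dN/dS equals dN over dS and kappa is recovered plausibly", {
  s <- simConstAlign(1200, 0.3, kappa = 4, seed = 21)
  est <- estimateRatesML(s$aln, s$tree)
  expect_equal(est@dn / est@ds, dNdS(est), tolerance = 1e-9)
  expect_gt(est@kappa, 2)   # simulated with kappa = 4
  expect_true(est@converged)
})

test_that("bootstrap SEs are seed-reproducible and zero for degenerate data", {
  s <- simConstAlign(150, 0.3, seed = 31)
  est <- estimateRatesML(s$aln, s$tree)
  b1 <- bootstrapSE(s$aln, s$tree, B = 15, seed = 99, pointEstimate = est)
  b2 <- bootstrapSE(s$aln, s$tree, B = 15, seed = 99, pointEstimate = est)
  expect_identical(b1@seDnds, b2@seDnds)
  expect_identical(b1@seDs, b2@seDs)
  expect_gt(b1@seDnds, 0)

  # all columns identical copies of one variable column: resampling can
  # never change the pattern weights, so every replicate is identical
  col <- c("TTT", "TTC", "TTA", "CTT")
  cm <- matrix(rep(col, 30), nrow = 4)
  rownames(cm) <- yeastTree()$tip.label
  aln1 <- codonAlignment(cm)
  estC <- estimateRatesML(aln1, yeastTree())
  bC <- bootstrapSE(aln1, yeastTree(), B = 10, seed = 1, pointEstimate = estC)
  expect_equal(bC@seDnds, 0)
  expect_false(bC@seReliable)   # zero spread is flagged, not trusted

  expect_error(bootstrapSE(s$aln, s$tree, B = 1), "at least 2")
})

test_that("two-taxon ML agrees approximately with the NG86 oracle", {
  tr2 <- ape::read.tree(text = "(a:0.15,b:0.15);")
  set.seed(8)
  sim <- rsaRates:::cpp_simulate_sites(tr2$edge, tr2$edge.length, 2L,
                                       rep(0.3, 800), 2, 1, rep(1/61, 61),
                                       codonPairTable())
  m <- matrix(senseCodons()[sim$tips], nrow = 2)
  rownames(m) <- tr2$tip.label
  est <- estimateRatesML(codonAlignment(m), tr2)
  ng <- ng86Rates(m[1, ], m[2, ])
  expect_lt(abs(dNdS(est) - ng$dnds) / ng$dnds, 0.25)
})
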