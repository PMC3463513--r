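# Synthetic-data generator: determinism, class structure, neutral flux,
# codon bias and synonymous-rate scaling.

test_that("identical seeds reproduce the study bit-for-bit", {
  cfg <- simulationConfig(seed = 77, nProteinsPerCell = 2,
                          residueRange = c(20, 30))
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(lapply(s1$alignments, codons),
                   lapply(s2$alignments, codons))
  expect_identical(s1$groundTruth, s2$groundTruth)
  expect_identical(s1$proteins$expression, s2$proteins$expression)
})

test_that("large-core proteins have lower average RSA by construction", {
  cfg <- simulationConfig(seed = 5, nProteinsPerCell = 30,
                          residueRange = c(60, 80))
  ps <- simulateProteinSet(cfg)
  avg <- vapply(ps$rsa, function(p) mean(p$rsa), numeric(1))
  byCell <- tapply(avg[ps$proteins$protein_id], ps$proteins$core_cell, mean)
  expect_lt(byCell[["largeCore"]], byCell[["smallCore"]])
})

test_that("zero branch lengths copy the root to every taxon", {
  cfg <- simulationConfig(seed = 3, nProteinsPerCell = 1,
                          residueRange = c(25, 25),
                          treeNewick = paste0("((cerevisiae:0,paradoxus:0):0,",
                                              "mikatae:0,bayanus:0);"))
  prof <- data.frame(residue_index = 1:25, residue_type = NA,
                     rsa = runif(25, 0, 100))
  sim <- simulateCodonAlignment(prof, "largeCore", "high", cfg)
  cm <- codons(sim$alignment)
  expect_true(all(cm[1, ] == cm[2, ] & cm[1, ] == cm[3, ] & cm[1, ] == cm[4, ]))
  expect_equal(sum(sim$nSyn) + sum(sim$nNonsyn), 0L)
})

test_that("neutral simulation matches the rate-matrix flux expectation", {
  cfg <- simulationConfig(seed = 8, biasLow = 0, biasHigh = 0,
                          synScaleLow = 1, synScaleHigh = 1)
  prof <- data.frame(residue_index = 1:10000, residue_type = NA,
                     rsa = rep(50, 10000))
  # omega = 1 at RSA 50: intercept + slope*50 = 1 with factor 1
  cfg@intercept <- 1; cfg@slopeSmallCore <- 0; cfg@slopeLargeCore <- 0
  set.seed(99)
  sim <- simulateCodonAlignment(prof, "smallCore", "high", cfg)
  pi <- rep(1 / 61, 61)   # bias 0: uniform families, near-uniform codons
  # expected nonsyn:syn flux ratio from the generator's own bookkeeping
  fl <- rsaRates:::cpp_gy94_flux(cfg@kappa, 1, 1,
                                 rsaRates:::.classCodonFreqs(0),
                                 codonPairTable())
  expRatio <- fl[["fluxN"]] / fl[["fluxS"]]
  nN <- sum(sim$nNonsyn); nS <- sum(sim$nSyn)
  obsRatio <- nN / nS
  # binomial MC error on the ratio via delta method
  pN <- expRatio / (1 + expRatio)
  seRatio <- sqrt(pN * (1 - pN) / (nN + nS)) / (1 - pN)^2
  expect_lt(abs(obsRatio - expRatio), 3 * seRatio)
})

test_that("expression-class codon bias raises CAI under the generator table", {
  cfg <- simulationConfig(seed = 21, nProteinsPerCell = 25,
                          residueRange = c(60, 80))
  study <- simulateStudy(cfg)
  prot <- study$proteins
  hi <- prot$expression[prot$expr_cell == "high"]
  lo <- prot$expression[prot$expr_cell == "low"]
  # pairwise comparisons: high-bias proteins should win almost always
  wins <- mean(outer(hi, lo, ">"))
  expect_gte(wins, 0.95)
})

test_that("the synonymous-rate scale slows the clock but preserves dN/dS", {
  set.seed(12)
  tr <- yeastTree()
  pi <- rsaRates:::.classCodonFreqs(1)
  pairs <- codonPairTable()
  simWith <- function(s) {
    sim <- rsaRates:::cpp_simulate_sites(tr$edge, tr$edge.length, 4L,
                                         rep(0.3, 4000), 2, s, pi, pairs)
    c(syn = sum(sim$nSyn), nonsyn = sum(sim$nNonsyn))
  }
  full <- simWith(1)
  halved <- simWith(0.5)
  # both substitution classes slow down together (uniform clock change)
  expect_lt(halved[["syn"]], 0.6 * full[["syn"]])
  expect_lt(halved[["nonsyn"]], 0.65 * full[["nonsyn"]])
  # the nonsynonymous:synonymous flux ratio (hence dN/dS) is unchanged
  r1 <- full[["nonsyn"]] / full[["syn"]]
  r2 <- halved[["nonsyn"]] / halved[["syn"]]
  expect_lt(abs(r1 - r2) / r1, 0.15)
})

test_that("config invariants are enforced before any sampling", {
  expect_error(simulationConfig(seed = 1, intercept = -2,
                                omegaFloor = -1), "positive")
  expect_error(simulationConfig(seed = 1, residueRange = c(50, 10)),
               "residue range")
  expect_error(validObject(new("SimulationConfig")), "invalid")
})

test_that("a study round-trips through the on-disk input formats", {
  cfg <- simulationConfig(seed = 14, nProteinsPerCell = 2,
                          residueRange = c(15, 20))
  study <- simulateStudy(cfg)
  d <- file.path(tempdir(), "studyRT")
  writeStudy(study, d)
  pid <- study$proteins$protein_id[1]
  aln <- readCodonAlignment(file.path(d, "alignments", paste0(pid, ".fasta")),
                            taxaOrder = taxa(study$alignments[[pid]]))
  expect_identical(codons(aln), codons(study$alignments[[pid]]))
  rsa <- readRsaTsv(file.path(d, "rsa", paste0(pid, ".tsv")))
  expect_equal(rsa$rsa, study$rsa[[pid]]$rsa, tolerance = 1e-8)
  expect_true(file.exists(file.path(d, "config.yaml")))
  unlink(d, recursive = TRUE)
})
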