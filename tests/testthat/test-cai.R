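# Relative adaptiveness and the codon adaptation index.

test_that("relative adaptiveness ratios and pseudo-counts are exact", {
  ref <- paste(c(rep("AAA", 80), rep("AAG", 20)), collapse = "")
  tab <- relativeAdaptiveness(ref)
  expect_equal(tab$w[tab$codon == "AAA"], 1)
  expect_equal(tab$w[tab$codon == "AAG"], 0.25)
  # unobserved codon in an observed family: pseudo-count 0.5 over the max
  ref2 <- paste(rep("GGT", 10), collapse = "")
  tab2 <- relativeAdaptiveness(ref2)
  expect_equal(tab2$w[tab2$codon == "GGA"], 0.5 / 10)
  # family never observed at all: every member gets w = 1
  expect_equal(tab2$w[tab2$codon == "AAA"], 1)
  expect_error(relativeAdaptiveness(character(0)), "empty")
})

test_that("every synonymous family has max w = 1 and exclusions are flagged", {
  set.seed(1)
  ref <- paste(sample(senseCodons(), 3000, replace = TRUE), collapse = "")
  tab <- relativeAdaptiveness(ref)
  for (fam in unique(tab$amino_acid))
    expect_equal(max(tab$w[tab$amino_acid == fam]), 1)
  expect_setequal(tab$codon[tab$excluded], c("ATG", "TGG"))
})

test_that("CAI is the geometric mean over counted codons", {
  tab <- data.frame(codon = c("AAA", "AAG", "ATG"),
                    amino_acid = c("K", "K", "M"),
                    w = c(1, 0.25, 1),
                    excluded = c(FALSE, FALSE, TRUE))
  r <- computeCai(c("AAG", "AAA"), tab)
  expect_equal(r$cai, sqrt(0.25))   # sqrt(0.25 * 1) = 0.5
  expect_equal(r$nCodons, 2L)

  # excluded-only input errors
  expect_error(computeCai(c("ATG", "ATG"), tab), "zero countable")
})

test_that("CAI is order-invariant, monotone in w, and in (0, 1]", {
  set.seed(4)
  ref <- paste(sample(senseCodons(), 2000, replace = TRUE), collapse = "")
  tab <- relativeAdaptiveness(ref)
  cods <- sample(senseCodons(), 60, replace = TRUE)
  c1 <- computeCai(cods, tab)$cai
  c2 <- computeCai(sample(cods), tab)$cai
  expect_equal(c1, c2)
  expect_true(c1 > 0 && c1 <= 1)

  # replacing a codon with its family's preferred synonym cannot lower CAI
  aa <- codonAminoAcids()
  countable <- !tab$excluded
  i <- which(cods %in% tab$codon[countable])[1]
  fam <- aa[match(cods[i], senseCodons())]
  best <- tab$codon[tab$amino_acid == fam][which.max(tab$w[tab$amino_acid == fam])]
  cods2 <- cods; cods2[i] <- best
  expect_gte(computeCai(cods2, tab)$cai, c1)

  # all-preferred input gives exactly 1
  pref <- tab$codon[tab$w == 1 & !tab$excluded]
  expect_equal(computeCai(rep(pref[1:5], 3), tab)$cai, 1)
})
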