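# Residue records, group assignment, RSA binning and concatenation.

test_that("codon columns join to RSA positions with correct gapless flags", {
  cm <- matrix(rep(c("TTT", "GAA", "CCA", "GGT"), each = 10), nrow = 4,
               byrow = TRUE)
  cm[2, 3] <- "---"
  cm[4, 7] <- "NNA"
  rsa <- data.frame(residue_index = 1:10, residue_type = NA, rsa = 1:10 * 9)
  rsa$rsa[5] <- NA   # template gap
  aln <- codonAlignment(cm)
  rec <- mapCodonsToStructure(aln, rsa, "px")
  expect_equal(nrow(rec), 10L)
  expect_false(rec$gapless[3])   # alignment gap
  expect_false(rec$gapless[5])   # missing RSA
  expect_false(rec$gapless[7])   # ambiguity treated as gap
  expect_true(all(rec$gapless[c(1, 2, 4, 6, 8, 9, 10)]))

  badRsa <- rsa[1:8, ]
  expect_error(mapCodonsToStructure(aln, badRsa, "px"), "px")
})

test_that("ranked-fraction grouping produces exact class sizes", {
  prot <- data.frame(protein_id = sprintf("p%02d", 1:9),
                     avg_rsa = c(10, 20, 30, 40, 50, 60, 70, 80, 90),
                     expression = c(5, 3, 8, 1, 9, 2, 7, 4, 6))
  g <- assignGroups(prot, fraction = 1 / 3)
  expect_equal(sum(g$core_class == "largeCore"), 3L)
  expect_equal(sum(g$core_class == "smallCore"), 3L)
  expect_equal(sum(g$core_class == "mid"), 3L)
  # bottom third by avg RSA are the large-core proteins
  expect_setequal(g$protein_id[g$core_class == "largeCore"],
                  c("p01", "p02", "p03"))
  expect_setequal(g$protein_id[g$expr_class == "low"],
                  prot$protein_id[order(prot$expression)][1:3])

  gHalf <- assignGroups(prot[1:8, ], fraction = 0.5)
  expect_equal(sum(gHalf$core_class == "mid"), 0L)

  tied <- transform(prot, expression = 1)
  expect_error(assignGroups(tied), "unrankable")
})

test_that("the two group axes are assigned independently", {
  set.seed(42)
  prot <- data.frame(protein_id = sprintf("p%02d", 1:12),
                     avg_rsa = runif(12, 10, 90),
                     expression = runif(12))
  g1 <- assignGroups(prot)
  prot2 <- transform(prot, expression = sample(expression))
  g2 <- assignGroups(prot2)
  expect_equal(g1$core_class, g2$core_class)
})

test_that("binning uses half-open intervals with a closed last bin", {
  rec <- makeRecords(c(10, 50, 90, 100, 49.999))
  bins <- binResidues(rec, edges = c(0, 50, 100))
  expect_equal(vapply(bins, function(b) nrow(b$records), 0L), c(2L, 3L))
  # 50 goes up, 100 stays in the last (closed) bin
  expect_true(50 %in% bins[[2]]$records$rsa)
  expect_true(100 %in% bins[[2]]$records$rsa)
  expect_equal(bins[[1]]$x, mean(c(10, 49.999)))

  expect_error(binResidues(rec, edges = c(0, 100, 50)), "increase")
  recBad <- rec; recBad$rsa[1] <- 101
  expect_error(binResidues(recBad, edges = c(0, 50, 100)), "outside")
})

test_that("record totals are conserved across any bin edge set", {
  set.seed(3)
  rec <- makeRecords(runif(200, 0, 100))
  for (edges in list(c(0, 50, 100), seq(0, 100, 10), c(0, 33, 66, 100))) {
    bins <- binResidues(rec, edges = edges)
    expect_equal(sum(vapply(bins, function(b) nrow(b$records), 0L)), 200L)
  }
})

test_that("bin concatenation is sorted, deterministic and gap-safe", {
  rec1 <- makeRecords(c(30, 10), proteinId = "pB")
  rec2 <- makeRecords(c(20), proteinId = "pA")
  members <- rbind(rec1, rec2)
  ba <- concatenateBinAlignment(members, bin = 1L, lo = 0, hi = 100, x = 20)
  expect_s4_class(ba, "BinnedAlignment")
  expect_equal(nCodons(ba), 3L)
  expect_equal(ba@proteinIds, c("pA", "pB", "pB"))  # protein-major order

  # shuffling input rows changes nothing
  ba2 <- concatenateBinAlignment(members[c(3, 1, 2), ], 1L, 0, 100, 20)
  expect_identical(codons(ba), codons(ba2))

  gapped <- makeRecords(c(15), codMat = matrix(c("---", "GAA", "GAA", "GAA"),
                                               ncol = 1))
  expect_error(concatenateBinAlignment(rbind(members, gapped)), "gapless")

  empty <- members[0, ]
  baE <- concatenateBinAlignment(empty, 2L, 0, 50, 25)
  expect_equal(nCodons(baE), 0L)
})

test_that("codon alignments round-trip through FASTA", {
  s <- simConstAlign(20, 0.3, seed = 9)
  f <- tempfile(fileext = ".fasta")
  writeCodonAlignment(s$aln, f)
  back <- readCodonAlignment(f, taxaOrder = taxa(s$aln))
  expect_identical(codons(back), codons(s$aln))
  expect_error(readCodonAlignment(f, taxaOrder = c("x", "y", "z", "w")),
               "taxa")
})
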