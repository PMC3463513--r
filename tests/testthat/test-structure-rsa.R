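# Shrake-Rupley SASA, RSA normalisation, and template-to-target transfer.

test_that("SASA of isolated and fully buried atoms matches closed forms", {
  a <- atomSet(element = "C", residueIndex = 1, residueType = "A",
               x = 0, y = 0, z = 0)
  s <- computeSasa(a, probeRadius = 1.4, nPoints = 960)
  expect_equal(s$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)

  # central atom enclosed by an occluding shell of 26 neighbours
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ] * 1.8
  shell <- atomSet(element = rep("S", nrow(g) + 1),
                   residueIndex = c(1, rep(2, nrow(g))),
                   residueType = c("A", rep("G", nrow(g))),
                   x = c(0, g$x), y = c(0, g$y), z = c(0, g$z))
  s2 <- computeSasa(shell)
  expect_equal(s2$sasa[s2$residue_index == 1], 0)
})

test_that("diatomic SASA matches the analytic spherical-cap oracle", {
  d <- 2.5
  a <- atomSet(element = c("C", "N"), residueIndex = 1:2,
               residueType = c("A", "G"), x = c(0, d), y = c(0, 0),
               z = c(0, 0))
  s <- computeSasa(a, probeRadius = 1.4, nPoints = 4000)
  expect_equal(s$sasa[1], capAreaOracle(1.7 + 1.4, 1.55 + 1.4, d),
               tolerance = 0.01)
  expect_equal(s$sasa[2], capAreaOracle(1.55 + 1.4, 1.7 + 1.4, d),
               tolerance = 0.01)
})

test_that("SASA converges as the sphere sampling is refined", {
  set.seed(7)
  n <- 10
  a <- atomSet(element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
               residueIndex = rep(1:5, each = 2),
               residueType = rep(c("A", "L", "K", "F", "D"), each = 2),
               x = runif(n, 0, 6), y = runif(n, 0, 6), z = runif(n, 0, 6))
  s1 <- computeSasa(a, nPoints = 960)
  s2 <- computeSasa(a, nPoints = 1920)
  expect_true(all(abs(s2$sasa - s1$sasa) <=
                    0.02 * pmax(s1$sasa, 1) + 1e-9))
})

test_that("unknown elements and empty structures are rejected", {
  expect_error(atomSet("Zz", 1, "A", 0, 0, 0), "unknown element")
  expect_error(atomSet("H", 1, "A", 0, 0, 0), "no heavy atoms")
})

test_that("RSA normalisation caps outliers at 100 and is scale-free", {
  raw <- data.frame(residue_index = 1:3, residue_type = c("A", "A", "G"),
                    sasa = c(50, 0, 60))
  norm <- c(A = 50, G = 50)
  r <- suppressMessages(normalizeRsa(raw, norm))
  expect_equal(r$rsa, c(100, 0, 100))   # 1.2x the normaliser capped at 100
  expect_equal(attr(r, "nCapped"), 1L)

  # common positive rescaling of raw SASA and normalisers changes nothing
  r2 <- suppressMessages(normalizeRsa(transform(raw, sasa = sasa * 3.7),
                                      norm * 3.7))
  expect_equal(r2$rsa, r$rsa)

  expect_error(normalizeRsa(raw, c(A = 50)), "no normaliser")
  expect_error(normalizeRsa(raw, c(A = 50, G = -1)), "positive")
})

test_that("empirical normalisation takes the 99th percentile per type", {
  prof <- data.frame(residue_type = rep("A", 200), sasa = seq_len(200))
  expect_equal(unname(empiricalNormalization(prof)["A"]),
               unname(quantile(1:200, 0.99)))
})

test_that("RSA transfer follows the alignment map and invents no values", {
  tmpl <- data.frame(residue_index = 1:10, residue_type = rep("A", 10),
                     rsa = seq(5, 95, by = 10))
  idMap <- data.frame(template_index = 1:10, target_index = 1:10)
  out <- transferRsa(tmpl, idMap, 10)
  expect_equal(out$rsa, tmpl$rsa)

  gapMap <- idMap[-3, ]   # one template gap
  out2 <- transferRsa(tmpl, gapMap, 10)
  expect_true(is.na(out2$rsa[3]))
  expect_equal(out2$rsa[-3], tmpl$rsa[-3])

  map70 <- idMap[1:7, ]
  out3 <- transferRsa(tmpl, map70, 10)
  expect_equal(sum(!is.na(out3$rsa)), 7L)
  # the non-missing outputs are a sub-multiset of the inputs
  expect_true(all(out3$rsa[!is.na(out3$rsa)] %in% tmpl$rsa))

  expect_error(transferRsa(tmpl, data.frame(template_index = 99,
                                            target_index = 1), 10),
               "absent")
  expect_error(transferRsa(tmpl, data.frame(template_index = c(1, 1),
                                            target_index = c(1, 2)), 10),
               "injective")
})

test_that("PDB ATOM records are read with hydrogens dropped", {
  pdbLine <- function(serial, name, resn, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, "", resn, "A", resno, "", x, y, z, 1.0, 0.0, elem)
  }
  lines <- c(pdbLine(1, " N", "ALA", 1, 0.0, 0.0, 0.0, "N"),
             pdbLine(2, " CA", "ALA", 1, 1.5, 0.0, 0.0, "C"),
             pdbLine(3, " H", "ALA", 1, 1.0, 1.0, 0.0, "H"),
             pdbLine(4, " N", "GLY", 2, 3.0, 0.5, 0.0, "N"),
             "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  a <- readPdbAtoms(f, chain = "A")
  expect_equal(nrow(a), 3L)          # hydrogen dropped
  expect_equal(a$residue_type, c("A", "A", "G"))
  expect_equal(a$residue_index, c(1L, 1L, 2L))
  s <- computeSasa(a, nPoints = 240)
  expect_equal(nrow(s), 2L)
  unlink(f)
})

test_that("RSA profiles round-trip through TSV with missing markers", {
  prof <- data.frame(residue_index = 1:3, residue_type = c("A", NA, "G"),
                     rsa = c(12.5, NA, 99))
  f <- tempfile(fileext = ".tsv")
  writeRsaTsv(prof, f)
  back <- readRsaTsv(f)
  expect_equal(back$rsa, prof$rsa)
  expect_true(any(grepl("\t\\.", readLines(f))))
})
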