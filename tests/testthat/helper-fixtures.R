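# Shared fixtures: small simulated alignments and residue-record builders.

yeastTree <- function(bl = c(0.08, 0.12, 0.12, 0.18, 0.2)) {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.1,d:0.1);")
  tr$edge.length <- bl
  tr
}

# Simulate a constant-omega 4-taxon alignment with the package's CTMC
# simulator (uniform codon frequencies unless given).
simConstAlign <- function(n, omega, kappa = 2, pi = rep(1 / 61, 61),
                          tree = yeastTree(), synScale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- rsaRates:::cpp_simulate_sites(tree$edge, tree$edge.length,
                                       length(tree$tip.label),
                                       rep(omega, n), kappa, synScale, pi,
                                       codonPairTable())
  m <- matrix(senseCodons()[sim$tips], nrow = length(tree$tip.label))
  rownames(m) <- tree$tip.label
  list(aln = codonAlignment(m), tree = tree, sim = sim)
}

# Residue records for synthetic binning tests: given RSA values and a
# codon matrix (4 x n), builds the record data.frame.
makeRecords <- function(rsa, codMat = NULL, proteinId = "p1",
                        taxa = c("a", "b", "c", "d")) {
  n <- length(rsa)
  if (is.null(codMat)) {
    pool <- c("TTT", "GAA", "CCA", "GGT", "ATT", "CTG")
    codMat <- matrix(sample(pool, 4 * n, replace = TRUE), nrow = 4)
  }
  aln <- codonAlignment(structure(apply(codMat, 1, paste0, collapse = ""),
                                  names = taxa))
  rsaProf <- data.frame(residue_index = seq_len(n),
                        residue_type = NA_character_, rsa = rsa)
  mapCodonsToStructure(aln, rsaProf, proteinId)
}
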