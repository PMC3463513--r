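# Synthetic study generator: proteins with class-specific RSA
# distributions, four-taxon codon alignments evolved under site-specific
# omega linear in RSA with group-specific slope/intercept,
# expression-dependent enrichment for preferred synonymous codons, and
# expression-dependent synonymous-rate reduction. Every residue's ground
# truth is recorded so recovery can be tested at each pipeline stage.

#' Ground-truth configuration for a synthetic study
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: four group-cells (core size x expression), RSA drawn from
#' class-specific Beta distributions (large-core proteins have lower mean
#' RSA, i.e. more buried residues), per-residue omega linear in RSA with a
#' core-size-specific slope, a uniform multiplicative omega factor for low
#' expression, codon-usage bias increasing with expression class, and a
#' synonymous-rate scale below 1 for high expression (uniform synonymous
#' selection).
#'
#' @slot nProteinsPerCell Proteins per group-cell.
#' @slot residueRange Min/max residues per protein (uniform draw).
#' @slot rsaShapesLargeCore,rsaShapesSmallCore Beta shape pairs for the
#'   per-residue RSA distribution (scaled to [0, 100]).
#' @slot intercept Baseline omega at RSA 0 (high-expression cells).
#' @slot slopeSmallCore,slopeLargeCore omega increase per percent RSA.
#' @slot exprOmegaFactor Multiplier applied to both intercept and slope in
#'   low-expression cells (uniform relaxation of constraint).
#' @slot omegaFloor Lower bound on per-site omega.
#' @slot kappa Transition/transversion ratio of the generator.
#' @slot treeNewick Newick tree with branch lengths (substitutions/codon).
#' @slot biasLow,biasHigh Preferred-codon enrichment (weight 1 + bias for
#'   the preferred codon of each synonymous family) per expression class.
#' @slot synScaleLow,synScaleHigh Synonymous-rate scale per expression
#'   class (< 1 models synonymous selection in highly expressed genes).
#' @slot wUnpreferred Relative adaptiveness assigned to unpreferred codons
#'   in the generator's own adaptiveness table.
#' @slot seed Mandatory integer seed.
#' @export
setClass("SimulationConfig", representation(
  nProteinsPerCell = "integer", residueRange = "numeric",
  rsaShapesLargeCore = "numeric", rsaShapesSmallCore = "numeric",
  intercept = "numeric", slopeSmallCore = "numeric",
  slopeLargeCore = "numeric", exprOmegaFactor = "numeric",
  omegaFloor = "numeric", kappa = "numeric", treeNewick = "character",
  biasLow = "numeric", biasHigh = "numeric",
  synScaleLow = "numeric", synScaleHigh = "numeric",
  wUnpreferred = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  scalars <- c("intercept", "slopeSmallCore", "slopeLargeCore",
               "exprOmegaFactor", "omegaFloor", "kappa", "biasLow",
               "biasHigh", "synScaleLow", "synScaleHigh", "wUnpreferred")
  for (s in scalars)
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      return(paste0("invalid or missing scalar slot '", s, "'"))
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a seed is mandatory")
  if (length(object@residueRange) != 2L || length(object@nProteinsPerCell) != 1L)
    return("invalid residue range or protein count")
  for (core in c("small", "large")) for (f in c(1, object@exprOmegaFactor)) {
    m <- if (core == "small") object@slopeSmallCore else object@slopeLargeCore
    om <- pmax(object@omegaFloor, f * (object@intercept + m * c(0, 100)))
    if (any(om <= 0)) return("omega(RSA) must be positive on [0, 100]")
  }
  if (object@synScaleLow <= 0 || object@synScaleHigh <= 0)
    return("synonymous-rate scales must be positive")
  if (object@residueRange[1] > object@residueRange[2] ||
      object@residueRange[1] < 1)
    return("invalid residue range")
  if (object@nProteinsPerCell < 1) return("need at least 1 protein per cell")
  TRUE
})

#' Construct a simulation configuration
#'
#' @param nProteinsPerCell,residueRange,rsaShapesLargeCore,rsaShapesSmallCore
#'   See \linkS4class{SimulationConfig}.
#' @param intercept,slopeSmallCore,slopeLargeCore,exprOmegaFactor,omegaFloor
#'   Ground-truth omega line parameters.
#' @param kappa,treeNewick Generator substitution model.
#' @param biasLow,biasHigh,synScaleLow,synScaleHigh,wUnpreferred
#'   Expression-class codon bias and synonymous-rate parameters.
#' @param seed Integer seed (mandatory).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed,
                             nProteinsPerCell = 50,
                             residueRange = c(120, 180),
                             rsaShapesLargeCore = c(1.2, 2.6),
                             rsaShapesSmallCore = c(2.0, 1.9),
                             intercept = 0.07,
                             slopeSmallCore = 0.0004,
                             slopeLargeCore = 0.0034,
                             exprOmegaFactor = 2.6,
                             omegaFloor = 0.01,
                             kappa = 2,
                             treeNewick = paste0(
                               "((cerevisiae:0.15,paradoxus:0.15):0.08,",
                               "mikatae:0.20,bayanus:0.20);"),
                             biasLow = 0.5, biasHigh = 4,
                             synScaleLow = 1.0, synScaleHigh = 0.6,
                             wUnpreferred = 0.25) {
  new("SimulationConfig",
      nProteinsPerCell = as.integer(nProteinsPerCell),
      residueRange = residueRange,
      rsaShapesLargeCore = rsaShapesLargeCore,
      rsaShapesSmallCore = rsaShapesSmallCore,
      intercept = intercept, slopeSmallCore = slopeSmallCore,
      slopeLargeCore = slopeLargeCore, exprOmegaFactor = exprOmegaFactor,
      omegaFloor = omegaFloor, kappa = kappa, treeNewick = treeNewick,
      biasLow = biasLow, biasHigh = biasHigh,
      synScaleLow = synScaleLow, synScaleHigh = synScaleHigh,
      wUnpreferred = wUnpreferred, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", 4 * object@nProteinsPerCell, "proteins",
      sprintf("(%d per cell), omega = f_e * (%.3g + m_c * RSA), seed %d\n",
              object@nProteinsPerCell, object@intercept, object@seed))
})

# Expression-class codon frequencies: uniform amino-acid usage; within
# each family the preferred codon (the alphabetically first of the family
# -- an arbitrary but fixed convention shared with the generator's
# adaptiveness table) carries weight (1 + bias), others weight 1.
.classCodonFreqs <- function(bias) {
  sc <- senseCodons()
  aa <- codonAminoAcids()
  pref <- !duplicated(aa)  # first codon (alphabetical) of each family
  w <- ifelse(pref, 1 + bias, 1)
  fam <- ave(w, aa, FUN = sum)
  pi <- (w / fam) / length(unique(aa))
  pi / sum(pi)
}

#' The generator's own relative-adaptiveness table
#'
#' Preferred codons (one per synonymous family) have w = 1; all other
#' codons share the configured unpreferred w. Met, Trp and stops excluded.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return Adaptiveness table as in \code{\link{relativeAdaptiveness}}.
#' @export
generatorAdaptiveness <- function(config) {
  sc <- senseCodons()
  aa <- codonAminoAcids()
  pref <- !duplicated(aa)
  single <- aa %in% c("M", "W")
  data.frame(codon = sc, amino_acid = aa,
             w = ifelse(pref | single, 1, config@wUnpreferred),
             excluded = single, stringsAsFactors = FALSE)
}

.cellLine <- function(config, core, expr) {
  m <- if (core == "largeCore") config@slopeLargeCore else config@slopeSmallCore
  f <- if (expr == "low") config@exprOmegaFactor else 1
  c(b = f * config@intercept, m = f * m)
}

#' Simulate protein RSA profiles and group structure
#'
#' Draws, for each of the four group-cells, proteins whose per-residue RSA
#' comes from the cell's core-size Beta distribution. Expression class
#' membership is recorded as ground truth; the observable expression proxy
#' comes later from the simulated sequences' CAI.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List: \code{proteins} (data.frame protein_id, core_cell,
#'   expr_cell, n_residues, seed), \code{rsa} (named list of RSA profile
#'   data.frames).
#' @export
simulateProteinSet <- function(config) {
  validObject(config)
  set.seed(config@seed)
  cells <- expand.grid(core = c("largeCore", "smallCore"),
                       expr = c("low", "high"),
                       stringsAsFactors = FALSE)
  nTot <- nrow(cells) * config@nProteinsPerCell
  protSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
  rows <- vector("list", nTot)
  rsa <- vector("list", nTot)
  id <- 0L
  for (ci in seq_len(nrow(cells))) {
    sh <- if (cells$core[ci] == "largeCore") config@rsaShapesLargeCore
          else config@rsaShapesSmallCore
    for (p in seq_len(config@nProteinsPerCell)) {
      id <- id + 1L
      set.seed(protSeeds[id])
      nres <- sample(seq(config@residueRange[1], config@residueRange[2]), 1L)
      pid <- sprintf("prot%04d", id)
      rows[[id]] <- data.frame(protein_id = pid,
                               core_cell = cells$core[ci],
                               expr_cell = cells$expr[ci],
                               n_residues = nres, seed = protSeeds[id],
                               stringsAsFactors = FALSE)
      rsa[[id]] <- data.frame(residue_index = seq_len(nres),
                              residue_type = NA_character_,
                              rsa = 100 * stats::rbeta(nres, sh[1], sh[2]),
                              stringsAsFactors = FALSE)
      names(rsa)[id] <- pid
    }
  }
  list(proteins = do.call(rbind, rows), rsa = rsa)
}

#' Simulate a codon alignment for one protein
#'
#' Per site, omega = max(floor, b + m * RSA) from the protein's group-cell
#' line; the root codon is drawn from the expression class's biased codon
#' frequencies and evolved along the tree by exact CTMC simulation under
#' the GY94 matrix with that omega, the configured kappa, and synonymous
#' entries scaled by the class's synonymous-rate factor.
#'
#' @param rsaProfile RSA profile data.frame for the protein.
#' @param coreCell "largeCore" or "smallCore".
#' @param exprCell "low" or "high".
#' @param config A \linkS4class{SimulationConfig}.
#' @return List: \code{alignment} (\linkS4class{CodonAlignment}),
#'   \code{truth} (data.frame residue_index, rsa, omega), \code{nSyn},
#'   \code{nNonsyn} (per-site substitution counts).
#' @export
simulateCodonAlignment <- function(rsaProfile, coreCell, exprCell, config) {
  tree <- ape::read.tree(text = config@treeNewick)
  line <- .cellLine(config, coreCell, exprCell)
  omega <- pmax(config@omegaFloor, line["b"] + line["m"] * rsaProfile$rsa)
  bias <- if (exprCell == "low") config@biasLow else config@biasHigh
  synScale <- if (exprCell == "low") config@synScaleLow else config@synScaleHigh
  pi <- .classCodonFreqs(bias)
  sim <- cpp_simulate_sites(tree$edge, tree$edge.length,
                            length(tree$tip.label), omega, config@kappa,
                            synScale, pi, codonPairTable())
  m <- matrix(senseCodons()[sim$tips], nrow = length(tree$tip.label))
  rownames(m) <- tree$tip.label
  aln <- codonAlignment(m)
  truth <- data.frame(residue_index = rsaProfile$residue_index,
                      rsa = rsaProfile$rsa, omega = as.numeric(omega),
                      stringsAsFactors = FALSE)
  list(alignment = aln, truth = truth,
       nSyn = sim$nSyn, nNonsyn = sim$nNonsyn)
}

#' Simulate a complete synthetic study
#'
#' Runs \code{\link{simulateProteinSet}} and, per protein (with a
#' deterministic per-protein RNG substream), \code{\link{simulateCodonAlignment}};
#' computes the observable expression proxy as the CAI of the first-taxon
#' sequence under the generator's own adaptiveness table.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List: \code{proteins} (ground-truth table with the CAI proxy
#'   column \code{expression}), \code{rsa}, \code{alignments} (named
#'   lists), \code{groundTruth} (per-residue records: protein_id,
#'   residue_index, rsa, omega, core_cell, expr_cell), \code{adaptiveness},
#'   \code{tree}, \code{config}.
#' @export
simulateStudy <- function(config) {
  ps <- simulateProteinSet(config)
  tab <- generatorAdaptiveness(config)
  tree <- ape::read.tree(text = config@treeNewick)
  alignments <- vector("list", nrow(ps$proteins))
  names(alignments) <- ps$proteins$protein_id
  gt <- vector("list", nrow(ps$proteins))
  cai <- numeric(nrow(ps$proteins))
  for (i in seq_len(nrow(ps$proteins))) {
    pr <- ps$proteins[i, ]
    set.seed(pr$seed + 1L)
    sim <- simulateCodonAlignment(ps$rsa[[pr$protein_id]], pr$core_cell,
                                  pr$expr_cell, config)
    alignments[[pr$protein_id]] <- sim$alignment
    # annotate residue types from the focal-taxon translation
    aaseq <- .translateCodons(codons(sim$alignment)[1L, ])
    ps$rsa[[pr$protein_id]]$residue_type <- aaseq
    gt[[i]] <- cbind(protein_id = pr$protein_id, sim$truth,
                     core_cell = pr$core_cell, expr_cell = pr$expr_cell,
                     stringsAsFactors = FALSE)
    cai[i] <- computeCai(codons(sim$alignment)[1L, ], tab)$cai
  }
  proteins <- ps$proteins
  proteins$expression <- cai
  list(proteins = proteins, rsa = ps$rsa, alignments = alignments,
       groundTruth = do.call(rbind, gt), adaptiveness = tab,
       tree = tree, config = config)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Per-protein FASTA codon alignments and RSA TSVs, an expression-proxy
#' TSV, the ground-truth records TSV, the generator adaptiveness table,
#' and the configuration as YAML.
#'
#' @param study Result of \code{\link{simulateStudy}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  alnDir <- file.path(dir, "alignments")
  rsaDir <- file.path(dir, "rsa")
  dir.create(alnDir, showWarnings = FALSE)
  dir.create(rsaDir, showWarnings = FALSE)
  for (pid in names(study$alignments)) {
    writeCodonAlignment(study$alignments[[pid]],
                        file.path(alnDir, paste0(pid, ".fasta")))
    writeRsaTsv(study$rsa[[pid]], file.path(rsaDir, paste0(pid, ".tsv")))
  }
  utils::write.table(study$proteins[, c("protein_id", "expression")],
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$groundTruth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeAdaptivenessTsv(study$adaptiveness, file.path(dir, "adaptiveness.tsv"))
  cfg <- study$config
  yaml::write_yaml(list(
    nProteinsPerCell = cfg@nProteinsPerCell,
    residueRange = cfg@residueRange,
    rsaShapesLargeCore = cfg@rsaShapesLargeCore,
    rsaShapesSmallCore = cfg@rsaShapesSmallCore,
    intercept = cfg@intercept, slopeSmallCore = cfg@slopeSmallCore,
    slopeLargeCore = cfg@slopeLargeCore,
    exprOmegaFactor = cfg@exprOmegaFactor, omegaFloor = cfg@omegaFloor,
    kappa = cfg@kappa, treeNewick = cfg@treeNewick,
    biasLow = cfg@biasLow, biasHigh = cfg@biasHigh,
    synScaleLow = cfg@synScaleLow, synScaleHigh = cfg@synScaleHigh,
    wUnpreferred = cfg@wUnpreferred, seed = cfg@seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
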