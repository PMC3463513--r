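# Solvent-accessible surface area and relative solvent accessibility:
# Shrake-Rupley sphere sampling over heavy atoms, per-residue-type
# normalisation to the 99th percentile, and RSA transfer from a template
# structure to a target protein through a residue alignment map.

# Bondi (1964) van der Waals radii in Angstrom, by element symbol.
.vdwRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)

#' Van der Waals radius lookup
#'
#' @param elements Character vector of element symbols.
#' @return Numeric radii in Angstrom (Bondi 1964 table).
#' @export
vdwRadius <- function(elements) {
  r <- .vdwRadii[toupper(elements)]
  if (anyNA(r))
    stop("unknown element radius for: ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Build an atom set from coordinates
#'
#' @param element Element symbols (hydrogens are dropped).
#' @param residueIndex 1-based residue index per atom (non-decreasing).
#' @param residueType One-letter amino acid code per atom.
#' @param x,y,z Coordinates in Angstrom.
#' @param radius Optional explicit van der Waals radii; looked up from the
#'   element otherwise.
#' @return A data.frame of class \code{atomSet} with one row per heavy atom.
#' @export
atomSet <- function(element, residueIndex, residueType, x, y, z,
                    radius = NULL) {
  keep <- toupper(element) != "H"
  if (is.null(radius)) radius <- vdwRadius(element[keep])
  else radius <- radius[keep]
  if (any(radius <= 0)) stop("van der Waals radii must be positive")
  df <- data.frame(element = toupper(element[keep]),
                   residue_index = as.integer(residueIndex[keep]),
                   residue_type = residueType[keep],
                   x = x[keep], y = y[keep], z = z[keep],
                   radius = radius, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty structure: no heavy atoms")
  class(df) <- c("atomSet", "data.frame")
  df
}

#' Read heavy atoms of one chain from a PDB file
#'
#' Reads ATOM records (via \pkg{bio3d}), keeps one chain, drops hydrogens
#' and alternate locations, and maps 3-letter residue names to one-letter
#' codes.
#'
#' @param file Path to a PDB file.
#' @param chain Chain identifier; default is the first chain present.
#' @return An \code{atomSet} data.frame.
#' @export
readPdbAtoms <- function(file, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, ]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1L, 1L)
  aa1 <- bio3d::aa321(at$resid)
  atomSet(element = elem, residueIndex = at$resno, residueType = aa1,
          x = at$x, y = at$y, z = at$z)
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), as used by Shrake-Rupley implementations.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure by sampling deterministic points
#' on each atom's expanded sphere and counting the points not occluded by
#' any neighbouring atom's expanded sphere; per-atom accessible areas are
#' summed into per-residue totals.
#'
#' @param structure An \code{atomSet} (hydrogens already excluded).
#' @param probeRadius Probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param nPoints Sphere sample points per atom (default 960).
#' @return A data.frame (\code{residue_index}, \code{residue_type},
#'   \code{sasa}) with raw SASA in square Angstrom.
#' @export
computeSasa <- function(structure, probeRadius = 1.4, nPoints = 960) {
  stopifnot(inherits(structure, "atomSet"))
  if (nrow(structure) == 0L) stop("empty structure")
  if (probeRadius <= 0) stop("probe radius must be positive")
  pts <- .spherePoints(nPoints)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  rExp <- structure$radius + probeRadius
  n <- nrow(xyz)
  atomArea <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rExp + rExp[i])^2 & seq_len(n) != i)
    p <- pts * rExp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      d2j <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & (d2j >= rExp[j]^2)
      if (!any(acc)) break
    }
    atomArea[i] <- 4 * pi * rExp[i]^2 * sum(acc) / nPoints
  }
  agg <- rowsum(atomArea, structure$residue_index)
  ridx <- as.integer(rownames(agg))
  rtype <- structure$residue_type[match(ridx, structure$residue_index)]
  data.frame(residue_index = ridx, residue_type = rtype,
             sasa = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Empirical per-residue-type SASA normalisation table
#'
#' The 99th percentile of raw SASA within each residue type over a
#' reference set of SASA profiles; used as the denominator when converting
#' raw SASA to relative solvent accessibility.
#'
#' @param profiles A SASA profile data.frame or a list of them
#'   (\code{residue_type}, \code{sasa}).
#' @param probs Percentile used as normaliser (default 0.99).
#' @return Named numeric vector: residue type to normalising SASA.
#' @export
empiricalNormalization <- function(profiles, probs = 0.99) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  all <- do.call(rbind, lapply(profiles, function(p)
    p[, c("residue_type", "sasa")]))
  out <- tapply(all$sasa, all$residue_type,
                stats::quantile, probs = probs, names = FALSE)
  out <- unlist(out)
  if (any(out <= 0))
    stop("non-positive normaliser for residue type(s): ",
         paste(names(out)[out <= 0], collapse = ", "))
  out
}

#' Normalise raw SASA to relative solvent accessibility
#'
#' RSA = 100 * sasa / normaliser for the residue's type, capped at 100
#' (values above the normaliser are outliers set to exactly 100).
#'
#' @param raw SASA profile data.frame (\code{residue_index},
#'   \code{residue_type}, \code{sasa}).
#' @param norm Named numeric vector mapping residue type to its normalising
#'   SASA (e.g. from \code{\link{empiricalNormalization}}).
#' @return An RSA profile data.frame (\code{residue_index},
#'   \code{residue_type}, \code{rsa} in [0, 100]); the number of capped
#'   residues is attached as attribute \code{nCapped}.
#' @export
normalizeRsa <- function(raw, norm) {
  miss <- setdiff(unique(raw$residue_type), names(norm))
  if (length(miss))
    stop("no normaliser for residue type(s): ", paste(miss, collapse = ", "))
  den <- norm[raw$residue_type]
  if (any(den <= 0)) stop("normalisers must be positive")
  rsa <- 100 * raw$sasa / as.numeric(den)
  nCapped <- sum(rsa > 100)
  if (nCapped > 0)
    message(nCapped, " residue(s) exceeded the normaliser; capped at 100% RSA")
  rsa <- pmin(rsa, 100)
  out <- data.frame(residue_index = raw$residue_index,
                    residue_type = raw$residue_type,
                    rsa = rsa, stringsAsFactors = FALSE)
  attr(out, "nCapped") <- nCapped
  out
}

#' Transfer RSA from a template structure to a target protein
#'
#' Mapped target residues inherit the template residue's RSA (site-specific
#' RSA depends mostly on backbone conformation, so it is conserved between
#' close homologs); unmapped (gapped) target positions are marked missing
#' (NA) and excluded downstream.
#'
#' @param templateRsa RSA profile data.frame of the template.
#' @param residueMap data.frame with columns \code{template_index},
#'   \code{target_index} (1-based, injective).
#' @param targetLength Number of residues in the target protein.
#' @return RSA profile data.frame on the target with NA for unmapped
#'   positions.
#' @export
transferRsa <- function(templateRsa, residueMap, targetLength) {
  stopifnot(all(c("template_index", "target_index") %in% names(residueMap)))
  if (anyDuplicated(residueMap$template_index) ||
      anyDuplicated(residueMap$target_index))
    stop("residue map must be injective on both sides")
  pos <- match(residueMap$template_index, templateRsa$residue_index)
  if (anyNA(pos))
    stop("map references template position(s) absent from the template RSA ",
         "profile: ",
         paste(residueMap$template_index[is.na(pos)], collapse = ", "))
  if (any(residueMap$target_index < 1 |
          residueMap$target_index > targetLength))
    stop("target indices outside 1..targetLength")
  rsa <- rep(NA_real_, targetLength)
  type <- rep(NA_character_, targetLength)
  rsa[residueMap$target_index] <- templateRsa$rsa[pos]
  type[residueMap$target_index] <- templateRsa$residue_type[pos]
  data.frame(residue_index = seq_len(targetLength), residue_type = type,
             rsa = rsa, stringsAsFactors = FALSE)
}

#' Read or write RSA/SASA profiles as TSV
#'
#' Columns \code{residue_index}, \code{residue_type}, \code{value}; missing
#' values written as ".".
#'
#' @param profile Profile data.frame (third column is the value column).
#' @param file Path.
#' @return \code{readRsaTsv} returns the profile data.frame.
#' @export
writeRsaTsv <- function(profile, file) {
  out <- profile
  val <- names(out)[3]
  out[[val]] <- ifelse(is.na(out[[val]]), ".", format(out[[val]], digits = 10))
  out$residue_type[is.na(out$residue_type)] <- "."
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeRsaTsv
#' @param valueName Name for the value column on read (default "rsa").
#' @export
readRsaTsv <- function(file, valueName = "rsa") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = ".")
  names(df)[3] <- valueName
  df[[valueName]] <- as.numeric(df[[valueName]])
  df
}

#' Read or write a template-to-target residue alignment map
#'
#' @param file Path to a TSV with columns \code{template_index},
#'   \code{target_index}.
#' @return data.frame with the two index columns.
#' @export
readResidueMap <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  stopifnot(all(c("template_index", "target_index") %in% names(df)))
  df
}
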