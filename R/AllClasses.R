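#' @import methods
NULL

#' Goldman-Yang codon model parameters
#'
#' Holds the single-ratio (one omega for the whole tree) parameterisation:
#' kappa (transition/transversion rate ratio), omega (dN/dS), and the
#' stationary codon frequencies over the 61 sense codons. The instantaneous
#' rate matrix built from these is scaled to one expected substitution per
#' codon per unit branch length.
#'
#' @slot kappa Transition/transversion rate ratio (>= 0).
#' @slot omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @slot pi Numeric vector of 61 sense-codon frequencies summing to 1.
#' @export
setClass("GY94Params", representation(
  kappa = "numeric", omega = "numeric", pi = "numeric"
))

setValidity("GY94Params", function(object) {
  if (length(object@kappa) != 1L || object@kappa < 0)
    return("kappa must be a single non-negative number")
  if (length(object@omega) != 1L || object@omega < 0)
    return("omega must be a single non-negative number")
  if (length(object@pi) != length(senseCodons()))
    return("pi must have one entry per sense codon")
  if (any(object@pi <= 0)) return("pi must be strictly positive")
  if (abs(sum(object@pi) - 1) > 1e-8) return("pi must sum to 1")
  TRUE
})

#' Construct GY94 model parameters
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS rate ratio.
#' @param pi Sense-codon frequencies (length 61, positive, sum 1); default
#'   uniform.
#' @return A \linkS4class{GY94Params} object.
#' @export
gy94Params <- function(kappa = 2, omega = 0.2,
                       pi = rep(1 / length(senseCodons()), length(senseCodons()))) {
  new("GY94Params", kappa = kappa, omega = omega, pi = as.numeric(pi))
}

#' Multi-taxon in-frame codon alignment
#'
#' A character matrix of codon triplets (rows = taxa, columns = codon sites)
#' with taxon labels. Gaps are "---"; ambiguity characters are allowed and
#' treated as gaps downstream.
#'
#' @slot taxa Character vector of taxon labels (rownames of \code{codons}).
#' @slot codons Character matrix, one 3-letter codon string per cell.
#' @export
setClass("CodonAlignment", representation(
  taxa = "character", codons = "matrix"
))

setValidity("CodonAlignment", function(object) {
  if (nrow(object@codons) != length(object@taxa))
    return("codons must have one row per taxon")
  if (length(object@taxa) && ncol(object@codons) > 0 &&
      !all(nchar(object@codons) == 3L))
    return("all codon entries must be 3 characters")
  if (anyDuplicated(object@taxa)) return("taxon labels must be unique")
  TRUE
})

#' Construct a codon alignment
#'
#' @param sequences Named character vector of equal-length nucleotide
#'   sequences (names = taxa), or a character matrix of codons.
#' @return A \linkS4class{CodonAlignment}.
#' @export
codonAlignment <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- sequences
    taxa <- rownames(m)
    if (is.null(taxa)) taxa <- paste0("taxon", seq_len(nrow(m)))
  } else {
    if (is.null(names(sequences)))
      stop("sequences must be named by taxon")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have equal length")
    if (lens[1] %% 3L != 0L)
      stop("sequence length must be divisible by 3")
    n <- lens[1] %/% 3L
    m <- t(vapply(sequences, function(s) {
      substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    }, character(n)))
    if (n == 1L) m <- matrix(m, ncol = 1L, dimnames = list(names(sequences), NULL))
    taxa <- names(sequences)
  }
  m <- toupper(m)
  rownames(m) <- taxa
  new("CodonAlignment", taxa = taxa, codons = m)
}

#' An RSA bin's concatenated gapless codon columns
#'
#' @slot binIndex Integer bin index.
#' @slot lo,hi RSA interval bounds in percent (half-open, last bin closed).
#' @slot xRsa Representative x-value (percent) for regression.
#' @slot taxa Taxon labels (fixed order across bins).
#' @slot codons Character matrix of gapless sense codons (taxa x columns).
#' @slot proteinIds Contributing protein ID per column.
#' @export
setClass("BinnedAlignment", representation(
  binIndex = "integer", lo = "numeric", hi = "numeric", xRsa = "numeric",
  taxa = "character", codons = "matrix", proteinIds = "character"
))

setValidity("BinnedAlignment", function(object) {
  if (ncol(object@codons) != length(object@proteinIds))
    return("one protein ID per codon column required")
  if (nrow(object@codons) != length(object@taxa))
    return("one codon row per taxon required")
  if (ncol(object@codons) > 0) {
    idx <- .codonIndex(object@codons)
    if (anyNA(idx))
      return("all codon columns must be gapless sense codons")
  }
  TRUE
})

#' Maximum-likelihood rate estimates for one concatenated alignment
#'
#' dN/dS (omega), dN and dS summed over the tree, with bootstrap standard
#' errors. \code{defined} is FALSE when there is no synonymous variation
#' (dS ~ 0) and dN/dS is therefore reported as NA.
#'
#' @slot dnds,dn,ds Point estimates.
#' @slot seDnds,seDn,seDs Bootstrap standard errors (NA before bootstrapping).
#' @slot nCodons Number of codon columns.
#' @slot logLik Maximised log-likelihood.
#' @slot kappa MLE of the transition/transversion ratio.
#' @slot treeLength Summed branch lengths (expected substitutions/codon).
#' @slot converged Optimiser convergence flag.
#' @slot defined TRUE when dN/dS is defined (dS > 0).
#' @slot nBootUndefined Count of bootstrap replicates with undefined dN/dS.
#' @slot seReliable FALSE when > 50\% of bootstrap replicates were undefined.
#' @export
setClass("RateEstimate", representation(
  dnds = "numeric", dn = "numeric", ds = "numeric",
  seDnds = "numeric", seDn = "numeric", seDs = "numeric",
  nCodons = "integer", logLik = "numeric", kappa = "numeric",
  treeLength = "numeric", converged = "logical", defined = "logical",
  nBootUndefined = "integer", seReliable = "logical"
))

#' Error-weighted straight-line fit
#'
#' @slot slope,intercept Fitted parameters (slope per percent RSA).
#' @slot seSlope,seIntercept Standard errors from the weighted normal
#'   equations.
#' @slot n Number of points.
#' @slot chisq Weighted residual sum of squares.
#' @export
setClass("LineFit", representation(
  slope = "numeric", intercept = "numeric",
  seSlope = "numeric", seIntercept = "numeric",
  n = "integer", chisq = "numeric"
))

setValidity("LineFit", function(object) {
  if (object@n < 3L) return("a line fit needs at least 3 points")
  if (!(object@seSlope > 0) || !(object@seIntercept > 0))
    return("standard errors must be positive")
  TRUE
})

# ---- generics ----------------------------------------------------------

#' @rdname accessors
#' @param x An object.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))
#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname accessors
#' @export
setGeneric("dNdS", function(x) standardGeneric("dNdS"))
#' @rdname accessors
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))
#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' Accessors for rsaRates objects
#'
#' \code{taxa} returns taxon labels, \code{nCodons} the number of codon
#' columns, \code{codons} the codon character matrix, \code{dnds} the point
#' estimate, \code{slope}/\code{intercept} the fitted line parameters.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("taxa", "CodonAlignment", function(x) x@taxa)
#' @rdname accessors
setMethod("taxa", "BinnedAlignment", function(x) x@taxa)
#' @rdname accessors
setMethod("nCodons", "CodonAlignment", function(x) ncol(x@codons))
#' @rdname accessors
setMethod("nCodons", "BinnedAlignment", function(x) ncol(x@codons))
#' @rdname accessors
setMethod("nCodons", "RateEstimate", function(x) x@nCodons)
#' @rdname accessors
setMethod("codons", "CodonAlignment", function(x) x@codons)
#' @rdname accessors
setMethod("codons", "BinnedAlignment", function(x) x@codons)
#' @rdname accessors
setMethod("dNdS", "RateEstimate", function(x) x@dnds)
#' @rdname accessors
setMethod("slope", "LineFit", function(x) x@slope)
#' @rdname accessors
setMethod("intercept", "LineFit", function(x) x@intercept)

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@taxa), "taxa x",
      ncol(object@codons), "codons\n")
  cat("  taxa:", paste(object@taxa, collapse = ", "), "\n")
})

setMethod("show", "BinnedAlignment", function(object) {
  cat(sprintf("BinnedAlignment: bin %d [%g, %g%%%s, x = %.2f, %d codons, %d proteins\n",
              object@binIndex, object@lo, object@hi,
              if (object@hi >= 100) "]" else ")",
              object@xRsa, ncol(object@codons),
              length(unique(object@proteinIds))))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate (%d codons): dN/dS = %s +/- %s, dN = %.4g, dS = %.4g\n",
              object@nCodons,
              if (object@defined) sprintf("%.4g", object@dnds) else "undefined",
              if (is.na(object@seDnds)) "NA" else sprintf("%.3g", object@seDnds),
              object@dn, object@ds))
})

setMethod("show", "LineFit", function(object) {
  cat(sprintf("LineFit: y = %.4g + %.4g x  (se_b = %.3g, se_m = %.3g, n = %d, chi2 = %.3g)\n",
              object@intercept, object@slope, object@seIntercept,
              object@seSlope, object@n, object@chisq))
})
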