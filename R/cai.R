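# Codon adaptation index: Sharp-Li relative adaptiveness from a reference
# set, and the geometric-mean CAI of coding sequences or binned codon
# multisets. Following the codonw convention, methionine, tryptophan and
# stop codons are excluded from the geometric mean.

.excludedCodons <- function() {
  aa <- codonAminoAcids()
  senseCodons()[aa %in% c("M", "W")]
}

#' Relative adaptiveness of each codon from reference sequences
#'
#' w(codon) = count(codon) / count(most frequent synonym in its family),
#' computed over a reference set of (ideally highly expressed) coding
#' sequences. Codons never observed receive a pseudo-count of 0.5.
#'
#' @param referenceSequences Character vector of in-frame coding sequences
#'   (nucleotide strings), or a character vector of codons.
#' @param referenceId Identifier stored with the table.
#' @return data.frame (\code{codon}, \code{amino_acid}, \code{w},
#'   \code{excluded}) with attribute \code{referenceId}; single-codon
#'   families (Met, Trp) and stop codons are flagged excluded.
#' @export
relativeAdaptiveness <- function(referenceSequences,
                                 referenceId = "reference") {
  if (length(referenceSequences) == 0L) stop("empty reference set")
  toCod <- function(s) {
    if (nchar(s) %% 3L != 0L)
      stop("reference sequence length must be divisible by 3")
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  cods <- toupper(unlist(lapply(referenceSequences, toCod)))
  sc <- senseCodons()
  aa <- codonAminoAcids()
  cnt <- table(factor(cods[cods %in% sc], levels = sc))
  cnt <- pmax(as.numeric(cnt), 0.5)   # pseudo-count for unobserved codons
  w <- numeric(length(sc))
  for (fam in unique(aa)) {
    idx <- which(aa == fam)
    w[idx] <- cnt[idx] / max(cnt[idx])
  }
  out <- data.frame(codon = sc, amino_acid = aa, w = w,
                    excluded = sc %in% .excludedCodons(),
                    stringsAsFactors = FALSE)
  attr(out, "referenceId") <- referenceId
  out
}

#' Codon adaptation index of a codon multiset
#'
#' Geometric mean of relative adaptiveness over counted codons; codons of
#' excluded families (Met, Trp) and stop codons are skipped. CAI depends
#' only on the codon multiset, not on order.
#'
#' @param codons Character vector of codons, a nucleotide string, or a
#'   \linkS4class{BinnedAlignment} (in which case the focal first-taxon
#'   codons are used).
#' @param table Adaptiveness table from \code{\link{relativeAdaptiveness}}.
#' @return List with \code{cai} and \code{nCodons} (codons counted).
#' @export
computeCai <- function(codons, table) {
  if (is(codons, "BinnedAlignment"))
    codons <- codons(codons)[1L, ]
  if (length(codons) == 1L && nchar(codons) > 3L)
    codons <- substring(codons, seq(1, nchar(codons), 3),
                        seq(3, nchar(codons), 3))
  codons <- toupper(codons)
  idx <- match(codons, table$codon)
  idx <- idx[!is.na(idx)]
  idx <- idx[!table$excluded[idx]]
  if (length(idx) == 0L) stop("zero countable codons for CAI")
  list(cai = exp(mean(log(table$w[idx]))), nCodons = length(idx))
}

#' Bootstrap standard error of per-bin CAI
#'
#' Resamples the bin's codon columns with replacement and recomputes CAI,
#' mirroring the codon-column bootstrap used for the rate estimates.
#'
#' @param binned A \linkS4class{BinnedAlignment}.
#' @param table Adaptiveness table.
#' @param B Number of replicates.
#' @param seed Optional seed.
#' @return List with \code{cai}, \code{se}, \code{nCodons}.
#' @export
caiWithSE <- function(binned, table, B = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  foc <- codons(binned)[1L, ]
  pt <- computeCai(foc, table)
  n <- length(foc)
  reps <- vapply(seq_len(B), function(b) {
    cs <- foc[sample.int(n, n, replace = TRUE)]
    out <- try(computeCai(cs, table)$cai, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, numeric(1))
  list(cai = pt$cai, se = stats::sd(reps, na.rm = TRUE),
       nCodons = pt$nCodons)
}

#' Write an adaptiveness table as TSV
#'
#' @param table Adaptiveness table.
#' @param file Path.
#' @export
writeAdaptivenessTsv <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
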