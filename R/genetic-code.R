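# Genetic-code bookkeeping shared by the GY94 machinery, the Nei-Gojobori
# oracle, the CAI module and the simulator. Standard nuclear code throughout;
# the 61 sense codons are kept in alphabetical (A<C<G<T) order.

.pkgEnv <- new.env(parent = emptyenv())

.nucs <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in alphabetical order.
#' @export
senseCodons <- function() {
  if (is.null(.pkgEnv$sense)) {
    all64 <- apply(expand.grid(.nucs, .nucs, .nucs)[, 3:1], 1L,
                   paste0, collapse = "")
    all64 <- sort(all64)
    code <- Biostrings::GENETIC_CODE
    .pkgEnv$sense <- all64[code[all64] != "*"]
    .pkgEnv$aa <- unname(code[.pkgEnv$sense])
  }
  .pkgEnv$sense
}

#' Amino acids encoded by the sense codons
#'
#' @return Character vector of one-letter amino acid codes, parallel to
#'   \code{senseCodons()}.
#' @export
codonAminoAcids <- function() {
  senseCodons()
  .pkgEnv$aa
}

# Translate a codon string vector to one-letter amino acids ("*" for stops,
# NA for anything containing non-ACGT characters).
.translateCodons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  out <- unname(code[codons])
  out
}

.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Single-nucleotide-change sense-codon pairs
#'
#' Unordered pairs of sense codons one nucleotide apart, with their
#' transition/transversion and synonymous/nonsynonymous classification.
#' Changes through stop codons do not appear because both endpoints must be
#' sense codons.
#'
#' @return Integer matrix with columns \code{i}, \code{j} (1-based indices
#'   into \code{senseCodons()}, i < j), \code{ts}, \code{syn} (0/1 flags).
#' @export
codonPairTable <- function() {
  if (is.null(.pkgEnv$pairs)) {
    cod <- senseCodons()
    aa <- codonAminoAcids()
    n <- length(cod)
    mat <- do.call(rbind, strsplit(cod, ""))
    rows <- vector("list", 600L)
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        diffs <- which(mat[i, ] != mat[j, ])
        if (length(diffs) == 1L) {
          k <- k + 1L
          rows[[k]] <- c(i, j,
                         as.integer(.isTransition(mat[i, diffs], mat[j, diffs])),
                         as.integer(aa[i] == aa[j]))
        }
      }
    }
    pairs <- do.call(rbind, rows[seq_len(k)])
    colnames(pairs) <- c("i", "j", "ts", "syn")
    storage.mode(pairs) <- "integer"
    .pkgEnv$pairs <- pairs
  }
  .pkgEnv$pairs
}

# Map codon strings to 1-based indices into senseCodons(); NA for gaps,
# ambiguity characters, or stop codons.
.codonIndex <- function(codons) {
  match(codons, senseCodons())
}
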