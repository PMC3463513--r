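# Joining RSA annotations with codon alignments into residue records,
# ranked-fraction group assignment, RSA binning, and per-bin concatenation
# of gapless codon columns.

#' Read a per-protein codon alignment from FASTA
#'
#' Multi-FASTA of equal-length aligned nucleotide sequences, one record per
#' taxon; '-' marks gaps. Taxon order is taken from \code{taxaOrder} when
#' given, otherwise from file order.
#'
#' @param file FASTA path.
#' @param taxaOrder Optional character vector fixing the row order.
#' @return A \linkS4class{CodonAlignment}.
#' @export
readCodonAlignment <- function(file, taxaOrder = NULL) {
  seqs <- Biostrings::readDNAStringSet(file)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(taxaOrder)) {
    if (!setequal(names(v), taxaOrder))
      stop("FASTA taxa do not match the configured taxon list in ", file)
    v <- v[taxaOrder]
  }
  codonAlignment(v)
}

#' Write a codon alignment as FASTA
#'
#' @param alignment A \linkS4class{CodonAlignment}.
#' @param file Output path.
#' @export
writeCodonAlignment <- function(alignment, file) {
  seqs <- apply(codons(alignment), 1L, paste0, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, taxa(alignment))), file)
  invisible(file)
}

# A codon is usable when it consists only of A/C/G/T and is a sense codon;
# gaps and ambiguity characters (N, X, ...) are treated as gaps.
.usableCodon <- function(codons) !is.na(.codonIndex(codons))

#' Join a codon alignment with an RSA profile into residue records
#'
#' One record per target residue position, carrying the RSA value and the
#' aligned codon column across taxa. The gapless flag is TRUE only when no
#' taxon has a gap, ambiguity character or stop codon in the column and the
#' RSA value is non-missing; only gapless records enter rate estimation.
#'
#' @param alignment \linkS4class{CodonAlignment} whose columns correspond
#'   1:1 to target residue positions.
#' @param rsa RSA profile data.frame on the target (NA = missing).
#' @param proteinId Protein identifier attached to every record.
#' @return data.frame with columns \code{protein_id},
#'   \code{residue_index}, \code{rsa}, \code{gapless}, and one
#'   \code{codon.<taxon>} column per taxon.
#' @export
mapCodonsToStructure <- function(alignment, rsa, proteinId) {
  n <- nCodons(alignment)
  if (n != nrow(rsa))
    stop("protein ", proteinId, ": alignment has ", n,
         " codons but the RSA profile has ", nrow(rsa), " residues")
  cm <- codons(alignment)
  usable <- apply(matrix(.usableCodon(cm), nrow = nrow(cm)), 2L, all)
  rec <- data.frame(protein_id = proteinId,
                    residue_index = rsa$residue_index,
                    rsa = rsa$rsa,
                    gapless = usable & !is.na(rsa$rsa),
                    stringsAsFactors = FALSE)
  for (t in taxa(alignment)) rec[[paste0("codon.", t)]] <- cm[t, ]
  rec
}

#' Assign proteins to core-size and expression groups by ranked fractions
#'
#' Proteins are ranked by average RSA (ascending): the bottom
#' \code{floor(fraction * N)} become large-core (small average RSA, large
#' buried core), the top the small-core group. Independently, proteins are
#' ranked by the expression proxy: bottom = low expression, top = high.
#' Ties are broken by protein ID for determinism.
#'
#' @param proteins data.frame with \code{protein_id}, \code{avg_rsa},
#'   \code{expression}.
#' @param fraction Quantile fraction in (0, 0.5]; 1/3 reproduces tertile
#'   grouping, 0.5 splits in halves (empty mid class).
#' @return The input with added factor columns \code{core_class}
#'   (\code{largeCore}/\code{mid}/\code{smallCore}) and \code{expr_class}
#'   (\code{low}/\code{mid}/\code{high}).
#' @export
assignGroups <- function(proteins, fraction = 1 / 3) {
  stopifnot(all(c("protein_id", "avg_rsa", "expression") %in% names(proteins)))
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]")
  N <- nrow(proteins)
  k <- floor(fraction * N)
  if (k < 2) stop("fewer than 2 proteins per class: increase N or fraction")
  classify <- function(v) {
    if (length(unique(v)) == 1L)
      stop("all proteins tied on the ranking value: unrankable")
    ord <- order(v, proteins$protein_id)
    cls <- rep("mid", N)
    cls[ord[seq_len(k)]] <- "bottom"
    cls[ord[seq(N - k + 1L, N)]] <- "top"
    nTies <- sum(duplicated(v))
    if (nTies > 0)
      message(nTies, " tie(s) in ranking broken by protein ID")
    cls
  }
  core <- classify(proteins$avg_rsa)
  expr <- classify(proteins$expression)
  out <- proteins
  out$core_class <- factor(ifelse(core == "bottom", "largeCore",
                           ifelse(core == "top", "smallCore", "mid")),
                           levels = c("largeCore", "mid", "smallCore"))
  out$expr_class <- factor(ifelse(expr == "bottom", "low",
                           ifelse(expr == "top", "high", "mid")),
                           levels = c("low", "mid", "high"))
  out
}

#' Bin residue records by RSA
#'
#' Intervals are half-open [lo, hi) with the last bin closed at 100. The
#' representative x-value of a bin is the mean RSA of its members (or the
#' interval midpoint).
#'
#' @param records Residue records (gapless only) from
#'   \code{\link{mapCodonsToStructure}}.
#' @param edges Strictly increasing numeric vector of bin edges starting at
#'   0 and ending at 100; default ten 10\%-wide bins.
#' @param xValue "mean" (default) or "midpoint".
#' @return List of per-bin lists: \code{bin} (index), \code{lo}, \code{hi},
#'   \code{x}, \code{records} (member rows). Empty bins are kept and
#'   flagged by zero rows.
#' @export
binResidues <- function(records, edges = seq(0, 100, by = 10),
                        xValue = c("mean", "midpoint")) {
  xValue <- match.arg(xValue)
  if (edges[1] != 0 || edges[length(edges)] != 100 ||
      any(diff(edges) <= 0))
    stop("edges must increase strictly from 0 to 100")
  if (any(!records$gapless))
    stop("only gapless records may be binned")
  if (any(records$rsa < 0 | records$rsa > 100))
    stop("RSA outside [0, 100]")
  nb <- length(edges) - 1L
  idx <- findInterval(records$rsa, edges, rightmost.closed = TRUE)
  lapply(seq_len(nb), function(b) {
    rows <- records[idx == b, , drop = FALSE]
    x <- if (nrow(rows) == 0L) (edges[b] + edges[b + 1L]) / 2
    else if (xValue == "mean") mean(rows$rsa)
    else (edges[b] + edges[b + 1L]) / 2
    list(bin = b, lo = edges[b], hi = edges[b + 1L], x = x, records = rows)
  })
}

#' Concatenate a bin's gapless codon columns into an alignment
#'
#' Columns are sorted by protein ID then residue index, so the result is
#' independent of input order; taxon order is fixed across bins.
#'
#' @param members Residue-record data.frame (all gapless).
#' @param bin,lo,hi,x Bin bookkeeping carried into the result.
#' @return A \linkS4class{BinnedAlignment} (zero columns for an empty bin).
#' @export
concatenateBinAlignment <- function(members, bin = 1L, lo = 0, hi = 100,
                                    x = NA_real_) {
  codCols <- grep("^codon\\.", names(members), value = TRUE)
  taxa <- sub("^codon\\.", "", codCols)
  if (nrow(members) > 0 && any(!members$gapless))
    stop("bin members must all be gapless")
  ord <- order(members$protein_id, members$residue_index)
  members <- members[ord, , drop = FALSE]
  cm <- t(as.matrix(members[, codCols, drop = FALSE]))
  rownames(cm) <- taxa
  if (nrow(members) == 0L)
    cm <- matrix(character(0), nrow = length(taxa), ncol = 0,
                 dimnames = list(taxa, NULL))
  new("BinnedAlignment", binIndex = as.integer(bin), lo = lo, hi = hi,
      xRsa = as.numeric(x), taxa = taxa, codons = cm,
      proteinIds = as.character(members$protein_id))
}

#' Per-protein average RSA over gapless records
#'
#' @param records Residue records for one or more proteins.
#' @return data.frame \code{protein_id}, \code{avg_rsa}, \code{n_residues}.
#' @export
averageRsa <- function(records) {
  keep <- !is.na(records$rsa)
  agg <- tapply(records$rsa[keep], records$protein_id[keep], mean)
  data.frame(protein_id = names(agg), avg_rsa = as.numeric(agg),
             n_residues = as.integer(table(records$protein_id[keep])[names(agg)]),
             stringsAsFactors = FALSE)
}
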