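# Nei-Gojobori (1986) counting estimator for a pair of coding sequences.
# Used here as an independent brute-force oracle for the likelihood
# estimator: synonymous/nonsynonymous sites by per-position enumeration,
# differences averaged over all shortest mutational pathways (pathways
# through stop codons excluded), Jukes-Cantor multiple-hit correction.

.ng86SiteCounts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    for (nuc in setdiff(.nucs, substring(codon, p, p))) {
      mut <- codon
      substring(mut, p, p) <- nuc
      if (code[[mut]] != "*" && code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# Average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways passing through a stop codon are
# excluded (if every pathway is blocked, steps are counted as nonsynonymous
# along the direct enumeration).
.ng86PairDiffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(pos) == 1L) list(pos) else {
    prm <- function(v) if (length(v) == 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(prm(v[-i]), function(r) c(v[i], r))))
    prm(pos)
  }
  tot <- c(syn = 0, nonsyn = 0)
  nvalid <- 0L
  for (ord in perms) {
    cur <- c1
    steps <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + steps; nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) return(c(syn = 0, nonsyn = length(pos)))
  tot / nvalid
}

#' Nei-Gojobori pairwise dN and dS
#'
#' Counting-method estimates for two equal-length gapless in-frame coding
#' sequences: exhaustive per-position site counting, pathway-averaged
#' difference counting, and Jukes-Cantor correction.
#'
#' @param seq1,seq2 Nucleotide strings (lengths equal, divisible by 3) or
#'   character vectors of codons.
#' @return A list with \code{dn}, \code{ds}, \code{dnds} (NA when dS = 0),
#'   and the raw counts \code{sites} and \code{diffs}.
#' @export
ng86Rates <- function(seq1, seq2) {
  toCodons <- function(s) {
    if (length(s) > 1L) return(toupper(s))
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L) stop("sequence length must be divisible by 3")
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  c1 <- toCodons(seq1); c2 <- toCodons(seq2)
  if (length(c1) != length(c2)) stop("sequences must have equal length")
  if (anyNA(.codonIndex(c1)) || anyNA(.codonIndex(c2)))
    stop("sequences must consist of gapless sense codons")

  sites1 <- rowSums(vapply(c1, .ng86SiteCounts, numeric(2)))
  sites2 <- rowSums(vapply(c2, .ng86SiteCounts, numeric(2)))
  S <- (sites1[["syn"]] + sites2[["syn"]]) / 2
  N <- (sites1[["nonsyn"]] + sites2[["nonsyn"]]) / 2

  diffs <- rowSums(mapply(.ng86PairDiffs, c1, c2))
  Sd <- diffs[["syn"]]; Nd <- diffs[["nonsyn"]]

  jc <- function(p) {
    if (p >= 0.75) stop("proportion of differences >= 3/4: ",
                        "Jukes-Cantor correction undefined")
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  ds <- if (S > 0) jc(Sd / S) else 0
  dn <- if (N > 0) jc(Nd / N) else 0
  list(dn = dn, ds = ds, dnds = if (ds > 0) dn / ds else NA_real_,
       sites = c(S = S, N = N), diffs = c(Sd = Sd, Nd = Nd))
}
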