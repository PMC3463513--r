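# Single-omega Goldman-Yang (GY94) rate estimation on a fixed tree:
# rate-matrix construction, pruning likelihood (C++ core), multi-start ML
# optimisation, codeml-style dN/dS site bookkeeping, codon-column bootstrap
# standard errors, and the Nei-Gojobori counting oracle.

#' Build the GY94 instantaneous rate matrix
#'
#' Constructs the 61x61 sense-codon rate matrix with entries proportional to
#' the target codon frequency, multiplied by kappa for transitions and omega
#' for nonsynonymous changes; multi-nucleotide changes have rate zero. The
#' matrix is scaled so the mean substitution flux at stationarity is one
#' substitution per codon per unit branch length.
#'
#' @param params A \linkS4class{GY94Params} object.
#' @return A list with \code{Q} (scaled rate matrix, dimnames = codons),
#'   \code{scale} (the unscaled mean flux), and \code{rhoN}, \code{rhoS}
#'   (fractions of the total flux that are nonsynonymous / synonymous).
#' @export
buildGY94Matrix <- function(params) {
  stopifnot(is(params, "GY94Params"))
  validObject(params)
  cod <- senseCodons()
  n <- length(cod)
  pairs <- codonPairTable()
  Q <- matrix(0, n, n, dimnames = list(cod, cod))
  s <- ifelse(pairs[, "ts"] == 1L, params@kappa, 1) *
    ifelse(pairs[, "syn"] == 1L, 1, params@omega)
  i <- pairs[, "i"]; j <- pairs[, "j"]
  Q[cbind(i, j)] <- s * params@pi[j]
  Q[cbind(j, i)] <- s * params@pi[i]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(params@pi * diag(Q))
  fluxN <- 2 * sum(s[pairs[, "syn"] == 0L] *
                     params@pi[i[pairs[, "syn"] == 0L]] *
                     params@pi[j[pairs[, "syn"] == 0L]])
  fluxS <- mu - fluxN
  list(Q = Q / mu, scale = mu, rhoN = fluxN / mu, rhoS = fluxS / mu)
}

# F3x4 codon frequencies from a codon character matrix (position-specific
# nucleotide frequencies with a +1 pseudocount per nucleotide, normalised
# over sense codons).
.f3x4 <- function(codMat) {
  cods <- codMat[!is.na(.codonIndex(codMat))]
  pos <- lapply(1:3, function(p) substring(cods, p, p))
  f <- lapply(pos, function(x) {
    cnt <- table(factor(x, levels = .nucs)) + 1
    as.numeric(cnt / sum(cnt))
  })
  sc <- senseCodons()
  b1 <- match(substring(sc, 1, 1), .nucs)
  b2 <- match(substring(sc, 2, 2), .nucs)
  b3 <- match(substring(sc, 3, 3), .nucs)
  pi <- f[[1]][b1] * f[[2]][b2] * f[[3]][b3]
  pi / sum(pi)
}

# Codon index matrix for an alignment-like object; errors on stop codons,
# NA for gaps/ambiguity.
.idxMatrix <- function(x) {
  m <- codons(x)
  idx <- matrix(.codonIndex(m), nrow = nrow(m))
  stops <- matrix(m %in% c("TAA", "TAG", "TGA"), nrow = nrow(m))
  if (any(stops)) {
    col <- which(apply(stops, 2, any))[1]
    stop("stop codon in alignment at column ", col)
  }
  rownames(idx) <- taxa(x)
  idx
}

# Collapse codon-index columns to unique site patterns with weights.
.sitePatterns <- function(idx) {
  nt <- nrow(idx)
  code <- as.vector(61^(seq_len(nt) - 1) %*% (idx - 1))
  u <- !duplicated(code)
  pat <- idx[, u, drop = FALSE]
  w <- as.numeric(tabulate(match(code, code[u]), nbins = sum(u)))
  list(pat = pat, w = w)
}

.checkTreeTaxa <- function(tree, labels) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, labels))
    stop("tree tip labels must match alignment taxa exactly")
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  invisible(TRUE)
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over site patterns under the single-omega GY94 model.
#' For a reversible model the value is independent of root placement (pulley
#' principle).
#'
#' @param alignment A \linkS4class{CodonAlignment} or
#'   \linkS4class{BinnedAlignment} with gapless sense-codon columns.
#' @param tree An \code{ape} \code{phylo} tree with branch lengths in
#'   expected substitutions per codon; tip labels must match the taxa.
#' @param params A \linkS4class{GY94Params} object.
#' @return The log-likelihood (sum over columns).
#' @export
treeLogLikelihood <- function(alignment, tree, params) {
  stopifnot(is(params, "GY94Params"))
  idx <- .idxMatrix(alignment)
  if (anyNA(idx)) stop("alignment must be gapless sense codons")
  .checkTreeTaxa(tree, rownames(idx))
  idx <- idx[tree$tip.label, , drop = FALSE]
  sp <- .sitePatterns(idx)
  # run the probability series to machine convergence here: this exported
  # value is compared against dense linear-algebra references in the tests
  cpp_gy94_loglik(sp$pat, sp$w, tree$edge, tree$edge.length,
                  params@kappa, params@omega, params@pi, codonPairTable(),
                  1e-16)
}

# Guarded quasi-Newton minimisation: L-BFGS-B is fast but its line search
# can fail outright on large-gradient instances (it then returns the
# starting point claiming convergence); detect that signature and fall
# back to the slower, very robust PORT routine.
.qnMinimize <- function(p0, negll, grad, lower, upper, reltol, maxit) {
  fit <- try(stats::optim(p0, negll, gr = grad, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = reltol / 2.2e-16,
                                         maxit = maxit)),
             silent = TRUE)
  ok <- !inherits(fit, "try-error") && fit$convergence == 0L &&
    !identical(fit$par, p0)
  if (ok)
    return(list(par = fit$par, value = fit$value, converged = TRUE))
  fit2 <- try(stats::nlminb(p0, negll, gradient = grad,
                            lower = lower, upper = upper,
                            control = list(rel.tol = reltol,
                                           iter.max = maxit + 100)),
              silent = TRUE)
  if (!inherits(fit2, "try-error"))
    return(list(par = fit2$par, value = fit2$objective,
                converged = fit2$convergence == 0L))
  if (inherits(fit, "try-error")) return(NULL)
  list(par = fit$par, value = fit$value, converged = FALSE)
}

# Internal fit driver shared by the point estimate and the bootstrap.
# Gradients: analytic for branch lengths (pre-order pass in the C++ core),
# forward differences on the log scale for kappa and omega.
# Returns list(kappa, omega, blens, logLik, converged).
.fitGY94 <- function(pat, w, edge, pairs, pi, starts, reltol, tol = 3e-10) {
  nb <- nrow(edge)
  ib <- seq_len(nb) + 2L
  negll <- function(lp) {
    -cpp_gy94_loglik(pat, w, edge, exp(lp[ib]),
                     exp(lp[1]), exp(lp[2]), pi, pairs, tol)
  }
  h <- 1e-6
  grad <- function(lp) {
    bl <- exp(lp[ib]); ka <- exp(lp[1]); om <- exp(lp[2])
    r <- cpp_gy94_loglik_grad(pat, w, edge, bl, ka, om, pi, pairs, tol)
    # forward differences on the log scale for the two matrix parameters
    gk <- (cpp_gy94_loglik(pat, w, edge, bl, exp(lp[1] + h), om, pi, pairs, tol) -
           r$loglik) / h
    go <- (cpp_gy94_loglik(pat, w, edge, bl, ka, exp(lp[2] + h), pi, pairs, tol) -
           r$loglik) / h
    -c(gk, go, r$gradBlens * bl)
  }
  best <- NULL
  for (st in starts) {
    p0 <- c(log(st$kappa), log(st$omega), log(pmax(st$blens, 1e-6)))
    fit <- .qnMinimize(p0, negll, grad,
                       lower = c(log(0.1), log(1e-4), rep(log(1e-7), nb)),
                       upper = c(log(50), log(30), rep(log(5), nb)),
                       reltol = reltol, maxit = 200)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(kappa = exp(best$par[1]), omega = exp(best$par[2]),
       blens = exp(best$par[seq_len(nb) + 2L]),
       logLik = -best$value, converged = best$converged)
}

# Reduced fit used for bootstrap replicates: omega, kappa and one overall
# tree-scale factor, with branch-length proportions held at the full-data
# MLE. Proportions are stable under codon-column resampling, so this leaves
# bootstrap SEs essentially unchanged at a fraction of the cost of the full
# joint refit (the bootstrap-calibration checks exercise exactly this mode).
.fitGY94Scale <- function(pat, w, edge, pairs, pi, start, reltol, tol = 1e-8) {
  prop <- start$blens / sum(start$blens)
  negll <- function(lp) {
    -cpp_gy94_loglik(pat, w, edge, exp(lp[3]) * prop,
                     exp(lp[1]), exp(lp[2]), pi, pairs, tol)
  }
  h <- 1e-6
  grad <- function(lp) {
    bl <- exp(lp[3]) * prop; ka <- exp(lp[1]); om <- exp(lp[2])
    r <- cpp_gy94_loglik_grad(pat, w, edge, bl, ka, om, pi, pairs, tol)
    gk <- (cpp_gy94_loglik(pat, w, edge, bl, exp(lp[1] + h), om, pi, pairs, tol) -
           r$loglik) / h
    go <- (cpp_gy94_loglik(pat, w, edge, bl, ka, exp(lp[2] + h), pi, pairs, tol) -
           r$loglik) / h
    -c(gk, go, sum(r$gradBlens * bl))
  }
  p0 <- c(log(start$kappa), log(start$omega), log(sum(start$blens)))
  fit <- .qnMinimize(p0, negll, grad,
                     lower = c(log(0.1), log(1e-4), log(1e-6)),
                     upper = c(log(50), log(30), log(12)),
                     reltol = reltol, maxit = 60)
  if (is.null(fit)) return(NULL)
  list(kappa = exp(fit$par[1]), omega = exp(fit$par[2]),
       blens = exp(fit$par[3]) * prop,
       logLik = -fit$value, converged = fit$converged)
}

# Translate (omega, kappa, blens, pi) MLEs into tree-summed dN and dS using
# mutational-opportunity site counts from the neutral (omega = 1) matrix.
.ratesFromMLE <- function(kappa, omega, blens, pi, pairs) {
  fl <- cpp_gy94_flux(kappa, omega, 1, pi, pairs)
  fl1 <- cpp_gy94_flux(kappa, 1, 1, pi, pairs)
  tot <- sum(fl)
  rhoN <- fl[["fluxN"]] / tot
  rhoS <- fl[["fluxS"]] / tot
  fN1 <- fl1[["fluxN"]] / sum(fl1)
  Tlen <- sum(blens)
  dn <- Tlen * rhoN / (3 * fN1)
  ds <- Tlen * rhoS / (3 * (1 - fN1))
  list(dn = dn, ds = ds)
}

#' Maximum-likelihood dN/dS estimation for a concatenated codon alignment
#'
#' Jointly optimises omega, kappa and all branch lengths of a fixed topology
#' by bounded quasi-Newton iteration on log-transformed parameters, from
#' three omega starting points. dN and dS are derived from the MLEs as
#' tree-summed substitutions per nonsynonymous / synonymous site, with
#' mutational-opportunity site counts computed from the neutral rate matrix
#' (codeml-style). Codon frequencies follow the F3x4 convention by default.
#'
#' @param alignment A \linkS4class{BinnedAlignment} or
#'   \linkS4class{CodonAlignment} of gapless sense codons.
#' @param tree Fixed topology (\code{ape} \code{phylo}); branch lengths, if
#'   present, seed the optimiser.
#' @param starts Numeric vector of omega starting values.
#' @param piMethod "F3x4" (default), "empirical" (observed codon
#'   frequencies), or "uniform".
#' @param reltol Relative convergence tolerance of the quasi-Newton
#'   optimiser.
#' @return A \linkS4class{RateEstimate} (bootstrap SE slots are NA; see
#'   \code{\link{bootstrapSE}}).
#' @export
estimateRatesML <- function(alignment, tree, starts = c(0.1, 0.5, 1.5),
                            piMethod = c("F3x4", "empirical", "uniform"),
                            reltol = 1e-9) {
  piMethod <- match.arg(piMethod)
  idx <- .idxMatrix(alignment)
  if (anyNA(idx)) stop("alignment must be gapless sense codons")
  if (ncol(idx) < 1L) stop("alignment must have at least one column")
  .checkTreeTaxa(tree, rownames(idx))
  pi <- switch(piMethod,
    F3x4 = .f3x4(codons(alignment)),
    empirical = {
      cnt <- tabulate(idx, nbins = length(senseCodons())) + 0.5
      cnt / sum(cnt)
    },
    uniform = rep(1 / length(senseCodons()), length(senseCodons()))
  )
  idx <- idx[tree$tip.label, , drop = FALSE]
  sp <- .sitePatterns(idx)
  pairs <- codonPairTable()

  if (all(apply(sp$pat, 2, function(col) length(unique(col)) == 1L))) {
    # no variation at all: zero rates, undefined ratio
    warning("no variation across taxa: dN = dS = 0, dN/dS undefined")
    return(new("RateEstimate", dnds = NA_real_, dn = 0, ds = 0,
               seDnds = NA_real_, seDn = NA_real_, seDs = NA_real_,
               nCodons = as.integer(sum(sp$w)), logLik = NA_real_,
               kappa = NA_real_, treeLength = 0, converged = TRUE,
               defined = FALSE, nBootUndefined = 0L, seReliable = TRUE))
  }

  bl0 <- if (!is.null(tree$edge.length) && all(tree$edge.length > 0))
    tree$edge.length else rep(0.05, nrow(tree$edge))
  startList <- lapply(starts, function(om)
    list(kappa = 2, omega = om, blens = bl0))
  fit <- .fitGY94(sp$pat, sp$w, tree$edge, pairs, pi, startList, reltol)
  if (is.null(fit))
    return(new("RateEstimate", dnds = NA_real_, dn = NA_real_, ds = NA_real_,
               seDnds = NA_real_, seDn = NA_real_, seDs = NA_real_,
               nCodons = as.integer(sum(sp$w)), logLik = NA_real_,
               kappa = NA_real_, treeLength = NA_real_, converged = FALSE,
               defined = FALSE, nBootUndefined = 0L, seReliable = FALSE))
  rates <- .ratesFromMLE(fit$kappa, fit$omega, fit$blens, pi, pairs)
  defined <- rates$ds > 1e-8
  if (!defined)
    warning("no synonymous variation: dN/dS undefined for this alignment")
  # an omega estimate pinned at the optimiser box is a boundary solution
  # (e.g. zero observed nonsynonymous changes); flag it unconverged so
  # downstream fits can exclude it
  atBound <- fit$omega <= 1.5e-3 || fit$omega >= 27
  est <- new("RateEstimate",
             dnds = if (defined) fit$omega else NA_real_,
             dn = rates$dn, ds = rates$ds,
             seDnds = NA_real_, seDn = NA_real_, seDs = NA_real_,
             nCodons = as.integer(sum(sp$w)), logLik = fit$logLik,
             kappa = fit$kappa, treeLength = sum(fit$blens),
             converged = fit$converged && !atBound, defined = defined,
             nBootUndefined = 0L, seReliable = !atBound)
  attr(est, "mle") <- fit
  attr(est, "pi") <- pi
  est
}

#' Codon-column bootstrap standard errors for dN/dS, dN and dS
#'
#' Resamples aligned codon columns with replacement B times, re-estimates
#' the rates for each replicate (warm-started at the original MLE), and
#' reports the sample standard deviation over defined replicates as the
#' standard error of each quantity.
#'
#' @param alignment,tree As in \code{\link{estimateRatesML}}.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @param pointEstimate Optional \linkS4class{RateEstimate} returned by
#'   \code{estimateRatesML} for the same alignment (recomputed if missing).
#' @param refit "scale" (default) re-estimates omega, kappa and the overall
#'   tree scale per replicate, holding branch-length proportions at the
#'   full-data MLE; "full" re-optimises every branch length jointly.
#' @param reltol Optimiser tolerance for the replicate fits.
#' @return The point estimate as a \linkS4class{RateEstimate} with
#'   \code{seDnds}, \code{seDn}, \code{seDs}, \code{nBootUndefined} and
#'   \code{seReliable} filled in.
#' @export
bootstrapSE <- function(alignment, tree, B = 100, seed = NULL,
                        pointEstimate = NULL, refit = c("scale", "full"),
                        reltol = 1e-7) {
  refit <- match.arg(refit)
  if (B < 2) stop("B must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pointEstimate))
    pointEstimate <- estimateRatesML(alignment, tree)
  est <- pointEstimate
  mle <- attr(est, "mle")
  pi <- attr(est, "pi")
  idx <- .idxMatrix(alignment)
  .checkTreeTaxa(tree, rownames(idx))
  idx <- idx[tree$tip.label, , drop = FALSE]
  sp <- .sitePatterns(idx)
  pairs <- codonPairTable()
  n <- ncol(idx)

  if (is.null(mle)) {
    # degenerate point estimate (no variation): resamples are identical
    est@seDnds <- NA_real_; est@seDn <- 0; est@seDs <- 0
    est@nBootUndefined <- as.integer(B)
    est@seReliable <- FALSE
    return(est)
  }

  om <- dn <- ds <- rep(NA_real_, B)
  start <- list(kappa = mle$kappa, omega = mle$omega, blens = mle$blens)
  for (b in seq_len(B)) {
    w <- as.numeric(stats::rmultinom(1, n, sp$w))
    keep <- w > 0
    fit <- if (refit == "scale")
      .fitGY94Scale(sp$pat[, keep, drop = FALSE], w[keep], tree$edge,
                    pairs, pi, start, reltol)
    else
      .fitGY94(sp$pat[, keep, drop = FALSE], w[keep], tree$edge,
               pairs, pi, list(start), reltol)
    if (is.null(fit)) next
    r <- .ratesFromMLE(fit$kappa, fit$omega, fit$blens, pi, pairs)
    dn[b] <- r$dn; ds[b] <- r$ds
    if (r$ds > 1e-8) om[b] <- fit$omega
  }
  nUndef <- sum(is.na(om))
  est@seDnds <- if (sum(!is.na(om)) >= 2) stats::sd(om, na.rm = TRUE) else NA_real_
  est@seDn <- stats::sd(dn, na.rm = TRUE)
  est@seDs <- stats::sd(ds, na.rm = TRUE)
  est@nBootUndefined <- as.integer(nUndef)
  # unreliable when: too many undefined replicates, a degenerate (zero)
  # spread, or a boundary point estimate (inherited from estimateRatesML)
  est@seReliable <- est@seReliable && nUndef <= B / 2 &&
    (is.na(est@seDnds) || est@seDnds > 0)
  if (nUndef > B / 2)
    warning("more than half of bootstrap replicates had undefined dN/dS")
  est
}

#' Estimate rates with bootstrap standard errors in one call
#'
#' @inheritParams bootstrapSE
#' @return A \linkS4class{RateEstimate} with SEs filled in.
#' @export
estimateRatesWithSE <- function(alignment, tree, B = 100, seed = NULL,
                                piMethod = "F3x4", reltol = 1e-7) {
  pt <- estimateRatesML(alignment, tree, piMethod = piMethod)
  bootstrapSE(alignment, tree, B = B, seed = seed, pointEstimate = pt,
              reltol = reltol)
}
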