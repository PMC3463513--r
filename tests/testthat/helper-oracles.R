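# Independent oracles kept deliberately separate from the package's own
# code paths: dense matrix-exponential likelihoods, a numerical chi-square
# minimiser for the weighted line fit, and the analytic two-sphere
# cap-area formula for SASA.

# Dense P(t) by direct matrix exponential (Higham's scaling-and-squaring,
# via the Matrix package) -- an accurate reference fully independent of
# the package's uniformization code path.
expmOracle <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# Likelihood of a small alignment by brute-force summation over internal
# states using dense matrix exponentials (independent of the pruning code).
bruteLogLik2Taxon <- function(aln, tree, params) {
  M <- buildGY94Matrix(params)
  sc <- senseCodons()
  cm <- codons(aln)[tree$tip.label, , drop = FALSE]
  tsum <- sum(tree$edge.length)
  P <- expmOracle(M$Q, tsum)
  ll <- 0
  for (s in seq_len(ncol(cm))) {
    i <- match(cm[1, s], sc); j <- match(cm[2, s], sc)
    ll <- ll + log(params@pi[i] * P[i, j])
  }
  ll
}

# Numerical chi-square minimiser for the straight-line fit with known
# per-point sigma (Nelder-Mead from several starts), plus standard errors
# from the analytic curvature of the chi-square surface evaluated
# numerically.
gridLineFitOracle <- function(x, y, sigma) {
  chisq <- function(par) sum(((y - par[1] - par[2] * x) / sigma)^2)
  best <- NULL
  for (b0 in c(-1, 0, 1, mean(y))) for (m0 in c(-1, 0, 1)) {
    f <- optim(c(b0, m0), chisq, control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || f$value < best$value) best <- f
  }
  # curvature of a quadratic surface: second differences
  h <- 1e-4
  p <- best$par
  d2b <- (chisq(p + c(h, 0)) - 2 * chisq(p) + chisq(p - c(h, 0))) / h^2
  d2m <- (chisq(p + c(0, h)) - 2 * chisq(p) + chisq(p - c(0, h))) / h^2
  dbm <- (chisq(p + c(h, h)) - chisq(p + c(h, -h)) -
            chisq(p + c(-h, h)) + chisq(p + c(-h, -h))) / (4 * h^2)
  H <- matrix(c(d2b, dbm, dbm, d2m), 2) / 2   # chi2 = const + dp' H dp
  V <- solve(H)
  list(intercept = p[1], slope = p[2],
       seIntercept = sqrt(V[1, 1]), seSlope = sqrt(V[2, 2]),
       chisq = best$value)
}

# Exact accessible area of sphere 1 (radius r1, expanded) partially
# occluded by sphere 2 at centre distance d: spherical cap cut-off.
capAreaOracle <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d <= abs(r1 - r2)) return(if (r1 < r2) 0 else 4 * pi * r1^2)
  # height of the cap of sphere 1 inside sphere 2
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}
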