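# Error-weighted straight-line fits to per-bin estimates versus RSA,
# t-tests of slopes/intercepts against nulls and between lines, and
# fold-change-versus-RSA curves with delta-method errors.

#' Error-weighted straight-line fit
#'
#' Minimises chi^2 = sum((y_i - b - m x_i) / sigma_i)^2 for points with
#' known per-point standard errors, via the closed-form normal-equation
#' sums S = sum 1/sigma^2, S_x, S_y, S_xx, S_xy; Delta = S S_xx - S_x^2;
#' se(m)^2 = S / Delta, se(b)^2 = S_xx / Delta.
#'
#' @param x,y Numeric vectors (e.g. bin RSA and per-bin dN/dS).
#' @param sigma Positive standard errors of y; points with missing or
#'   non-positive sigma (or missing y) are dropped with a message.
#' @return A \linkS4class{LineFit}.
#' @export
weightedLineFit <- function(x, y, sigma) {
  keep <- is.finite(x) & is.finite(y) & is.finite(sigma) & sigma > 0
  if (sum(!keep) > 0)
    message(sum(!keep), " point(s) with undefined estimate or error dropped",
            " from line fit")
  x <- x[keep]; y <- y[keep]; sigma <- sigma[keep]
  n <- length(x)
  if (n < 3L) stop("at least 3 points with finite positive errors required")
  if (length(unique(x)) == 1L) stop("all x identical: line undetermined")
  w <- 1 / sigma^2
  S <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  Delta <- S * Sxx - Sx^2
  m <- (S * Sxy - Sx * Sy) / Delta
  b <- (Sxx * Sy - Sx * Sxy) / Delta
  chisq <- sum(((y - b - m * x) / sigma)^2)
  new("LineFit", slope = m, intercept = b,
      seSlope = sqrt(S / Delta), seIntercept = sqrt(Sxx / Delta),
      n = as.integer(n), chisq = chisq)
}

.comparisonResult <- function(parameter, estimate, se, t, df, nullValue,
                              groupA = NA_character_, groupB = NA_character_,
                              analysis = NA_character_) {
  data.frame(analysis = analysis, group_A = groupA, group_B = groupB,
             parameter = parameter, estimate = estimate, se = se,
             t = t, df = df, p = 2 * stats::pt(-abs(t), df),
             null_value = nullValue, stringsAsFactors = FALSE)
}

#' Compare a slope or intercept between two fitted lines
#'
#' t = (param_A - param_B) / sqrt(se_A^2 + se_B^2) against the two-tailed
#' t-distribution with n_A + n_B - 4 degrees of freedom.
#'
#' @param fitA,fitB \linkS4class{LineFit} objects.
#' @param parameter "slope" or "intercept".
#' @param groupA,groupB,analysis Optional labels carried into the result.
#' @return One-row data.frame: \code{parameter}, \code{estimate}
#'   (difference), \code{se}, \code{t}, \code{df}, \code{p}.
#' @export
compareLineParams <- function(fitA, fitB,
                              parameter = c("slope", "intercept"),
                              groupA = "A", groupB = "B",
                              analysis = NA_character_) {
  parameter <- match.arg(parameter)
  pa <- if (parameter == "slope") fitA@slope else fitA@intercept
  pb <- if (parameter == "slope") fitB@slope else fitB@intercept
  sa <- if (parameter == "slope") fitA@seSlope else fitA@seIntercept
  sb <- if (parameter == "slope") fitB@seSlope else fitB@seIntercept
  se <- sqrt(sa^2 + sb^2)
  if (se == 0) stop("zero combined standard error")
  df <- fitA@n + fitB@n - 4L
  .comparisonResult(parameter, pa - pb, se, (pa - pb) / se, df, 0,
                    groupA, groupB, analysis)
}

#' Test a slope or intercept against a null value
#'
#' t = (param - null) / se against the two-tailed t-distribution with
#' n - 2 degrees of freedom. The natural nulls are slope 0 (no RSA
#' dependence) and, for fold-change fits, intercept 1 (no fold change).
#'
#' @param fit A \linkS4class{LineFit}.
#' @param parameter "slope" or "intercept".
#' @param nullValue Null value (default 0).
#' @param analysis Optional label.
#' @return One-row data.frame as in \code{\link{compareLineParams}}.
#' @export
testParamNull <- function(fit, parameter = c("slope", "intercept"),
                          nullValue = 0, analysis = NA_character_) {
  parameter <- match.arg(parameter)
  pa <- if (parameter == "slope") fit@slope else fit@intercept
  se <- if (parameter == "slope") fit@seSlope else fit@seIntercept
  if (se == 0) stop("zero standard error")
  df <- fit@n - 2L
  .comparisonResult(parameter, pa, se, (pa - nullValue) / se, df, nullValue)
}

#' Fold-change-versus-RSA curve between two per-bin series
#'
#' Per bin, R = y_A / y_B with the delta-method standard error
#' SE_R = R sqrt((s_A/y_A)^2 + (s_B/y_B)^2). Bins where either estimate is
#' undefined or y_B <= 0 are dropped with a message.
#'
#' @param seriesA,seriesB data.frames with columns \code{x}, \code{y},
#'   \code{sigma}, on identical bins (same \code{x}).
#' @return data.frame \code{x}, \code{ratio}, \code{se}.
#' @export
foldChangeCurve <- function(seriesA, seriesB) {
  if (nrow(seriesA) != nrow(seriesB) ||
      any(abs(seriesA$x - seriesB$x) > 1e-9 & !(is.na(seriesA$x) | is.na(seriesB$x))))
    stop("series must share identical bins")
  ok <- is.finite(seriesA$y) & is.finite(seriesB$y) & seriesB$y > 0 &
    is.finite(seriesA$sigma) & is.finite(seriesB$sigma)
  if (sum(!ok) > 0)
    message(sum(!ok), " bin(s) with undefined or non-positive denominator ",
            "dropped from fold-change curve")
  if (!any(ok)) stop("no common defined bins")
  a <- seriesA[ok, ]; b <- seriesB[ok, ]
  ratio <- a$y / b$y
  se <- ratio * sqrt((a$sigma / a$y)^2 + (b$sigma / b$y)^2)
  data.frame(x = a$x, ratio = ratio, se = se)
}

#' Fit and test a fold-change curve
#'
#' Convenience wrapper: error-weighted line fit to the fold-change points,
#' plus the two null tests (slope = 0, intercept = 1).
#'
#' @param fc Fold-change data.frame from \code{\link{foldChangeCurve}}.
#' @param analysis Optional label.
#' @return List with \code{fit} (\linkS4class{LineFit}) and \code{tests}
#'   (two-row data.frame).
#' @export
foldChangeTests <- function(fc, analysis = NA_character_) {
  fit <- weightedLineFit(fc$x, fc$ratio, fc$se)
  tests <- rbind(
    testParamNull(fit, "slope", 0, analysis = analysis),
    testParamNull(fit, "intercept", 1, analysis = analysis))
  list(fit = fit, tests = tests)
}
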