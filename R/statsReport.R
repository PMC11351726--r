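# Statistical reporting: Pearson correlation with simple-regression slope
# F-test, and unpaired two-sided t-tests for per-timepoint group comparison.

#' Pearson correlation with simple linear regression
#'
#' Reports the Pearson coefficient r with its two-sided p-value, the
#' least-squares slope and intercept of y on x, and the slope F-statistic
#' with (1, n-2) degrees of freedom. In simple regression F equals the
#' squared slope t-statistic and the two p-values coincide.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' pearsonWithRegression(c(1, 2, 3), c(1, 3, 2))  # r = 0.5
#' @export
pearsonWithRegression <- function(x, y) {
  if (length(x) != length(y)) stop("degenerate data: unequal lengths")
  n <- length(x)
  if (n < 3) stop("degenerate data: need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate data: constant input")
  fit <- stats::lm(y ~ x)
  # a perfect fit makes the F-statistic numerically unstable; r = +/-1 and
  # the p-values are handled explicitly below, so the warning is redundant
  an <- suppressWarnings(stats::anova(fit))
  Fstat <- an[["F value"]][1]
  pF <- an[["Pr(>F)"]][1]
  r <- stats::cor(x, y)
  # p for r from its t transform, df = n - 2
  if (abs(r) >= 1) {
    pR <- 0
  } else {
    tR <- r * sqrt((n - 2) / (1 - r^2))
    pR <- 2 * stats::pt(-abs(tR), df = n - 2)
  }
  cf <- stats::coef(fit)
  new("CorrelationResult", r = r, n = as.integer(n),
      slope = unname(cf[2]), intercept = unname(cf[1]),
      F = Fstat, pR = pR, pF = pF)
}

#' Unpaired two-sided t-test
#'
#' Pooled-variance (Student) test by default, df = n_a + n_b - 2; Welch
#' available via \code{welch = TRUE}. Degenerate inputs are defined, not
#' errors: zero pooled variance with equal means gives t = 0, p = 1;
#' complete separation with zero variance gives p at the smallest
#' representable positive double.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch variant.
#' @return list(t, p, df).
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("degenerate data: each group needs at least 2 observations")
  na <- length(a); nb <- length(b)
  pooledVar <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (pooledVar == 0) {
    df <- na + nb - 2
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                p = .Machine$double.xmin, df = df))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Write a stats report as JSON
#' @param results named list of \linkS4class{CorrelationResult} objects,
#'   t-test lists, or plain values.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStatsJson <- function(results, path) {
  flat <- lapply(results, function(x) {
    if (is(x, "CorrelationResult"))
      list(r = x@r, n = x@n, slope = x@slope, intercept = x@intercept,
           F = x@F, p_r = x@pR, p_F = x@pF)
    else x
  })
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
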