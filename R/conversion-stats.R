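# Cohort statistics for SNV-driven conversion:
# binned conversion fractions against off-target counts, weighted
# through-origin regression, rate prediction and the two-sample Z test.

#' Bin conversion outcomes by off-target count
#'
#' Bins per-target conversion outcomes by the number of three-mismatch
#' off-target sites and reports the converted fraction per bin. Bins are
#' half-open `[low, low + binWidth)` over `range`; empty bins are omitted.
#'
#' @param summaries A data.frame with columns `n3` (off-target count) and
#'   `converted` (logical), e.g. `perTarget` from [genomeConversionRate()].
#' @param binWidth Bin width on the off-target-count axis (default 5).
#' @param range Numeric length-2 range of counts retained (default
#'   `c(0, 100)`; the upper edge is inclusive).
#' @return A data.frame with columns `binLow`, `binHigh`, `center`, `n`,
#'   `converted`, `fraction`.
#' @export
binFractions <- function(summaries, binWidth = 5, range = c(0, 100)) {
  if (nrow(summaries) == 0L) stop("no target summaries supplied")
  if (binWidth <= 0) stop("binWidth must be positive")
  keep <- summaries$n3 >= range[1L] & summaries$n3 <= range[2L]
  s <- summaries[keep, , drop = FALSE]
  lo <- range[1L] + floor((s$n3 - range[1L]) / binWidth) * binWidth
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(s)),
                                converted = as.integer(s$converted)) ~ lo,
                          data = data.frame(lo = lo), FUN = sum)
  agg <- agg[order(agg$lo), , drop = FALSE]
  data.frame(binLow = agg$lo, binHigh = agg$lo + binWidth,
             center = agg$lo + binWidth / 2, n = agg$n,
             converted = agg$converted, fraction = agg$converted / agg$n)
}

#' Fit a zero-intercept regression of conversion fraction on off-target count
#'
#' Weighted least squares with the intercept fixed at zero:
#' `beta = sum(w x f) / sum(w x^2)` with weights `w` equal to the per-bin
#' target counts, `x` the bin centers and `f` the converted fractions.
#' Weighting by bin counts makes the binned fit identical to the per-target
#' through-origin fit. The coefficient of determination is the uncentered
#' `R^2 = 1 - SS_res / sum(w f^2)`, the form appropriate for through-origin
#' models. The slope is reported in percent per off-target site.
#'
#' @param bins A data.frame from [binFractions()] (columns `center`, `n`,
#'   `fraction`), or any data.frame with those columns.
#' @param range Fit range on the off-target-count axis (default
#'   `c(0, 100)`); bins whose centers fall outside are dropped.
#' @return An [OriginRegression-class].
#' @examples
#' b <- data.frame(center = c(10, 30, 50), n = c(5, 5, 5),
#'                 fraction = 0.00145 * c(10, 30, 50))
#' regressionSlope(fitThroughOrigin(b))  # 0.145 (percent per off-target)
#' @export
fitThroughOrigin <- function(bins, range = c(0, 100)) {
  b <- if (all(c("binLow", "binHigh") %in% names(bins)))
    bins[bins$binLow <= range[2L] & bins$binHigh >= range[1L], ,
         drop = FALSE]
  else
    bins[bins$center >= range[1L] & bins$center <= range[2L], , drop = FALSE]
  if (nrow(b) < 2L)
    stop("need at least two non-empty bins inside the fit range")
  if (all(b$center == 0))
    stop("all bin centers are zero; slope undefined")
  fit <- stats::lm(fraction ~ 0 + center, data = b, weights = b$n)
  beta <- unname(stats::coef(fit)[1L])
  ## vcov warns on an exactly collinear (noiseless) fit; the SE is then 0
  se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))[1L]))
  w <- b$n
  ssRes <- sum(w * stats::residuals(fit)^2)
  ssTot <- sum(w * b$fraction^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  methods::new("OriginRegression", slopePct = beta * 100,
               slopeSE = se * 100, r2 = r2,
               fitRange = as.numeric(range), bins = b)
}

#' Predict a cohort conversion rate from a through-origin regression
#'
#' Linear extrapolation `slope x meanN3` on the percent scale: the expected
#' percentage of targets acquiring an SNV-converted off-target for a cohort
#' with the given mean three-mismatch off-target count.
#'
#' @param regression An [OriginRegression-class], or a numeric slope in
#'   percent per off-target.
#' @param meanN3 Mean three-mismatch off-target count of the cohort.
#' @return Predicted conversion rate, in percent.
#' @examples
#' predictRate(0.145, 16.17)  # 2.34 (percent, 2 d.p.)
#' @export
predictRate <- function(regression, meanN3) {
  if (meanN3 < 0) stop("meanN3 must be non-negative")
  slope <- if (methods::is(regression, "OriginRegression"))
    regressionSlope(regression) else as.numeric(regression)
  slope * meanN3
}

#' Two-sided Z test for a difference of means from summary statistics
#'
#' Normal-approximation comparison of two sample means given only
#' mean/standard deviation/size summaries, as used to compare off-target
#' count distributions between site-selection strategies:
#' `z = (meanA - meanB) / sqrt(sdA^2/nA + sdB^2/nB)`, `p = 2 Phi(-|z|)`.
#' With very large samples p underflows to exactly 0 in double precision.
#' When both variances are zero and the means are equal, `z = 0`, `p = 1`
#' by convention.
#'
#' @param meanA,sdA,nA Summary statistics of sample A (`nA >= 2`).
#' @param meanB,sdB,nB Summary statistics of sample B (`nB >= 2`).
#' @return A list with elements `z` and `p`.
#' @examples
#' twoSampleZTest(16.17, 12.56, 927104, 46.83, 25.76, 1922668)$p  # 0
#' @export
twoSampleZTest <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2L || nB < 2L) stop("both samples need n >= 2")
  if (sdA < 0 || sdB < 0) stop("standard deviations must be non-negative")
  se <- sqrt(sdA^2 / nA + sdB^2 / nB)
  if (se == 0) {
    if (meanA == meanB) return(list(z = 0, p = 1))
    return(list(z = sign(meanA - meanB) * Inf, p = 0))
  }
  z <- (meanA - meanB) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Extrapolate a clinically relevant off-target mutation rate
#'
#' Scales a cohort conversion percentage by the relative Cas9 activity
#' expected at a converted (typically heterozygous, two-mismatch) off-target
#' site: `rate_percent x activity_fraction`, on the percent scale.
#'
#' @param conversionPercent Conversion rate in percent (0-100).
#' @param relativeActivityFraction Relative off-target activity as a
#'   fraction of on-target activity (0-1).
#' @return The extrapolated rate, in percent.
#' @examples
#' extrapolateClinicalRate(2.0, 0.33)  # 0.66
#' @export
extrapolateClinicalRate <- function(conversionPercent,
                                    relativeActivityFraction) {
  if (conversionPercent < 0 || conversionPercent > 100)
    stop("conversionPercent must lie in [0, 100]")
  if (relativeActivityFraction < 0 || relativeActivityFraction > 1)
    stop("relativeActivityFraction must lie in [0, 1]")
  conversionPercent * relativeActivityFraction
}
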