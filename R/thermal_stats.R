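#' Thermal-axis normalization and summary statistics
#'
#' Helpers shared by all analyses: mapping absolute temperature onto the
#' normalized ramp axis (%T_LOE), temperature binning, the oxygen-solubility
#' reference curve, and the t-test machinery used for group comparisons and
#' per-bin laterality tests.
#'
#' @name thermal_stats
NULL

#' Normalized ramp progress (%T_LOE)
#'
#' Maps absolute water temperature onto the normalized range of a warming
#' ramp: 0% at the initial temperature `T0` and 100% at the temperature of
#' loss of equilibrium `T_LOE` of that experiment. This is the common axis on
#' which experiments with different start and endpoint temperatures are
#' aligned before averaging across specimens.
#'
#' @param temp numeric vector of absolute temperatures (degC).
#' @param t0 initial (ramp start) temperature, degC.
#' @param t_loe temperature at loss of equilibrium, degC; must exceed `t0`.
#' @return numeric vector of percentages (0 at `t0`, 100 at `t_loe`; values
#'   outside the ramp extrapolate linearly).
#' @examples
#' percent_tloe(8, t0 = 0.5, t_loe = 15.5)  # 50
#' @export
percent_tloe <- function(temp, t0, t_loe) {
  if (!is.numeric(temp)) stop("`temp` must be numeric")
  if (t_loe <= t0) stop("`t_loe` must exceed `t0`")
  100 * (temp - t0) / (t_loe - t0)
}

#' Thermal axis of one experiment
#'
#' @param t0,t_loe ramp start and loss-of-equilibrium temperatures (degC).
#' @return object of class `thermal_axis` with a `$pct(temp)` mapping.
#' @export
thermal_axis <- function(t0, t_loe) {
  if (t_loe <= t0) stop("`t_loe` must exceed `t0`")
  structure(
    list(t0 = t0, t_loe = t_loe,
         pct = function(temp) percent_tloe(temp, t0, t_loe)),
    class = "thermal_axis"
  )
}

#' Equilibrium dissolved-oxygen concentration of seawater
#'
#' Henry's-law air-saturation O2 concentration as a function of temperature
#' and salinity, using the Garcia & Gordon (1992) refit of the Benson & Krause
#' solubility data. Serves as the theoretical reference for the progressive
#' aquatic hypoxia that accompanies a warming ramp: warmer and saltier water
#' holds less oxygen.
#'
#' @param temp_c water temperature in degC, within [-2, 30].
#' @param salinity practical salinity (psu), within [0, 40].
#' @return dissolved O2 at air saturation, mg per liter. Strictly decreasing
#'   in both temperature and salinity.
#' @examples
#' do2_saturation(0, 35)   # ~11.4 mg/L, polar surface seawater
#' @export
do2_saturation <- function(temp_c, salinity) {
  if (any(temp_c < -2 | temp_c > 30)) stop("`temp_c` outside supported range [-2, 30]")
  if (any(salinity < 0 | salinity > 40)) stop("`salinity` outside supported range [0, 40]")
  # Garcia & Gordon (1992), Benson & Krause coefficient set, C in mL/L
  ts <- log((298.15 - temp_c) / (273.15 + temp_c))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  ln_c <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 + a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) + c0 * salinity^2
  # mL O2 / L -> mg / L (1 mL O2 at STP = 1.42905 mg)
  exp(ln_c) * 1.42905
}

.ttest_result <- function(t, df, p, flavor, degenerate = FALSE) {
  structure(
    list(t = t, df = df, p = p, flavor = flavor, degenerate = degenerate),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g%s\n",
              tolower(x$flavor), x$t, x$df, x$p,
              if (isTRUE(x$degenerate)) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Welch two-sample t-test (unequal variances, two-tailed)
#'
#' Used to compare endpoint temperatures (T_LOE) between species groups.
#' Degrees of freedom follow Welch-Satterthwaite; for equal group sizes with
#' equal sample variances this reduces to the pooled value nA + nB - 2.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a `ttest_result` with fields `t`, `df`, `p`, `flavor = "WELCH"`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  .ttest_result(unname(ht$statistic), unname(ht$parameter), ht$p.value, "WELCH")
}

#' One-sample t-test against a theoretical mean
#'
#' Used per temperature bin to compare lateralization indices against the
#' theoretical zero of a random left/right choice. A zero-variance sample is
#' degenerate for the t statistic; it is flagged rather than silently tested,
#' with p reported as 1 when every value equals `mu0` and as the machine
#' floor otherwise (the data deviate from `mu0` with no measured spread).
#'
#' @param x numeric vector, length >= 2.
#' @param mu0 null-hypothesis mean (default 0).
#' @return a `ttest_result`; `degenerate` is `TRUE` when `var(x) == 0`.
#' @export
one_sample_ttest <- function(x, mu0 = 0) {
  if (length(x) < 2) stop("need n >= 2")
  if (stats::var(x) == 0) {
    if (x[1] == mu0) return(.ttest_result(0, length(x) - 1, 1, "ONE_SAMPLE", TRUE))
    return(.ttest_result(sign(x[1] - mu0) * Inf, length(x) - 1,
                         .Machine$double.xmin, "ONE_SAMPLE", TRUE))
  }
  ht <- stats::t.test(x, mu = mu0, alternative = "two.sided")
  .ttest_result(unname(ht$statistic), unname(ht$parameter), ht$p.value, "ONE_SAMPLE")
}

#' Two-tailed critical value of Student's t distribution
#'
#' @param alpha two-tailed significance level.
#' @param df degrees of freedom.
#' @return the critical t value such that P(|T| > t) = alpha.
#' @examples
#' t_critical(0.05, 8)  # 2.306
#' @export
t_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (any(df <= 0)) stop("`df` must be positive")
  stats::qt(1 - alpha / 2, df)
}

#' Bin records by absolute temperature
#'
#' Half-open, lower-closed bins `[k*width, (k+1)*width)` anchored at `origin`.
#' Record order is preserved within bins.
#'
#' @param df data.frame with a temperature column.
#' @param width bin width in degC (> 0).
#' @param temp_col name of the temperature column (default `"temp"`).
#' @param origin bin-anchoring offset (default 0).
#' @return named list of data.frames; names are the lower bin edges.
#' @export
bin_by_temperature <- function(df, width, temp_col = "temp", origin = 0) {
  if (width <= 0) stop("`width` must be positive")
  if (!temp_col %in% names(df)) stop("missing temperature column: ", temp_col)
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  lower <- floor((df[[temp_col]] - origin) / width) * width + origin
  split(df, factor(lower, levels = sort(unique(lower))))
}
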