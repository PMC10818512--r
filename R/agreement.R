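# Agreement statistics between the IMU-based and optical foot strike angle:
# Bland-Altman bias and 95% limits of agreement, repeatability coefficient,
# ICC(3,1) with its F-based confidence interval, and the within-subject
# variants.

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `imu - omcs`. Reports the mean difference
#' (bias), the sample standard deviation (n-1 denominator) and the 95%
#' limits of agreement `mean +/- 1.96 * SD`.
#'
#' @param imu,omcs Paired measurements (same length, n >= 2), e.g. the
#'   per-stride FSA of the two systems, in degrees.
#' @return An object of class `bland_altman`: list with `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high` and the `differences`.
#' @export
bland_altman <- function(imu, omcs) {
  stopifnot(length(imu) == length(omcs))
  d <- imu - omcs
  d <- d[is.finite(d)]
  if (length(d) < 2L) stop("Bland-Altman needs at least 2 paired differences")
  m <- mean(d)
  s <- stats::sd(d)
  loa <- limits_of_agreement(m, s)
  structure(list(n = length(d), mean_diff = m, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2], differences = d),
            class = "bland_altman")
}

#' 95% limits of agreement from summary statistics
#'
#' `mean_diff +/- 1.96 * sd_diff`, the classical large-sample limits (no
#' small-sample t correction).
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD of the paired differences.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' limits_of_agreement(1.4, 2.3)  # c(-3.108, 5.908)
#' @export
limits_of_agreement <- function(mean_diff, sd_diff) {
  c(mean_diff - 1.96 * sd_diff, mean_diff + 1.96 * sd_diff)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.2f, SD = %.2f, LoA [%.2f, %.2f]\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Repeatability coefficient of paired differences
#'
#' Defined here as `1.96 * sqrt(mean(d^2))`, i.e. 1.96 times the root mean
#' square of the inter-system differences; about 95% of absolute differences
#' are expected below this bound. Unlike `1.96 * sqrt(2) * SD`, this
#' definition includes the systematic bias, so it never decreases when a
#' constant offset is added to all differences.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @return The repeatability coefficient (same units as the input).
#' @seealso [rc_from_summary()]
#' @export
repeatability_coefficient <- function(differences) {
  d <- differences[is.finite(differences)]
  if (length(d) < 2L) stop("repeatability coefficient needs n >= 2")
  1.96 * sqrt(mean(d^2))
}

#' Repeatability coefficient from summary statistics
#'
#' For differences with mean m and (population) SD s,
#' `RMS = sqrt(m^2 + s^2)`, hence `RC = 1.96 * sqrt(m^2 + s^2)`.
#'
#' @param mean_diff,sd_diff Mean and SD of the differences.
#' @examples
#' rc_from_summary(1.4, 2.3)  # 5.28
#' @export
rc_from_summary <- function(mean_diff, sd_diff) {
  1.96 * sqrt(mean_diff^2 + sd_diff^2)
}

#' ICC(3,1): two-way mixed, single measure, consistency
#'
#' Intraclass correlation for k fixed raters (here the two measurement
#' systems) scoring n targets (strides), computed from the two-way ANOVA
#' mean squares as `(MS_R - MS_E) / (MS_R + (k-1) MS_E)` where MS_R is the
#' between-target and MS_E the residual mean square. The consistency form
#' is insensitive to a constant inter-system bias. The 95% confidence
#' interval uses the F-distribution bounds on `MS_R / MS_E`.
#'
#' @param imu,omcs Paired measurements (n >= 3).
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, `k` and the mean
#'   squares `ms_rows`, `ms_error`.
#' @export
icc_3_1 <- function(imu, omcs, conf = 0.95) {
  stopifnot(length(imu) == length(omcs))
  ok <- is.finite(imu) & is.finite(omcs)
  x <- cbind(imu[ok], omcs[ok])
  n <- nrow(x)
  k <- 2L
  if (n < 3L) stop("ICC needs at least 3 targets")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0 || (ms_rows + (k - 1) * ms_err) == 0)
    stop("ICC undefined: no between-target variance")
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  alpha <- 1 - conf
  fobs <- ms_rows / ms_err
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  list(icc = icc,
       ci_low = (fl - 1) / (fl + k - 1),
       ci_high = (fu - 1) / (fu + k - 1),
       n = n, k = k, ms_rows = ms_rows, ms_error = ms_err)
}

#' Interpretation band for reliability/correlation magnitudes
#'
#' Magnitude bands: weak below 0.5, moderate in [0.5, 0.75), good in
#' [0.75, 0.9), excellent at or above 0.9. Applied to |r| since negative
#' correlations are banded by magnitude.
#'
#' @param r Correlation or ICC value.
#' @return One of `"weak"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
classify_correlation <- function(r) {
  a <- abs(r)
  if (!is.finite(a)) return(NA_character_)
  if (a < 0.5) "weak" else if (a < 0.75) "moderate"
  else if (a < 0.9) "good" else "excellent"
}

#' Within-subject agreement analysis
#'
#' Runs a Bland-Altman analysis and computes the repeatability coefficient
#' per subject, then summarizes across subjects: mean and (n-1) SD of the
#' per-subject repeatability coefficients, a Bland-Altman analysis of the
#' per-subject mean FSAs, and the pooled per-subject biases. Subjects with
#' fewer than 2 strides are excluded with a warning.
#'
#' @param subject Factor/character vector of subject ids, one per stride.
#' @param imu,omcs Paired per-stride measurements.
#' @return List with `per_subject` (data.frame: subject, n, mean_diff,
#'   sd_diff, loa_low, loa_high, rc), `rc_mean`, `rc_sd`, `mean_diff_mean`,
#'   `mean_diff_sd`, and `subject_means` (per-subject mean FSA of each
#'   system).
#' @export
within_subject_agreement <- function(subject, imu, omcs) {
  stopifnot(length(subject) == length(imu), length(imu) == length(omcs))
  subject <- as.character(subject)
  ids <- unique(subject)
  rows <- list()
  means <- list()
  for (id in ids) {
    i <- subject == id
    if (sum(i) < 2L) {
      warning("subject ", id, " excluded: fewer than 2 strides")
      next
    }
    ba <- bland_altman(imu[i], omcs[i])
    rows[[id]] <- data.frame(
      subject = id, n = ba$n, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      rc = repeatability_coefficient(ba$differences))
    means[[id]] <- data.frame(subject = id, fsa_imu = mean(imu[i]),
                              fsa_omcs = mean(omcs[i]))
  }
  if (length(rows) < 2L)
    stop("within-subject analysis needs at least 2 subjects with >= 2 strides")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  sm <- do.call(rbind, means)
  rownames(sm) <- NULL
  list(per_subject = per,
       rc_mean = mean(per$rc), rc_sd = stats::sd(per$rc),
       mean_diff_mean = mean(per$mean_diff),
       mean_diff_sd = stats::sd(per$mean_diff),
       subject_means = sm)
}
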