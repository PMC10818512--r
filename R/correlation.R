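# Pearson correlation machinery for the indicator-vs-propulsion tables:
# stride-by-stride and within-subject scopes, per system, for the AUC and
# peak propulsion targets.

#' Indicator column names of a stride table
#' @return Character vector of the eight candidate indicators.
#' @export
propulsion_indicators <- function() {
  c("foot_angle_tc", "shank_angle_tc",
    "max_foot_angvel", "max_shank_angvel",
    "max_foot_angacc", "max_shank_angacc",
    "max_shank_linacc", "stride_length")
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n-2 degrees of freedom (via [stats::cor.test()]). Pairs with missing
#' values are dropped; zero variance in either variable is flagged as an
#' error.
#'
#' @param x,y Numeric vectors.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation tables: indicators vs forward propulsion
#'
#' For each of the eight candidate indicators, each system (OMCS, IMU), and
#' each propulsion target (AUC and peak), computes (a) the stride-by-stride
#' Pearson correlation with its p-value over all eligible strides pooled,
#' and (b) the within-subject scope: the per-subject correlations summarized
#' as mean and (n-1) SD across subjects. Only strides flagged eligible enter
#' (propulsion requires a clean force plate). Each cell carries its
#' interpretation band; stride-by-stride cells also carry a significance
#' flag (p < 0.05).
#'
#' @param stride_tab A `stride_table` with propulsion columns (see
#'   [propulsion_for_strides()]).
#' @param min_subject_strides Minimum eligible strides for a subject to
#'   enter the within-subject scope.
#' @return A data.frame of class `correlation_report` with columns
#'   `indicator`, `system`, `target`, `scope`, `r`, `p`, `r_sd`, `n`,
#'   `interpretation`, `significant`.
#' @export
correlation_tables <- function(stride_tab, min_subject_strides = 3L) {
  tab <- stride_tab[stride_tab$eligible %in% TRUE, , drop = FALSE]
  if (nrow(tab) < 3L) stop("not enough eligible strides for correlation")
  rows <- list()
  for (ind in propulsion_indicators()) {
    for (sys in c("omcs", "imu")) {
      col <- paste(ind, sys, sep = "_")
      for (tgt in c("auc", "peak")) {
        tcol <- paste0("prop_", tgt)
        if (!col %in% names(tab)) {
          rows[[length(rows) + 1L]] <- data.frame(
            indicator = ind, system = sys, target = tgt,
            scope = "stride_by_stride", r = NA_real_, p = NA_real_,
            r_sd = NA_real_, n = 0L, interpretation = NA_character_,
            significant = NA)
          next
        }
        pr <- pearson_r(tab[[col]], tab[[tcol]])
        rows[[length(rows) + 1L]] <- data.frame(
          indicator = ind, system = sys, target = tgt,
          scope = "stride_by_stride", r = pr$r, p = pr$p, r_sd = NA_real_,
          n = pr$n, interpretation = classify_correlation(pr$r),
          significant = pr$p < 0.05)
        # within-subject: per-subject r, then mean +/- SD across subjects
        rs <- c()
        for (id in unique(tab$subject_id)) {
          i <- tab$subject_id == id
          if (sum(i) < min_subject_strides) next
          if (stats::sd(tab[[col]][i]) == 0 || stats::sd(tab[[tcol]][i]) == 0)
            next
          rs <- c(rs, pearson_r(tab[[col]][i], tab[[tcol]][i])$r)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          indicator = ind, system = sys, target = tgt,
          scope = "within_subject",
          r = if (length(rs)) mean(rs) else NA_real_,
          p = NA_real_,
          r_sd = if (length(rs) > 1) stats::sd(rs) else NA_real_,
          n = length(rs),
          interpretation = if (length(rs)) classify_correlation(mean(rs))
                           else NA_character_,
          significant = NA)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}
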