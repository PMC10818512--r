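# Forward propulsion from the anterior-posterior ground reaction force:
# braking-to-propulsion transition (BPT), body-weight-normalized area under
# the propulsive curve, propulsive peak, and stride eligibility ("only one
# foot on a single force plate").

#' Detect the braking-to-propulsion transition
#'
#' The BPT is the last zero crossing of the stance-windowed AP ground
#' reaction force from negative (braking) to positive (propulsive) before
#' terminal contact. If the force is positive throughout the stance the BPT
#' is the stance start; if it never becomes positive the stride has no
#' propulsive phase and `NA` is returned.
#'
#' @param ap_grf AP force over one stance window (force-rate samples, N or
#'   BW).
#' @return Index of the BPT within the window, or `NA` (no propulsive
#'   phase).
#' @export
detect_bpt <- function(ap_grf) {
  n <- length(ap_grf)
  pos <- which(ap_grf > 0)
  if (length(pos) == 0L) return(NA_integer_)
  neg_before <- which(ap_grf[seq_len(max(pos))] < 0)
  if (length(neg_before) == 0L) return(1L)
  # last negative->positive transition
  k <- max(neg_before)
  up <- which(ap_grf[k:n] > 0)
  if (length(up) == 0L) return(NA_integer_)
  as.integer(k + up[1] - 1L)
}

#' Body-weight-normalized propulsion area under the curve
#'
#' Trapezoidal integral of the AP ground reaction force divided by body
#' weight, from the braking-to-propulsion transition until terminal
#' contact, with `dt = 1/fs_force`. Units: BW s.
#'
#' @param ap_grf AP force over one stance window (N).
#' @param bpt,tc Window bounds (force-rate sample indices within `ap_grf`,
#'   `bpt < tc`).
#' @param body_weight Body weight (N).
#' @param fs_force Force sample rate (Hz).
#' @return The normalized integral (BW s).
#' @export
propulsion_auc <- function(ap_grf, bpt, tc, body_weight, fs_force) {
  if (is.na(bpt) || is.na(tc) || bpt >= tc) stop("inverted propulsion window")
  if (body_weight <= 0) stop("body_weight must be positive")
  pracma::trapz(seq.int(bpt, tc) / fs_force, ap_grf[bpt:tc] / body_weight)
}

#' Peak body-weight-normalized propulsion
#'
#' Maximum of the BW-normalized AP ground reaction force between the
#' braking-to-propulsion transition and terminal contact. Dimensionless
#' (BW).
#'
#' @inheritParams propulsion_auc
#' @export
propulsion_peak <- function(ap_grf, bpt, tc, body_weight) {
  if (is.na(bpt) || is.na(tc) || bpt >= tc) stop("inverted propulsion window")
  if (body_weight <= 0) stop("body_weight must be positive")
  max(ap_grf[bpt:tc]) / body_weight
}

#' Stride eligibility: one foot on a single force plate
#'
#' A stride is eligible for propulsion analysis only if its foot's own plate
#' carries the stance load, no foreign load appears on that plate during the
#' stride's swing, and the contralateral foot demonstrably loads the other
#' plate during the double-support portions of the stance. Strides where
#' both feet share one plate fail these checks. Low-level crosstalk below
#' `threshold` (default 20 N, a typical plate noise floor) is ignored.
#'
#' @param own_vert Vertical force of the stride's own plate (full series,
#'   force rate, N).
#' @param contra_vert Vertical force of the other plate (N).
#' @param stance Force-rate index window `c(ic, tc)` of the stride's stance.
#' @param cycle Force-rate index window `c(ic, next_ic)` of the full stride.
#' @param contra_stance Optional list of the contralateral side's stance
#'   windows (force rate) used for the double-support checks.
#' @param threshold Load threshold (N).
#' @param body_weight Body weight (N), used for the own-load check.
#' @return Logical: is the stride eligible?
#' @export
stride_eligibility <- function(own_vert, contra_vert, stance, cycle,
                               contra_stance = NULL, threshold = 20,
                               body_weight = NULL) {
  n <- length(own_vert)
  w <- function(a, b) seq.int(max(1L, a), min(n, b))
  # (i) the stance foot loads its own plate throughout mid-stance (the
  # 35-65% stretch of stance is single support, so a displaced or swapped
  # stance cannot mimic it)
  min_load <- if (is.null(body_weight)) 10 * threshold else 0.3 * body_weight
  len <- stance[2] - stance[1]
  mid <- w(stance[1] + round(0.35 * len), stance[2] - round(0.35 * len))
  if (length(mid) < 2L || min(own_vert[mid]) < min_load) return(FALSE)
  # (ii) no foreign load on the own plate during the swing of this stride
  sw <- c(stance[2], cycle[2])
  shrink <- round(0.1 * (sw[2] - sw[1]))
  if (sw[2] - shrink > sw[1] + shrink &&
      max(own_vert[w(sw[1] + shrink, sw[2] - shrink)]) >= threshold)
    return(FALSE)
  # (iii) during double support the contralateral foot is on the other plate
  if (!is.null(contra_stance)) {
    for (cs in contra_stance) {
      a <- max(stance[1], cs[1])
      b <- min(stance[2], cs[2])
      if (b - a < 5L) next
      sh <- round(0.25 * (b - a))
      if (max(contra_vert[w(a + sh, b - sh)]) < threshold) return(FALSE)
    }
  }
  TRUE
}

#' Propulsion measures for every stride of a stride table
#'
#' For each row of a [build_stride_table()] output, windows the AP force of
#' the stride's own plate by the optical stance (gold-standard events mapped
#' to the force rate), detects the BPT, integrates the BW-normalized
#' propulsion AUC, extracts the peak, and flags eligibility.
#'
#' @param trial A filtered [gait_trial()].
#' @param stride_tab A `stride_table`.
#' @param threshold Crosstalk threshold (N) for [stride_eligibility()].
#' @return `stride_tab` with added columns `bpt_idx`, `prop_auc`,
#'   `prop_peak`, `eligible`.
#' @export
propulsion_for_strides <- function(trial, stride_tab, threshold = 20) {
  ratio <- round(trial$meta$fs_force / trial$meta$fs_motion)
  bw <- trial$meta$body_weight
  fsf <- trial$meta$fs_force
  nf <- nrow(trial$forces$L)
  stride_tab$bpt_idx <- NA_integer_
  stride_tab$prop_auc <- NA_real_
  stride_tab$prop_peak <- NA_real_
  stride_tab$eligible <- FALSE
  if (nrow(stride_tab) == 0L) return(stride_tab)
  to_f <- function(i) pmin(nf, pmax(1L, (i - 1L) * ratio + 1L))
  for (r in seq_len(nrow(stride_tab))) {
    s <- stride_tab$side[r]
    contra <- if (s == "L") "R" else "L"
    ic_f <- to_f(stride_tab$ic_omcs[r])
    tc_f <- to_f(stride_tab$tc_omcs[r])
    # full cycle end: next ipsilateral IC (from table ordering), else
    # extrapolate one stance length past TC
    same <- which(stride_tab$side == s)
    pos <- match(r, same)
    nic_f <- if (!is.na(pos) && pos < length(same))
      to_f(stride_tab$ic_omcs[same[pos + 1L]]) else
        min(nf, tc_f + (tc_f - ic_f))
    ap <- trial$forces[[s]][ic_f:tc_f, "fy"]
    bpt <- detect_bpt(ap)
    contra_st <- lapply(which(stride_tab$side == contra &
                                stride_tab$ic_omcs < stride_tab$tc_omcs[r] + ratio &
                                stride_tab$tc_omcs > stride_tab$ic_omcs[r] - ratio),
                        function(j) c(to_f(stride_tab$ic_omcs[j]),
                                      to_f(stride_tab$tc_omcs[j])))
    elig <- stride_eligibility(trial$forces[[s]][, "fz"],
                               trial$forces[[contra]][, "fz"],
                               c(ic_f, tc_f), c(ic_f, nic_f),
                               contra_st, threshold, bw)
    if (!is.na(bpt) && bpt < length(ap)) {
      stride_tab$bpt_idx[r] <- ic_f + bpt - 1L
      stride_tab$prop_auc[r] <- propulsion_auc(ap, bpt, length(ap), bw, fsf)
      stride_tab$prop_peak[r] <- propulsion_peak(ap, bpt, length(ap), bw)
    } else {
      elig <- FALSE  # no propulsive phase on this plate
    }
    stride_tab$eligible[r] <- elig
  }
  stride_tab
}
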