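#' Centre-of-pressure trajectory from plate moments
#'
#' Computes the planar COP from the vertical force and the frontal/sagittal
#' moments, using the plate convention with origin at the plate surface:
#' `COP_x = -My / Fz` (x mediolateral), `COP_y = Mx / Fz` (y
#' anteroposterior). Samples where the vertical load falls below
#' `load_threshold` are flagged invalid (COP is undefined on an unloaded
#' plate) and set to `NA` so they never enter extrema.
#'
#' @param trial A `gi_trial` (see [simulate_trial()], [read_trial_csv()]).
#' @param load_threshold Minimum vertical force (N) for a valid COP sample.
#' @return Tibble with columns `t`, `cop_x`, `cop_y`, `valid`.
#' @export
compute_cop <- function(trial, load_threshold = 10) {
  stopifnot(inherits(trial, "gi_trial"))
  d <- trial$data
  valid <- is.finite(d$Fz) & d$Fz >= load_threshold
  tibble(
    t = d$t,
    cop_x = ifelse(valid, -d$My / d$Fz, NA_real_),
    cop_y = ifelse(valid, d$Mx / d$Fz, NA_real_),
    valid = valid)
}

#' Centre-of-mass kinematics from ground-reaction forces
#'
#' The horizontal COM acceleration follows from Newton's second law,
#' `a = F / mass`, applied to the recorded shear forces (y anteroposterior,
#' x mediolateral). Velocity is the cumulative trapezoidal integral of the
#' acceleration with the integration constant fixed by quiet standing:
#' `v(t0) = 0`. When `t0` is supplied, the mean horizontal force over the
#' preceding baseline is removed first, so static offsets do not integrate
#' into a spurious drift.
#'
#' @param trial A `gi_trial`.
#' @param t0 Gait-initiation onset time (s) at which velocity is pinned to
#'   zero; defaults to the first sample.
#' @param baseline_correct Subtract the pre-`t0` mean of each horizontal
#'   force channel before integrating?
#' @return Tibble with `t`, `a_ap`, `a_ml` (m/s^2), `v_ap`, `v_ml` (m/s).
#' @export
com_kinematics <- function(trial, t0 = NULL, baseline_correct = TRUE) {
  stopifnot(inherits(trial, "gi_trial"))
  if (is.null(trial$mass) || !is.finite(trial$mass) || trial$mass <= 0) {
    abort("`trial$mass` must be a positive number of kilograms.")
  }
  d <- trial$data
  fy <- d$Fy
  fx <- d$Fx
  i0 <- 1L
  if (!is.null(t0)) {
    if (t0 < d$t[1] || t0 > d$t[nrow(d)]) abort("`t0` outside the recording.")
    i0 <- which.min(abs(d$t - t0))
    if (baseline_correct && i0 > 1L) {
      fy <- fy - mean(fy[seq_len(i0 - 1L)])
      fx <- fx - mean(fx[seq_len(i0 - 1L)])
    }
  }
  a_ap <- fy / trial$mass
  a_ml <- fx / trial$mass
  v_ap <- cumtrapz(d$t, a_ap)
  v_ml <- cumtrapz(d$t, a_ml)
  tibble(t = d$t,
         a_ap = a_ap, a_ml = a_ml,
         v_ap = v_ap - v_ap[i0],
         v_ml = v_ml - v_ml[i0])
}
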