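#' Extract the 11 gait-initiation variables from a trial
#'
#' Computes the registry features ([gi_features()]) from one force-plate
#' recording and its event landmarks:
#'
#' * APA durations per axis: from each COP axis' own onset (same sustained
#'   deviation rule as [detect_events()]) to heel-off, so the mediolateral
#'   and anteroposterior APAs can differ;
#' * COP shifts: maximal absolute COP displacement from baseline per axis
#'   within the APA window `[t0, ho]`;
#' * COM velocities: anteroposterior at heel-off, toe-off and heel
#'   contact, mediolateral at heel-off and toe-off, from [com_kinematics()]
#'   with `v(t0) = 0`;
#' * `foot_lift = to - ho`;
#' * `fz_peak`: maximum vertical force within +/- `peak_window_s` of heel
#'   contact.
#'
#' @param trial A `gi_trial`.
#' @param events A `gi_events` (or named vector with `t0`, `ho`, `to`,
#'   `hc`); detected automatically when `NULL`.
#' @param fc,order Zero-phase low-pass settings applied before extraction;
#'   `fc = NULL` uses the raw signals.
#' @param k_sigma,min_sustain_ms Per-axis COP onset rule (see
#'   [detect_events()]).
#' @param peak_window_s Half-width (s) of the search window for the
#'   heel-contact force peak.
#' @return A one-row tibble with the 11 registry columns.
#' @export
#' @examples
#' trial <- simulate_trial(trial_spec(noise_sd = 0))
#' extract_features(trial, fc = NULL)
extract_features <- function(trial, events = NULL, fc = 10, order = 2,
                             k_sigma = 2.5, min_sustain_ms = 50,
                             peak_window_s = 0.15) {
  stopifnot(inherits(trial, "gi_trial"))
  if (is.null(events)) {
    events <- detect_events(trial, fc = fc, order = order,
                            k_sigma = k_sigma,
                            min_sustain_ms = min_sustain_ms)
  }
  ev <- validate_events(unclass(events))
  d0 <- trial$data
  if (ev["t0"] < d0$t[1] || ev["hc"] > d0$t[nrow(d0)]) {
    abort("Events fall outside the recording span.")
  }

  ft <- filter_trial(trial, fc, order)
  d <- ft$data
  idx_of <- function(time) which.min(abs(d$t - time))
  i_t0 <- idx_of(ev["t0"])
  i_ho <- idx_of(ev["ho"])
  i_to <- idx_of(ev["to"])
  i_hc <- idx_of(ev["hc"])

  cop <- compute_cop(ft)
  base_idx <- seq_len(max(i_t0 - 1L, 2L))
  sustain_n <- max(1L, round(min_sustain_ms / 1000 * ft$fs))

  axis_apa <- function(x) {
    i_on <- cop_onset(x, base_idx, k_sigma, sustain_n, to = i_ho)
    if (is.na(i_on)) {
      warn("COP axis shows no onset before heel-off; using t0 for its APA.")
      i_on <- i_t0
    }
    d$t[i_ho] - d$t[i_on]
  }
  apa_ml <- axis_apa(cop$cop_x)
  apa_ap <- axis_apa(cop$cop_y)

  win <- i_t0:i_ho
  shift_of <- function(x) {
    max(abs(x[win] - mean(x[base_idx], na.rm = TRUE)), na.rm = TRUE)
  }
  cop_shift_ml <- shift_of(cop$cop_x)
  cop_shift_ap <- shift_of(cop$cop_y)

  kin <- com_kinematics(ft, t0 = ev[["t0"]])

  peak_win <- which(abs(d$t - ev["hc"]) <= peak_window_s)
  fz_peak <- max(d$Fz[peak_win])

  out <- tibble(
    apa_ml = apa_ml, apa_ap = apa_ap,
    cop_shift_ap = cop_shift_ap, cop_shift_ml = cop_shift_ml,
    v_com_ap_ho = kin$v_ap[i_ho], v_com_ap_to = kin$v_ap[i_to],
    v_com_ap_hc = kin$v_ap[i_hc],
    v_com_ml_ho = kin$v_ml[i_ho], v_com_ml_to = kin$v_ml[i_to],
    foot_lift = unname(ev["to"] - ev["ho"]),
    fz_peak = fz_peak)
  if (out$foot_lift <= 0) abort("Invalid features: foot_lift must be > 0.")
  if (out$fz_peak <= 0) abort("Invalid features: fz_peak must be > 0.")
  out[gi_features()]
}
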