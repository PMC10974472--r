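#' The gait-initiation feature registry
#'
#' Names (and units) of the eleven kinetic variables the package extracts
#' from one gait-initiation trial and analyses cohort-wide:
#'
#' * `apa_ml`, `apa_ap` — anticipatory postural adjustment durations on the
#'   mediolateral and anteroposterior centre-of-pressure axes (s), measured
#'   from each axis' own onset to swing heel-off;
#' * `cop_shift_ap`, `cop_shift_ml` — maximal absolute COP displacement per
#'   axis during the APA window (m);
#' * `v_com_ap_ho`, `v_com_ap_to`, `v_com_ap_hc` — anteroposterior
#'   centre-of-mass velocity at heel-off, toe-off and heel contact (m/s);
#' * `v_com_ml_ho`, `v_com_ml_to` — mediolateral COM velocity at heel-off
#'   and toe-off (m/s);
#' * `foot_lift` — duration between heel-off and toe-off (s);
#' * `fz_peak` — vertical ground-reaction force peak at heel contact (N).
#'
#' The registry is the column contract shared by the synthetic cohort
#' generator, the trial feature extractor and the PCA front end.
#'
#' @return Character vector of the 11 feature names, in canonical order.
#' @export
#' @examples
#' gi_features()
gi_features <- function() {
  c("apa_ml", "apa_ap", "cop_shift_ap", "cop_shift_ml",
    "v_com_ap_ho", "v_com_ap_to", "v_com_ap_hc",
    "v_com_ml_ho", "v_com_ml_to",
    "foot_lift", "fz_peak")
}

#' Units of the registry features
#' @return Named character vector mapping feature name to SI unit.
#' @export
gi_feature_units <- function() {
  c(apa_ml = "s", apa_ap = "s", cop_shift_ap = "m", cop_shift_ml = "m",
    v_com_ap_ho = "m/s", v_com_ap_to = "m/s", v_com_ap_hc = "m/s",
    v_com_ml_ho = "m/s", v_com_ml_to = "m/s",
    foot_lift = "s", fz_peak = "N")
}

# standard gravity used throughout (m/s^2)
GRAVITY <- 9.81
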