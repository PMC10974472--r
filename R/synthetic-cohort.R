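#' Specify a synthetic two-group gait-initiation cohort
#'
#' Defines the population model from which [simulate_cohort()] draws: two
#' multivariate-normal groups ("control" and "pd") over the 11-variable
#' feature registry ([gi_features()]), sharing a covariance matrix. The
#' default group difference is concentrated on the variables that drive the
#' leading principal components of gait-initiation data — the vertical force
#' peak at heel contact, the anteroposterior centre-of-mass velocities and
#' the anticipatory-postural-adjustment durations — with smaller shifts
#' elsewhere. `effect` scales that whole difference profile (1 = default
#' separation, 0 = identical populations).
#'
#' @param n_control,n_pd Participants per group (each at least 2).
#' @param effect Multiplier on the default control-vs-pd mean difference.
#'   Ignored for a variable whose mean is supplied explicitly in
#'   `feature_means_pd`.
#' @param feature_means_control,feature_means_pd Optional named numeric
#'   vectors of per-variable population means (units per
#'   [gi_feature_units()]); defaults are field-plausible values for healthy
#'   seniors and Parkinsonian patients off medication.
#' @param covariance Optional 11 x 11 symmetric positive semi-definite
#'   covariance matrix shared by both groups; the default combines
#'   per-variable SDs of roughly 10-15\% of the control means with moderate
#'   physiological correlations (APA durations, COM velocities).
#' @param seed Integer seed making [simulate_cohort()] deterministic.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' simulate_cohort(spec)
cohort_spec <- function(n_control = 10, n_pd = 10, effect = 1,
                        feature_means_control = NULL,
                        feature_means_pd = NULL,
                        covariance = NULL, seed = NULL) {
  feats <- gi_features()
  p <- length(feats)
  if (n_control < 2 || n_pd < 2) {
    abort("Each group needs at least 2 participants.")
  }

  mu_c <- c(apa_ml = 0.55, apa_ap = 0.45,
            cop_shift_ap = 0.040, cop_shift_ml = 0.060,
            v_com_ap_ho = 0.15, v_com_ap_to = 0.35, v_com_ap_hc = 0.85,
            v_com_ml_ho = 0.10, v_com_ml_to = 0.12,
            foot_lift = 0.20, fz_peak = 850)
  # control - pd difference profile at effect = 1: PD gait initiation is
  # slower (longer APAs), hypometric (smaller COP shifts and COM
  # velocities) and lands more softly (smaller Fz peak).
  delta <- c(apa_ml = 0.10, apa_ap = 0.10,
             cop_shift_ap = -0.010, cop_shift_ml = -0.015,
             v_com_ap_ho = -0.05, v_com_ap_to = -0.10, v_com_ap_hc = -0.25,
             v_com_ml_ho = -0.02, v_com_ml_to = -0.02,
             foot_lift = 0.05, fz_peak = -130)

  if (!is.null(feature_means_control)) {
    mu_c[names(feature_means_control)] <- feature_means_control
  }
  mu_p <- mu_c + effect * delta
  if (!is.null(feature_means_pd)) {
    mu_p[names(feature_means_pd)] <- feature_means_pd
  }
  if (length(mu_c) != p || length(mu_p) != p ||
      !setequal(names(mu_c), feats)) {
    abort("Mean vectors must cover exactly the 11-feature registry.")
  }

  if (is.null(covariance)) covariance <- default_cohort_covariance()
  check_psd(covariance, "covariance")
  if (!identical(dim(covariance), c(p, p))) {
    abort(sprintf("`covariance` must be %d x %d.", p, p))
  }
  dimnames(covariance) <- list(feats, feats)

  structure(
    list(n_control = as.integer(n_control), n_pd = as.integer(n_pd),
         feature_means_control = mu_c[feats], feature_means_pd = mu_p[feats],
         covariance = covariance, effect = effect, seed = seed),
    class = "cohort_spec")
}

# Default shared covariance: per-variable SDs combined with a moderate
# physiological correlation structure (verified PSD; smallest eigenvalue of
# the correlation matrix is ~0.10).
default_cohort_covariance <- function() {
  feats <- gi_features()
  sds <- c(apa_ml = 0.08, apa_ap = 0.07,
           cop_shift_ap = 0.008, cop_shift_ml = 0.012,
           v_com_ap_ho = 0.03, v_com_ap_to = 0.06, v_com_ap_hc = 0.12,
           v_com_ml_ho = 0.02, v_com_ml_to = 0.025,
           foot_lift = 0.03, fz_peak = 60)[feats]
  R <- diag(length(feats))
  dimnames(R) <- list(feats, feats)
  setr <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  setr("apa_ml", "apa_ap", 0.5)
  setr("v_com_ap_ho", "v_com_ap_to", 0.7)
  setr("v_com_ap_ho", "v_com_ap_hc", 0.5)
  setr("v_com_ap_to", "v_com_ap_hc", 0.7)
  setr("v_com_ml_ho", "v_com_ml_to", 0.6)
  setr("cop_shift_ap", "v_com_ap_ho", 0.4)
  setr("cop_shift_ap", "apa_ap", 0.3)
  setr("cop_shift_ml", "apa_ml", 0.3)
  setr("cop_shift_ml", "v_com_ml_ho", 0.35)
  setr("foot_lift", "v_com_ap_to", -0.25)
  setr("foot_lift", "apa_ml", 0.2)
  setr("foot_lift", "apa_ap", 0.2)
  setr("fz_peak", "v_com_ap_hc", 0.45)
  setr("fz_peak", "v_com_ap_to", 0.3)
  diag(sds) %*% R %*% diag(sds)
}

#' Draw a synthetic cohort feature table
#'
#' Samples `n_control + n_pd` participants from the two multivariate-normal
#' populations of a [cohort_spec()]. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `participant_id`, `group`
#'   (`"control"`/`"pd"`) and the 11 registry features.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  feats <- gi_features()
  draw <- function(n, mu) {
    x <- MASS::mvrnorm(n, mu = mu[feats], Sigma = spec$covariance)
    if (n == 1L) x <- matrix(x, nrow = 1)
    colnames(x) <- feats
    x
  }
  with_seed(spec$seed, {
    xc <- draw(spec$n_control, spec$feature_means_control)
    xp <- draw(spec$n_pd, spec$feature_means_pd)
    dplyr::bind_rows(
      dplyr::mutate(as_tibble(xc), group = "control"),
      dplyr::mutate(as_tibble(xp), group = "pd")
    ) |>
      dplyr::mutate(
        participant_id = sprintf("P%02d", dplyr::row_number()),
        .before = 1
      ) |>
      dplyr::relocate("group", .after = "participant_id")
  })
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d control + %d pd participants, effect = %g, seed = %s\n",
    x$n_control, x$n_pd, x$effect,
    if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
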