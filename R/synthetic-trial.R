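#' Specify a synthetic force-plate gait-initiation trial
#'
#' Defines the deterministic waveform model from which [simulate_trial()]
#' builds a six-channel force-plate recording (Fx, Fy, Fz, Mx, My, Mz).
#' The trial reproduces the canonical phases of gait initiation:
#'
#' 1. quiet standing up to `t0` (Fz = mass * g, centre of pressure at its
#'    origin, zero horizontal force);
#' 2. the anticipatory postural adjustment between `t0` and heel-off `ho`:
#'    the COP ramps mediolaterally toward the swing side (amplitude
#'    `cop_ml`) and posteriorly (amplitude `cop_ap`, starting `apa_ap`
#'    seconds before heel-off), while the centre of mass accelerates;
#' 3. foot lift between `ho` and toe-off `to`: the vertical load falls by
#'    `unload_frac` of body weight;
#' 4. step execution, ending in a vertical force peak of `fz_peak` newtons
#'    exactly at heel contact `hc`.
#'
#' All phase transitions are raised-cosine, so the waveform is smooth and
#' essentially band-limited below the 10 Hz cut-off used downstream.
#' Horizontal forces are derived analytically from piecewise raised-cosine
#' centre-of-mass velocity profiles hitting the configured velocities at the
#' events; moments are derived from the COP convention `COP_x = -My / Fz`,
#' `COP_y = Mx / Fz` (x mediolateral, y anteroposterior, z vertical up).
#'
#' @param duration Trial length (s).
#' @param fs Sampling rate (Hz); must exceed twice the downstream filter
#'   cut-off.
#' @param mass Participant mass (kg).
#' @param t0,ho,to,hc Event times (s): gait-initiation onset, swing
#'   heel-off, swing toe-off, swing heel contact; must satisfy
#'   `0 < t0 < ho < to < hc < duration`.
#' @param cop_ap,cop_ml APA COP excursion amplitudes (m).
#' @param apa_ap Anteroposterior APA duration (s); the AP COP onset is at
#'   `ho - apa_ap`, so `apa_ap <= ho - t0` (the mediolateral onset defines
#'   `t0`).
#' @param v_ap COM anteroposterior velocities at `c(ho, to, hc)` (m/s).
#' @param v_ml COM mediolateral velocities at `c(ho, to)` (m/s); returns to
#'   zero at heel contact.
#' @param unload_frac Fraction of body weight shed during foot lift.
#' @param fz_peak Vertical force peak at heel contact (N); default
#'   `1.15 * mass * 9.81`.
#' @param rise_dur Duration of the loading rise ending at the heel-contact
#'   peak (s); must fit between `to` and `hc`.
#' @param noise_sd Gaussian noise SD added to the force channels (N);
#'   moments receive `0.25 * noise_sd` N m. Zero gives a noiseless trial.
#' @param seed Integer seed for the noise stream.
#'
#' @return An object of class `trial_spec`.
#' @seealso [simulate_trial()]
#' @export
trial_spec <- function(duration = 3, fs = 500, mass = 75,
                       t0 = 1.0, ho = 1.55, to = 1.75, hc = 2.15,
                       cop_ap = 0.040, cop_ml = 0.060, apa_ap = 0.45,
                       v_ap = c(ho = 0.15, to = 0.35, hc = 0.85),
                       v_ml = c(ho = 0.10, to = 0.12),
                       unload_frac = 0.12, fz_peak = NULL,
                       rise_dur = 0.15, noise_sd = 1.0, seed = NULL) {
  if (!(0 < t0 && t0 < ho && ho < to && to < hc && hc < duration)) {
    abort("Event times must satisfy 0 < t0 < ho < to < hc < duration.")
  }
  if (fs <= 20) abort("`fs` must exceed twice the 10 Hz filter cut-off.")
  if (mass <= 0) abort("`mass` must be positive.")
  if (apa_ap <= 0 || apa_ap > ho - t0 + 1e-12) {
    abort("`apa_ap` must lie in (0, ho - t0].")
  }
  if (rise_dur <= 0 || rise_dur > hc - to) {
    abort("`rise_dur` must fit between toe-off and heel contact.")
  }
  if (unload_frac <= 0 || unload_frac >= 1) {
    abort("`unload_frac` must be in (0, 1).")
  }
  fz_peak <- fz_peak %||% (1.15 * mass * GRAVITY)
  if (fz_peak <= mass * GRAVITY) {
    abort("`fz_peak` must exceed the body weight mass * g.")
  }
  structure(
    list(duration = duration, fs = fs, mass = mass,
         events = c(t0 = t0, ho = ho, to = to, hc = hc),
         cop_ap = cop_ap, cop_ml = cop_ml, apa_ap = apa_ap,
         v_ap = v_ap, v_ml = v_ml, unload_frac = unload_frac,
         fz_peak = fz_peak, rise_dur = rise_dur,
         noise_sd = noise_sd, seed = seed),
    class = "trial_spec")
}

# raised cosine ramp: 0 at s = 0, 1 at s = 1, zero slope at both ends
rcos <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2

# piecewise raised-cosine interpolation through (knots, values); flat
# outside; returns the value and the analytic time derivative
rcos_path <- function(t, knots, values) {
  v <- rep(values[1], length(t))
  dv <- rep(0, length(t))
  for (j in seq_len(length(knots) - 1)) {
    ta <- knots[j]; tb <- knots[j + 1]
    sel <- t >= ta & t < tb
    s <- (t[sel] - ta) / (tb - ta)
    v[sel] <- values[j] + (values[j + 1] - values[j]) * rcos(s)
    dv[sel] <- (values[j + 1] - values[j]) * pi / (2 * (tb - ta)) * sin(pi * s)
  }
  v[t >= knots[length(knots)]] <- values[length(values)]
  list(value = v, deriv = dv)
}

#' Simulate a force-plate gait-initiation trial
#'
#' Builds the six-channel recording described by a [trial_spec()], plus the
#' ground-truth events and feature values it was constructed from, for use
#' in recovery tests of the extraction chain.
#'
#' @param spec A [trial_spec()].
#' @return A `gi_trial`: a list with `data` (tibble of `t`, `Fx`, `Fy`,
#'   `Fz`, `Mx`, `My`, `Mz`; SI units), `fs`, `mass`, and `truth` holding
#'   the event times, the noiseless COP trajectory and the one-row tibble of
#'   ground-truth registry features.
#' @export
#' @examples
#' trial <- simulate_trial(trial_spec(noise_sd = 0))
#' head(trial$data)
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  ev <- spec$events
  t <- seq(0, spec$duration, by = 1 / spec$fs)
  mg <- spec$mass * GRAVITY

  # vertical load: quiet stance, unloading ramp HO -> TO, single-support
  # plateau, loading rise peaking exactly at HC, recovery to body weight
  rise_start <- ev["hc"] - spec$rise_dur
  plateau <- mg * (1 - spec$unload_frac)
  fz <- rep(mg, length(t))
  fz <- ifelse(t >= ev["ho"] & t < ev["to"],
               mg - (mg - plateau) * rcos((t - ev["ho"]) / (ev["to"] - ev["ho"])),
               fz)
  fz[t >= ev["to"] & t < rise_start] <- plateau
  sel <- t >= rise_start & t < ev["hc"]
  fz[sel] <- plateau + (spec$fz_peak - plateau) *
    rcos((t[sel] - rise_start) / spec$rise_dur)
  rec_end <- min(ev["hc"] + 0.15, spec$duration)
  sel <- t >= ev["hc"] & t < rec_end
  fz[sel] <- spec$fz_peak - (spec$fz_peak - mg) *
    rcos((t[sel] - ev["hc"]) / (rec_end - ev["hc"]))
  fz[t >= rec_end] <- mg

  # COP trajectories (m): ML ramps to +cop_ml at HO then transfers toward
  # the stance side; AP ramps posteriorly to -cop_ap then travels forward
  t0_ap <- ev["ho"] - spec$apa_ap
  cop_x <- rcos_path(t, c(ev["t0"], ev["ho"], ev["to"]),
                     c(0, spec$cop_ml, -0.3 * spec$cop_ml))$value
  cop_y <- rcos_path(t, c(t0_ap, ev["ho"], ev["hc"]),
                     c(0, -spec$cop_ap, 0.08))$value

  # COM velocity profiles and the horizontal forces that produce them
  vap <- rcos_path(t, c(ev["t0"], ev["ho"], ev["to"], ev["hc"]),
                   c(0, spec$v_ap[["ho"]], spec$v_ap[["to"]], spec$v_ap[["hc"]]))
  vml <- rcos_path(t, c(ev["t0"], ev["ho"], ev["to"], ev["hc"]),
                   c(0, spec$v_ml[["ho"]], spec$v_ml[["to"]], 0))
  fy <- spec$mass * vap$deriv          # anteroposterior force
  fx <- spec$mass * vml$deriv          # mediolateral force

  # moments from the plate convention COP_x = -My/Fz, COP_y = Mx/Fz
  my <- -cop_x * fz
  mx <- cop_y * fz
  mz <- rep(0, length(t))

  dat <- tibble(t = t, Fx = fx, Fy = fy, Fz = fz, Mx = mx, My = my, Mz = mz)
  if (spec$noise_sd > 0) {
    dat <- with_seed(spec$seed, {
      n <- nrow(dat)
      dplyr::mutate(dat,
        Fx = .data$Fx + rnorm(n, 0, spec$noise_sd),
        Fy = .data$Fy + rnorm(n, 0, spec$noise_sd),
        Fz = .data$Fz + rnorm(n, 0, spec$noise_sd),
        Mx = .data$Mx + rnorm(n, 0, 0.25 * spec$noise_sd),
        My = .data$My + rnorm(n, 0, 0.25 * spec$noise_sd))
    })
  }

  truth_features <- tibble(
    apa_ml = unname(ev["ho"] - ev["t0"]),
    apa_ap = spec$apa_ap,
    cop_shift_ap = spec$cop_ap,
    cop_shift_ml = spec$cop_ml,
    v_com_ap_ho = spec$v_ap[["ho"]],
    v_com_ap_to = spec$v_ap[["to"]],
    v_com_ap_hc = spec$v_ap[["hc"]],
    v_com_ml_ho = spec$v_ml[["ho"]],
    v_com_ml_to = spec$v_ml[["to"]],
    foot_lift = unname(ev["to"] - ev["ho"]),
    fz_peak = spec$fz_peak)

  structure(
    list(data = dat, fs = spec$fs, mass = spec$mass,
         truth = list(events = ev,
                      cop = tibble(t = t, cop_x = cop_x, cop_y = cop_y),
                      features = truth_features),
         spec = spec),
    class = "gi_trial")
}

#' @export
print.gi_trial <- function(x, ...) {
  cat(sprintf("<gi_trial> %.2f s at %g Hz, mass %g kg, events t0/HO/TO/HC = %s s\n",
              max(x$data$t), x$fs, x$mass,
              paste(format(x$truth$events), collapse = "/")))
  invisible(x)
}

#' Write / read a trial as CSV
#'
#' The on-disk schema is `t,Fx,Fy,Fz,Mx,My,Mz` (s, N, N m) with one header
#' line; ground-truth events go to a `<name>.events.csv` sidecar with
#' columns `event,time_s`.
#'
#' @param trial A `gi_trial`.
#' @param path Output CSV path.
#' @param events Write the ground-truth sidecar too?
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, events = TRUE) {
  stopifnot(inherits(trial, "gi_trial"))
  utils::write.csv(trial$data, path, row.names = FALSE, quote = FALSE)
  if (events && !is.null(trial$truth$events)) {
    ev <- data.frame(event = names(trial$truth$events),
                     time_s = unname(trial$truth$events))
    utils::write.csv(ev, sub("\\.csv$", ".events.csv", path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @param mass Participant mass (kg), needed for COM kinematics.
#' @param fs Sampling rate; inferred from the time column when `NULL`.
#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path, mass, fs = NULL) {
  dat <- as_tibble(utils::read.csv(path))
  need <- c("t", "Fx", "Fy", "Fz", "Mx", "My", "Mz")
  if (!all(need %in% names(dat))) {
    abort(sprintf("Trial CSV must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  fs <- fs %||% (1 / stats::median(diff(dat$t)))
  truth <- NULL
  sidecar <- sub("\\.csv$", ".events.csv", path)
  if (file.exists(sidecar)) {
    ev <- utils::read.csv(sidecar)
    truth <- list(events = stats::setNames(ev$time_s, ev$event))
  }
  structure(list(data = dat[need], fs = fs, mass = mass, truth = truth),
            class = "gi_trial")
}
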