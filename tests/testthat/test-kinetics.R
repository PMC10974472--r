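test_that("low-pass filter has unit DC gain and halves power at the cut-off", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  expect_equal(lowpass_filter(rep(3.7, length(t)), fs, 10), rep(3.7, length(t)))

  # forward-backward application squares the single-pass 1/sqrt(2) at fc
  x <- sin(2 * pi * 10 * t)
  y <- lowpass_filter(x, fs, fc = 10)
  mid <- t > 1 & t < 3   # away from the ends
  ratio <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_equal(ratio, 0.5, tolerance = 0.02)

  # far-band rejection: 100 Hz at least 40x down after the zero-phase pass
  hi <- sin(2 * pi * 100 * t)
  lo <- sin(2 * pi * 1 * t)
  y2 <- lowpass_filter(lo + hi, fs, fc = 10)
  resid <- y2[mid] - lowpass_filter(lo, fs, fc = 10)[mid]
  expect_lt(sqrt(mean(resid^2)), sqrt(mean(hi[mid]^2)) / 40)

  expect_error(lowpass_filter(x, fs, fc = 300), "Nyquist")
  expect_error(lowpass_filter(x, fs, fc = 10, order = 0), "order")
})

test_that("filtering is near-idempotent on band-limited signals", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  x <- 0.4 * sin(2 * pi * 1.5 * t) + 0.2 * cos(2 * pi * 0.7 * t)
  y <- lowpass_filter(x, fs, fc = 10)
  expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("COP follows the moment ratios and flags unloaded samples", {
  mk <- function(fz, mx, my) {
    structure(list(
      data = tibble::tibble(t = seq_along(fz) / 500, Fx = 0, Fy = 0,
                            Fz = fz, Mx = mx, My = my, Mz = 0),
      fs = 500, mass = 70), class = "gi_trial")
  }
  # point load at the plate origin
  cop <- compute_cop(mk(rep(700, 10), rep(0, 10), rep(0, 10)))
  expect_equal(cop$cop_x, rep(0, 10))
  expect_equal(cop$cop_y, rep(0, 10))
  # direct ratio: Fz = 700 N, Mx = 21 N m -> cop_y = 0.03 m
  cop <- compute_cop(mk(rep(700, 5), rep(21, 5), rep(0, 5)))
  expect_equal(cop$cop_y, rep(0.03, 5))
  # unloaded plate: invalid, excluded from extrema
  cop <- compute_cop(mk(c(700, 5, 700), c(21, 21, 21), c(0, 0, 0)))
  expect_equal(cop$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(cop$cop_y[2]))
})

test_that("COM kinematics obey Newton's law and the closed-form integrals", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  mass <- 80
  mk <- function(fy) structure(list(
    data = tibble::tibble(t = t, Fx = 0, Fy = fy, Fz = mass * 9.81,
                          Mx = 0, My = 0, Mz = 0),
    fs = fs, mass = mass), class = "gi_trial")

  # quiet standing: zero horizontal force -> zero velocity
  kin <- com_kinematics(mk(rep(0, length(t))), t0 = 1)
  expect_equal(kin$v_ap, rep(0, length(t)))

  # constant force from t0: v = c * (t - t0)
  cc <- 0.8
  fy <- ifelse(t >= 1, mass * cc, 0)
  kin <- com_kinematics(mk(fy), t0 = 1)
  post <- t >= 1
  # trapezoid smears one sample at the force step
  expect_equal(kin$v_ap[post], cc * (t[post] - 1), tolerance = 1e-3)
  # pinning v(t0) = 0 leaves the half-sample trapezoid of the step before t0
  expect_lt(max(abs(kin$v_ap[t <= 1 - 1 / fs])), 1e-3)

  # sinusoidal force: matches the analytic antiderivative to O(dt^2)
  w <- 2 * pi * 2
  fy <- ifelse(t >= 1, mass * sin(w * (t - 1)), 0)
  kin <- com_kinematics(mk(fy), t0 = 1)
  v_true <- ifelse(t >= 1, (1 - cos(w * (t - 1))) / w, 0)
  expect_lt(max(abs(kin$v_ap - v_true)), (w / 500)^2)

  bad <- mk(rep(0, length(t)))
  bad$mass <- -5
  expect_error(com_kinematics(bad), "mass")
})

test_that("velocity is invariant to a constant force offset after baseline correction", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  mass <- 80
  fy <- ifelse(t >= 1, mass * 0.5, 0)
  mk <- function(fy) structure(list(
    data = tibble::tibble(t = t, Fx = 0, Fy = fy, Fz = mass * 9.81,
                          Mx = 0, My = 0, Mz = 0),
    fs = fs, mass = mass), class = "gi_trial")
  v1 <- com_kinematics(mk(fy), t0 = 1)$v_ap
  v2 <- com_kinematics(mk(fy + 3.2), t0 = 1)$v_ap
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("events on a noiseless trial are recovered within one sample", {
  spec <- trial_spec(noise_sd = 0)
  tr <- simulate_trial(spec)
  ev <- detect_events(tr, fc = NULL)
  expect_true(all(abs(unclass(ev) - spec$events) <= 1 / spec$fs + 1e-12))
})

test_that("quiet standing yields no gait-initiation detection", {
  spec <- trial_spec(noise_sd = 0)
  tr <- simulate_trial(spec)
  pre <- tr$data$t < 0.9 * spec$events["t0"]
  quiet <- structure(list(data = tr$data[pre, ], fs = tr$fs, mass = tr$mass),
                     class = "gi_trial")
  expect_error(detect_events(quiet, fc = NULL), "no gait initiation")
})

test_that("noisy event detection keeps the median error below 10 ms", {
  errs <- purrr::map(1:20, function(s) {
    spec <- trial_spec(noise_sd = 1, seed = s)
    tr <- simulate_trial(spec)
    ev <- detect_events(tr)
    abs(unclass(ev) - spec$events) * 1000
  })
  expect_lte(stats::median(unlist(errs)), 10)
})

test_that("noiseless feature extraction reproduces the configured ground truth", {
  spec <- trial_spec(noise_sd = 0)
  tr <- simulate_trial(spec)
  f <- extract_features(tr, events = tr$truth$events, fc = NULL)
  truth <- tr$truth$features
  # durations to within one sample, amplitudes/velocities to fine tolerance
  for (v in c("apa_ml", "apa_ap", "foot_lift")) {
    expect_lt(abs(f[[v]] - truth[[v]]), 2 / spec$fs + 1e-12)
  }
  expect_equal(f$cop_shift_ap, truth$cop_shift_ap, tolerance = 1e-10)
  expect_equal(f$cop_shift_ml, truth$cop_shift_ml, tolerance = 1e-10)
  expect_equal(f$fz_peak, truth$fz_peak, tolerance = 1e-10)
  for (v in c("v_com_ap_ho", "v_com_ap_to", "v_com_ap_hc",
              "v_com_ml_ho", "v_com_ml_to")) {
    expect_equal(f[[v]], truth[[v]], tolerance = 1e-3)
  }
})

test_that("degenerate events are rejected by the feature invariants", {
  tr <- simulate_trial(trial_spec(noise_sd = 0))
  ev <- tr$truth$events
  bad <- c(t0 = ev[["t0"]], ho = ev[["to"]], to = ev[["to"]], hc = ev[["hc"]])
  expect_error(extract_features(tr, events = bad, fc = NULL), "ordering")
  outside <- c(t0 = 1, ho = 1.5, to = 1.7, hc = 99)
  expect_error(extract_features(tr, events = outside, fc = NULL), "span|outside")
})

test_that("the heel-contact peak feature is local: doubling it leaves others unchanged", {
  base <- trial_spec(noise_sd = 0)
  mg <- base$mass * 9.81
  peak1 <- mg * 1.15
  s1 <- trial_spec(noise_sd = 0, fz_peak = peak1)
  s2 <- trial_spec(noise_sd = 0, fz_peak = 2 * peak1)
  f1 <- extract_features(simulate_trial(s1), events = s1$events, fc = NULL)
  f2 <- extract_features(simulate_trial(s2), events = s2$events, fc = NULL)
  expect_equal(f2$fz_peak / f1$fz_peak, 2, tolerance = 1e-10)
  others <- setdiff(gi_features(), "fz_peak")
  expect_equal(f1[others], f2[others], tolerance = 1e-10)
})

test_that("feature extraction commutes with a rigid time shift", {
  shift <- 0.4
  s1 <- trial_spec(noise_sd = 0)
  s2 <- trial_spec(noise_sd = 0, duration = 3 + shift,
                   t0 = 1 + shift, ho = 1.55 + shift, to = 1.75 + shift,
                   hc = 2.15 + shift)
  f1 <- extract_features(simulate_trial(s1), events = s1$events, fc = NULL)
  f2 <- extract_features(simulate_trial(s2), events = s2$events, fc = NULL)
  expect_equal(as.data.frame(f1), as.data.frame(f2), tolerance = 1e-6)
})
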