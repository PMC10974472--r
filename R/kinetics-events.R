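#' Detect the four gait-initiation events
#'
#' Finds the temporal landmarks of gait initiation on a force-plate trial:
#'
#' * `t0` (onset): first sample where the centre of pressure deviates from
#'   its quiet-standing baseline by more than `k_sigma` baseline SDs on
#'   either axis, sustained for at least `min_sustain_ms`, then refined by
#'   backtracking to where the deviation emerges from the baseline noise
#'   floor;
#' * `ho` (swing heel-off): onset of the body-weight unloading ramp —
#'   located by finding the first drop of the vertical force below
#'   `(1 - unload_threshold)` of body weight after `t0` and backtracking to
#'   where the downward slope flattens out;
#' * `to` (swing toe-off): end of the same unloading ramp (slope
#'   flattening into the single-support plateau);
#' * `hc` (swing heel contact): location of the terminal vertical-force
#'   peak.
#'
#' Detection operates on zero-phase low-pass filtered channels (`fc`,
#' `order`); pass `fc = NULL` to detect on the raw signals, which is exact
#' for noise-free data (filtering smears onsets symmetrically in time).
#'
#' @param trial A `gi_trial`.
#' @param fc,order Low-pass cut-off (Hz) and order used before detection;
#'   `fc = NULL` disables filtering.
#' @param k_sigma COP deviation threshold in baseline SDs.
#' @param min_sustain_ms Minimum duration (ms) the COP deviation must be
#'   sustained to count as onset.
#' @param baseline_s Length (s) of the quiet-standing baseline window at
#'   the start of the recording.
#' @param unload_threshold Body-weight fraction whose loss marks the
#'   unloading ramp (default 5\%).
#' @param slope_frac Fraction of the maximum ramp slope below which the
#'   ramp is considered flat when locating its end points.
#' @return A named numeric vector of class `gi_events` with elements
#'   `t0`, `ho`, `to`, `hc` (s).
#' @export
detect_events <- function(trial, fc = 10, order = 2,
                          k_sigma = 2.5, min_sustain_ms = 50,
                          baseline_s = 0.5, unload_threshold = 0.05,
                          slope_frac = 0.02) {
  stopifnot(inherits(trial, "gi_trial"))
  ft <- filter_trial(trial, fc, order)
  d <- ft$data
  n <- nrow(d)
  base_idx <- which(d$t < baseline_s)
  if (length(base_idx) < 10L) {
    abort("Baseline window too short: need >= 10 quiet-standing samples.")
  }

  cop <- compute_cop(ft)
  sustain_n <- max(1L, round(min_sustain_ms / 1000 * ft$fs))
  ons <- c(
    cop_onset(cop$cop_x, base_idx, k_sigma, sustain_n),
    cop_onset(cop$cop_y, base_idx, k_sigma, sustain_n))
  ons <- ons[!is.na(ons)]
  if (length(ons) == 0L) abort("no gait initiation detected")
  i_t0 <- min(ons)

  fz <- d$Fz
  mg <- mean(fz[base_idx])
  lvl <- mg * (1 - unload_threshold)
  after <- which(fz < lvl & seq_len(n) > i_t0)
  if (length(after) == 0L) {
    abort("no gait initiation detected: vertical force never unloads")
  }
  cross <- after[1]

  dfz <- diff(fz)
  sd_d <- sd(dfz[base_idx[-length(base_idx)]])
  s_max <- abs(min(dfz[i_t0:cross]))
  eps <- max(slope_frac * s_max, 3 * sd_d, 1e-12)

  i_ho <- cross
  while (i_ho > i_t0 + 1L && dfz[i_ho - 1L] <= -eps) i_ho <- i_ho - 1L
  i_to <- cross
  while (i_to < n && dfz[i_to] <= -eps) i_to <- i_to + 1L

  i_hc <- i_to - 1L + which.max(fz[i_to:n])

  ev <- c(t0 = d$t[i_t0], ho = d$t[i_ho], to = d$t[i_to], hc = d$t[i_hc])
  validate_events(ev)
  structure(ev, class = "gi_events")
}

# first sustained deviation of a COP axis from its baseline, refined by
# backtracking to the noise floor; NA when the axis never leaves baseline
cop_onset <- function(x, base_idx, k_sigma, sustain_n, from = NULL, to = NULL) {
  mu <- mean(x[base_idx], na.rm = TRUE)
  s <- sd(x[base_idx], na.rm = TRUE)
  dev <- abs(x - mu)
  dev[is.na(dev)] <- 0
  thr <- max(k_sigma * s, 1e-9)
  n <- length(dev)
  lo <- from %||% (max(base_idx) + 1L)
  hi <- to %||% n
  ok <- dev > thr
  if (sustain_n > 1L) {
    cs <- c(0, cumsum(ok))
    idx <- lo:(hi - sustain_n + 1L)
    idx <- idx[idx >= 1L]
    hit <- idx[(cs[idx + sustain_n] - cs[idx]) == sustain_n]
  } else {
    hit <- which(ok[lo:hi]) + lo - 1L
  }
  if (length(hit) == 0L) return(NA_integer_)
  i <- hit[1]
  floor_thr <- max(0.5 * s, 1e-12)
  while (i > 1L && dev[i - 1L] > floor_thr) i <- i - 1L
  i
}

validate_events <- function(ev) {
  need <- c("t0", "ho", "to", "hc")
  if (!all(need %in% names(ev))) {
    abort("Events must contain t0, ho, to, hc.")
  }
  ev <- ev[need]
  if (any(diff(unname(ev)) <= 0)) {
    abort(sprintf(
      "Event ordering violated: need t0 < ho < to < hc, got %s.",
      paste(sprintf("%s=%.4g", need, ev), collapse = ", ")))
  }
  invisible(ev)
}

#' @export
print.gi_events <- function(x, ...) {
  cat("<gi_events> ",
      paste(sprintf("%s = %.3f s", names(x), unclass(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
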