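# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derivation: one global seed fans out to
# per-stage seeds without correlated streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(cohort = 101L, trial = 211L, boot_control = 307L,
               boot_pd = 401L, gmm = 503L, jaccard = 601L, misc = 701L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 997L
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

# Symmetric PSD check with a diagnostic naming the offending eigenvalue.
check_psd <- function(m, name = "covariance", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  floor_ok <- -tol * max(abs(ev), 1)
  if (any(ev < floor_ok)) {
    abort(sprintf(
      "`%s` is not positive semi-definite: smallest eigenvalue %.3e.",
      name, min(ev)))
  }
  invisible(ev)
}

# Cumulative trapezoidal integral of y over uniformly sampled t.
cumtrapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  dt <- diff(t)
  c(0, cumsum(dt * (y[-n] + y[-1]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
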