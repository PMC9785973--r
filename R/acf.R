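## Autocorrelation engine.
##
## For a set of scalar series x_s(t), t = 0..n-1, the lag-k estimate is
##   C(k) = sum_s sum_{t=0}^{n-1-k} x_s(t) x_s(t+k) / (n_series * (n-k))
## i.e. every frame is used as a time origin and the normalization is the
## exact count of origins contributing to each lag. "fft" evaluates the
## raw lag sums with a zero-padded FFT (exact up to roundoff), "direct"
## is the O(n^2) reference path; the two must agree to 1e-10 relative.

acf_raw_sums <- function(x, n_lags, method = c("fft", "direct")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_lags > n) abort("n_lags cannot exceed the series length")
  if (method == "direct") {
    out <- numeric(n_lags)
    for (k in 0:(n_lags - 1)) {
      out[k + 1] <- sum(x[1:(n - k), , drop = FALSE] *
                        x[(1 + k):n, , drop = FALSE])
    }
    return(out)
  }
  nfft <- nextn(2L * n, 2)
  total <- numeric(n_lags)
  # chunk columns to bound memory on wide inputs
  chunk <- max(1L, floor(2^23 / nfft))
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    cols <- j0:min(ncol(x), j0 + chunk - 1L)
    xp <- rbind(x[, cols, drop = FALSE],
                matrix(0, nfft - n, length(cols)))
    ft <- stats::mvfft(xp)
    ac <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / nfft
    total <- total + rowSums(ac[seq_len(n_lags), , drop = FALSE])
  }
  total
}

new_acf_series <- function(lags_fs, values, n_origins, normalized, kind) {
  out <- tibble(lag_fs = lags_fs, value = values, n_origins = as.integer(n_origins))
  attr(out, "normalized") <- normalized
  attr(out, "acf_kind") <- kind
  class(out) <- c("hydro_acf", class(out))
  out
}

#' Velocity autocorrelation function of an atom selection
#'
#' Estimates `Z(t) = <v_j(t0 + t) . v_j(t0)>`, averaged over all atoms
#' `j` in the selection and over every valid time origin `t0` in the
#' trajectory (or trajectory interval). With `normalize = TRUE` the
#' result is divided by `<v_j(0) . v_j(0)>` so that `Z(0) = 1` exactly;
#' the cosine transform of this normalized VACF is the vibrational
#' density of states.
#'
#' @param traj A `hydro_trajectory` with velocities.
#' @param atoms Integer atom ids to include (non-empty).
#' @param max_lag_fs Largest lag, fs. Default: half the interval span.
#' @param normalize Normalize to `Z(0) = 1` (default TRUE).
#' @param method `"fft"` (default) or the O(n^2) `"direct"` reference
#'   estimator; the two agree to 1e-10 relative.
#' @return A tibble of class `hydro_acf` with columns `lag_fs`, `value`
#'   and `n_origins` (time origins contributing to each lag).
#' @export
#' @examples
#' gas <- gen_ou_gas(n_atoms = 20, tau_fs = 50, kT_over_m = 1e-5,
#'                   dt_fs = 5, duration_fs = 2000, box = 30, seed = 1)
#' velocity_acf(gas$trajectory, atoms = gas$topology$atom_id, max_lag_fs = 250)
velocity_acf <- function(traj, atoms, max_lag_fs = NULL, normalize = TRUE,
                         method = c("fft", "direct")) {
  method <- match.arg(method)
  require_velocities(traj, "velocity_acf()")
  if (length(atoms) == 0) abort("empty atom selection")
  nf <- n_frames(traj)
  if (nf < 2) abort("velocity_acf() needs at least 2 frames")
  dt <- frame_dt(traj)
  span <- traj$times[nf] - traj$times[1]
  if (is.null(max_lag_fs)) max_lag_fs <- span / 2
  if (max_lag_fs >= span + dt / 2) {
    abort("max_lag_fs must be smaller than the interval span")
  }
  n_lags <- min(nf, floor(max_lag_fs / dt + 1e-9) + 1L)
  rows <- atom_rows(traj, atoms)
  # lay out one column per atom-component
  v <- traj$velocities[rows, , , drop = FALSE]
  m <- matrix(aperm(v, c(3, 1, 2)), nrow = nf)
  raw <- acf_raw_sums(m, n_lags, method = method)
  n_origins <- nf - 0:(n_lags - 1)
  z <- raw / (n_origins * length(rows))
  if (normalize) z <- z / z[1]
  new_acf_series((0:(n_lags - 1)) * dt, z, n_origins, normalize, "velocity")
}

#' Autocorrelation of a dipole-flux series
#'
#' Estimates the flux-flux ACF `<J(t0 + t) . J(t0)>` of a single
#' 3-vector time series (typically `J = dM/dt` from [dipole_flux()]),
#' averaged over all time origins. Unnormalized by default, since the
#' IR intensity scale carries the squared charges.
#'
#' @param flux A `hydro_flux` tibble from [dipole_flux()], or any data
#'   frame with columns `time_fs`, `Jx`, `Jy`, `Jz`.
#' @param max_lag_fs Largest lag, fs. Default: half the series span.
#' @param normalize Normalize to 1 at zero lag (default FALSE).
#' @inheritParams velocity_acf
#' @return A tibble of class `hydro_acf`.
#' @export
flux_acf <- function(flux, max_lag_fs = NULL, normalize = FALSE,
                     method = c("fft", "direct")) {
  method <- match.arg(method)
  need <- c("time_fs", "Jx", "Jy", "Jz")
  if (!all(need %in% names(flux))) {
    abort("flux must have columns time_fs, Jx, Jy, Jz")
  }
  nf <- nrow(flux)
  if (nf < 2) abort("flux_acf() needs at least 2 samples")
  check_uniform_times(flux$time_fs)
  dt <- flux$time_fs[2] - flux$time_fs[1]
  span <- flux$time_fs[nf] - flux$time_fs[1]
  if (is.null(max_lag_fs)) max_lag_fs <- span / 2
  if (max_lag_fs >= span + dt / 2) {
    abort("max_lag_fs must be smaller than the interval span")
  }
  n_lags <- min(nf, floor(max_lag_fs / dt + 1e-9) + 1L)
  m <- cbind(flux$Jx, flux$Jy, flux$Jz)
  raw <- acf_raw_sums(m, n_lags, method = method)
  n_origins <- nf - 0:(n_lags - 1)
  z <- raw / n_origins
  if (normalize) {
    if (z[1] == 0) abort("cannot normalize: zero-lag flux ACF is 0")
    z <- z / z[1]
  }
  new_acf_series((0:(n_lags - 1)) * dt, z, n_origins, normalize, "flux")
}
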