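test_that("VACF of perfectly correlated motion is 1 at every lag", {
  nf <- 50
  pos <- lapply(seq_len(nf), function(f) matrix(0.1 * f, 4, 3))
  vel <- lapply(seq_len(nf), function(f) matrix(rep(c(0.1, -0.2, 0.05), each = 4), 4, 3))
  traj <- make_traj(pos, vel)
  z <- velocity_acf(traj, atoms = 1:4, max_lag_fs = 20)
  expect_equal(z$value, rep(1, 21), tolerance = 1e-12)
  expect_identical(z$value[1], 1) # exact at zero lag
  expect_true(all(diff(z$n_origins) <= 0))
})

test_that("VACF of a cosine mode reproduces the cosine over many periods", {
  omega <- wavenumber_to_angular(1650)
  times <- 0:1999
  v <- cos(omega * times)
  pos <- lapply(times + 1, function(f) matrix(0, 1, 3))
  vel <- lapply(seq_along(times), function(f) matrix(c(v[f], 0, 0), 1, 3))
  traj <- make_traj(pos, vel)
  z <- velocity_acf(traj, atoms = 1, max_lag_fs = 400)
  expect_lt(max(abs(z$value - cos(omega * z$lag_fs))), 0.02)
})

test_that("OU velocities give an exponential VACF with the planted tau", {
  tau <- 50
  ou <- gen_ou_gas(300, tau_fs = tau, kT_over_m = 2e-5, dt_fs = 5,
                   duration_fs = 10000, seed = 11)
  z <- velocity_acf(ou$trajectory, ou$topology$atom_id, max_lag_fs = 3 * tau)
  ref <- exp(-z$lag_fs / tau)
  rel_rmse <- sqrt(mean((z$value - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel_rmse, 0.05)
  expect_identical(z$value[1], 1)
  expect_lt(max(abs(z$value)), 1.05)
})

test_that("FFT and direct lag-loop ACF estimators agree to 1e-10", {
  set.seed(3)
  for (n in c(64, 1000, 4096)) {
    nf <- n
    vel <- lapply(seq_len(nf), function(f) matrix(rnorm(6, sd = 0.01), 2, 3))
    pos <- lapply(seq_len(nf), function(f) matrix(0, 2, 3))
    traj <- make_traj(pos, vel)
    a <- velocity_acf(traj, 1:2, max_lag_fs = nf / 2, method = "fft",
                      normalize = FALSE)
    b <- velocity_acf(traj, 1:2, max_lag_fs = nf / 2, method = "direct",
                      normalize = FALSE)
    expect_lt(max(abs(a$value - b$value)) / max(abs(b$value)), 1e-10)
    # and against the standalone brute-force oracle
    m <- matrix(unlist(lapply(vel, as.numeric)), nrow = nf, byrow = TRUE)
    expect_equal(a$value, brute_acf(m, nrow(a)) / 2, tolerance = 1e-10)
  }
})

test_that("ACF is even in time: reversed series gives the same ACF", {
  set.seed(8)
  nf <- 256
  vseq <- matrix(rnorm(nf * 3, sd = 0.02), nf, 3)
  fwd <- make_traj(lapply(1:nf, function(f) matrix(0, 1, 3)),
                   lapply(1:nf, function(f) matrix(vseq[f, ], 1, 3)))
  rev <- make_traj(lapply(1:nf, function(f) matrix(0, 1, 3)),
                   lapply(1:nf, function(f) matrix(vseq[nf + 1 - f, ], 1, 3)))
  za <- velocity_acf(fwd, 1, max_lag_fs = 100, normalize = FALSE)
  zb <- velocity_acf(rev, 1, max_lag_fs = 100, normalize = FALSE)
  expect_lt(max(abs(za$value - zb$value)) / max(abs(za$value)), 1e-10)
})

test_that("VACF of a union of equal-size disjoint sets is the mean of the parts", {
  set.seed(9)
  nf <- 120
  vel <- lapply(seq_len(nf), function(f) matrix(rnorm(12, sd = 0.01), 4, 3))
  pos <- lapply(seq_len(nf), function(f) matrix(0, 4, 3))
  traj <- make_traj(pos, vel)
  u <- velocity_acf(traj, 1:4, max_lag_fs = 40, normalize = FALSE)
  a <- velocity_acf(traj, 1:2, max_lag_fs = 40, normalize = FALSE)
  b <- velocity_acf(traj, 3:4, max_lag_fs = 40, normalize = FALSE)
  expect_equal(u$value, (a$value + b$value) / 2, tolerance = 1e-12)
})

test_that("cosine ACF transforms to a peak at the mode wavenumber", {
  omega <- wavenumber_to_angular(1650)
  lags <- seq(0, 3000, by = 1)
  acf <- hydrolayer:::new_acf_series(lags, cos(omega * lags),
                                     rep(1000L, length(lags)), TRUE, "velocity")
  s <- acf_to_spectrum(acf, window = "none")
  step <- s$wavenumber[2] - s$wavenumber[1]
  expect_lt(abs(s$wavenumber[which.max(s$intensity)] - 1650), step + 1e-9)
})

test_that("exponential ACF transforms to the analytic Lorentzian", {
  tau <- 20
  lags <- seq(0, 20 * tau, by = 0.5)
  acf <- hydrolayer:::new_acf_series(lags, exp(-lags / tau),
                                     rep(1000L, length(lags)), TRUE, "velocity")
  s <- acf_to_spectrum(acf, window = "none", zero_pad_factor = 2)
  om <- wavenumber_to_angular(s$wavenumber)
  lor <- tau / (1 + (om * tau)^2)
  sel <- om * tau <= 3 # down to a tenth of the zero-frequency value
  expect_lt(max(abs(s$intensity[sel] - lor[sel]) / lor[sel]), 0.02)
})

test_that("zero ACF transforms to the zero spectrum", {
  acf <- hydrolayer:::new_acf_series(0:99, rep(0, 100), rep(10L, 100),
                                     FALSE, "velocity")
  s <- acf_to_spectrum(acf)
  expect_true(all(s$intensity == 0))
})

test_that("FFT and direct cosine-transform paths agree to 1e-10", {
  set.seed(12)
  lags <- seq(0, 500, by = 2)
  vals <- exp(-lags / 80) * cos(wavenumber_to_angular(900) * lags)
  acf <- hydrolayer:::new_acf_series(lags, vals, rep(50L, length(lags)),
                                     FALSE, "velocity")
  for (win in c("none", "hann")) {
    a <- acf_to_spectrum(acf, window = win, zero_pad_factor = 2, method = "fft")
    b <- acf_to_spectrum(acf, window = win, zero_pad_factor = 2, method = "direct")
    expect_lt(max(abs(a$intensity - b$intensity)) / max(abs(a$intensity)), 1e-10)
    expect_equal(a$wavenumber, b$wavenumber)
  }
})

test_that("rectangular-window transform satisfies the Parseval-type sum rule", {
  # sum_m S(nu_m) * dnu = Z(0) / (4c) for the trapezoid-weighted
  # one-sided transform of a pure cosine (documented grid constant)
  omega <- wavenumber_to_angular(1200)
  lags <- seq(0, 2000, by = 1)
  acf <- hydrolayer:::new_acf_series(lags, cos(omega * lags),
                                     rep(100L, length(lags)), TRUE, "velocity")
  s <- acf_to_spectrum(acf, window = "none")
  dnu <- s$wavenumber[2] - s$wavenumber[1]
  expect_equal(sum(s$intensity) * dnu * 4 * hydrolayer:::.c_cm_fs, 1,
               tolerance = 0.02)
})

test_that("planted mode wavenumbers are recovered within one grid step", {
  set.seed(21)
  for (rep in 1:4) {
    nu <- runif(1, 100, 3750)
    fix <- gen_harmonic_waters(10, mode_spec(nu, 0.03), dt_fs = 1,
                               duration_fs = 3000, box = 30, seed = 100 + rep)
    z <- velocity_acf(fix$trajectory, fix$topology$atom_id)
    s <- acf_to_spectrum(z, window = "hann", zero_pad_factor = 2)
    step <- s$wavenumber[2] - s$wavenumber[1]
    expect_lt(abs(s$wavenumber[which.max(s$intensity)] - nu), step + 1e-9)
  }
})

test_that("spectral preconditions are enforced", {
  ou <- gen_ou_gas(5, tau_fs = 50, kT_over_m = 1e-5, dt_fs = 5,
                   duration_fs = 200, seed = 1)
  expect_error(velocity_acf(ou$trajectory, integer(0)), "empty atom")
  expect_error(velocity_acf(ou$trajectory, 1, max_lag_fs = 500),
               "max_lag")
  pos_only <- trajectory(ou$trajectory$times, ou$trajectory$positions,
                         NULL, c(60, 60, 60))
  expect_error(velocity_acf(pos_only, 1), "no velocities")
  bad <- tibble::tibble(lag_fs = c(0, 1, 3), value = c(1, 0.5, 0.2))
  expect_error(acf_to_spectrum(bad), "non-uniform")
})
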