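two_pop_fixture <- function() {
  make_layered_harmonic_box(
    pops = list(
      list(n = 6, radius_A = 1.8, nu_cm1 = 1650, amplitude = 0.03),
      list(n = 8, radius_A = 9.5, nu_cm1 = 1600, amplitude = 0.03)
    ),
    dt = 2, duration = 2400, box = 30, seed = 55
  )
}

scheme_for <- function(fix, include_bulk = TRUE) {
  span <- max(fix$trajectory$times)
  build_interval_scheme(span, layer_partition(c(2.2, 3.4, 4.5, 7.0)),
                        analysis_window_fs = 2000,
                        interval_fs = c(1000, 1000, 500, 500),
                        n_intervals = 2, include_bulk = include_bulk)
}

test_that("interval membership joins residence onto the interval scheme", {
  fix <- two_pop_fixture()
  part <- layer_partition(c(2.2, 3.4, 4.5, 7.0))
  labels <- layer_labels(fix$trajectory, fix$topology, part)
  sch <- scheme_for(fix)
  mem <- interval_members(labels, sch, threshold = 0.9)
  near <- fix$molecule_ids[fix$population == 1]
  far <- fix$molecule_ids[fix$population == 2]
  expect_setequal(unique(mem$molecule_id[mem$layer == 1]), near)
  expect_setequal(unique(mem$molecule_id[mem$layer == 0]), far)
  expect_true(all(mem$occupancy == 1))
  # disjoint within every interval
  for (iv in unique(mem$interval[mem$layer %in% c(1, 0)])) {
    sub <- mem[mem$interval == iv & mem$start_fs == mem$start_fs[1], ]
  }
})

test_that("layer spectra separate planted populations by wavenumber", {
  fix <- two_pop_fixture()
  part <- layer_partition(c(2.2, 3.4, 4.5, 7.0))
  labels <- layer_labels(fix$trajectory, fix$topology, part)
  sch <- scheme_for(fix)
  mem <- interval_members(labels, sch, threshold = 0.9)
  s1 <- layer_spectrum(fix$trajectory, fix$topology, mem, kind = "vdos_H",
                       layer = 1, window = "hann", zero_pad_factor = 2)
  s0 <- layer_spectrum(fix$trajectory, fix$topology, mem, kind = "vdos_H",
                       layer = 0, window = "hann", zero_pad_factor = 2)
  peak <- function(s) s$wavenumber[which.max(s$intensity)]
  step <- s1$wavenumber[2] - s1$wavenumber[1]
  expect_lt(abs(peak(s1) - 1650), 2 * step)
  expect_lt(abs(peak(s0) - 1600), 2 * step)
  expect_equal(spectrum_meta(s1)$n_intervals, 2)
})

test_that("averaging identical intervals equals a single interval", {
  fix <- two_pop_fixture()
  # tile the first 1000 fs block three times so that every analysis
  # interval sees literally identical data
  nf_tile <- 500L
  nf <- 3L * nf_tile
  idx <- rep(seq_len(nf_tile), 3)
  traj <- trajectory((seq_len(nf) - 1) * 2,
                     fix$trajectory$positions[, , idx],
                     fix$trajectory$velocities[, , idx],
                     fix$trajectory$box[1, ])
  sch <- build_interval_scheme(max(traj$times),
                               layer_partition(c(2.2, 3.4, 4.5, 7.0)),
                               analysis_window_fs = 2000,
                               interval_fs = rep(1000, 4), n_intervals = 2)
  near <- fix$molecule_ids[fix$population == 1]
  mem <- full_members(sch, list("1" = near))
  avg <- layer_spectrum(traj, fix$topology, mem, kind = "vdos_H", layer = 1)
  one <- layer_spectrum(traj, fix$topology, mem[mem$interval == 1, ],
                        kind = "vdos_H", layer = 1)
  expect_equal(avg$intensity, one$intensity, tolerance = 1e-12)
})

test_that("cumulative spectrum over all layers plus bulk is the whole-box spectrum", {
  fix <- two_pop_fixture()
  part <- layer_partition(c(2.2, 3.4, 4.5, 7.0))
  labels <- layer_labels(fix$trajectory, fix$topology, part)
  sch <- scheme_for(fix)
  # common scheme for pooling: same interval length everywhere
  sch_common <- build_interval_scheme(max(fix$trajectory$times), part,
                                      analysis_window_fs = 2000,
                                      interval_fs = rep(1000, 4),
                                      n_intervals = 2, include_bulk = TRUE)
  mem <- interval_members(labels, sch_common, threshold = 0.9)
  for (kind in c("vdos_H", "ir")) {
    cum <- cumulative_layer_spectrum(fix$trajectory, fix$topology, mem,
                                     kind = kind, k = 4, include_bulk = TRUE,
                                     window = "hann")
    whole <- layer_spectrum(fix$trajectory, fix$topology,
                            full_members(sch_common,
                                         list("1" = fix$molecule_ids)),
                            kind = kind, layer = 1, window = "hann")
    expect_lt(max(abs(cum$intensity - whole$intensity)) /
                max(abs(whole$intensity)), 1e-10)
  }
})

test_that("k = 1 cumulative equals the layer-1 spectrum", {
  fix <- two_pop_fixture()
  part <- layer_partition(c(2.2, 3.4, 4.5, 7.0))
  labels <- layer_labels(fix$trajectory, fix$topology, part)
  sch <- scheme_for(fix)
  mem <- interval_members(labels, sch, threshold = 0.9)
  cum1 <- cumulative_layer_spectrum(fix$trajectory, fix$topology,
                                    mem[mem$layer == 1, ], kind = "vdos_H",
                                    k = 1)
  lay1 <- layer_spectrum(fix$trajectory, fix$topology, mem, kind = "vdos_H",
                         layer = 1)
  expect_equal(cum1$intensity, lay1$intensity, tolerance = 1e-12)
})

test_that("pooling equal populations keeps both peaks at the planted ratio", {
  fix <- make_layered_harmonic_box(
    pops = list(
      # equal velocity amplitudes: displacement scales as 1/omega
      list(n = 10, radius_A = 1.8, nu_cm1 = 1650, amplitude = 0.03),
      list(n = 10, radius_A = 9.5, nu_cm1 = 3300, amplitude = 0.015)
    ),
    dt = 1, duration = 4000, box = 30, seed = 77
  )
  part <- layer_partition(c(2.2, 3.4, 4.5, 7.0))
  sch <- build_interval_scheme(4000, part, analysis_window_fs = 4000,
                               interval_fs = rep(4000, 4), n_intervals = 1,
                               include_bulk = TRUE)
  near <- fix$molecule_ids[fix$population == 1]
  far <- fix$molecule_ids[fix$population == 2]
  mem <- full_members(sch, list("1" = near, "0" = far))
  pooled <- cumulative_layer_spectrum(fix$trajectory, fix$topology, mem,
                                      kind = "vdos_H", k = 1,
                                      include_bulk = TRUE, window = "hann",
                                      zero_pad_factor = 2)
  # compare band areas (robust to peak-vs-grid alignment): equal-size
  # populations with equal velocity amplitudes make a 50/50 mix
  near_area <- sum(pooled$intensity[abs(pooled$wavenumber - 1650) < 60])
  far_area <- sum(pooled$intensity[abs(pooled$wavenumber - 3300) < 60])
  expect_lt(abs(near_area / far_area - 1), 0.02)
})

test_that("overlapping member sets across layers are rejected", {
  fix <- two_pop_fixture()
  sch <- build_interval_scheme(max(fix$trajectory$times),
                               layer_partition(c(2.2, 3.4, 4.5, 7.0)),
                               analysis_window_fs = 2000,
                               interval_fs = rep(1000, 4), n_intervals = 2)
  near <- fix$molecule_ids[fix$population == 1]
  mem <- full_members(sch, list("1" = near, "2" = near[1])) # molecule in both
  expect_error(
    cumulative_layer_spectrum(fix$trajectory, fix$topology, mem,
                              kind = "vdos_H", k = 2),
    "overlapping member sets"
  )
})

test_that("selection contract: vdos kinds require matching atoms", {
  ou <- gen_ou_gas(4, tau_fs = 50, kT_over_m = 1e-5, dt_fs = 5,
                   duration_fs = 1000, seed = 2)
  sch <- build_interval_scheme(1000, layer_partition(7), analysis_window_fs = 1000,
                               interval_fs = 1000, n_intervals = 1)
  mem <- full_members(sch, list("1" = ou$topology$molecule_id))
  # OU gas atoms are all O: an H-VDOS over them is a contract violation
  expect_error(
    layer_spectrum(ou$trajectory, ou$topology, mem, kind = "vdos_H", layer = 1),
    "no H atoms"
  )
  s <- layer_spectrum(ou$trajectory, ou$topology, mem, kind = "vdos_O",
                      layer = 1, window = "none")
  expect_s3_class(s, "hydro_spectrum")
})

test_that("molecular and collective IR modes agree for a single molecule", {
  fix <- make_layered_harmonic_box(
    pops = list(list(n = 1, radius_A = 1.8, nu_cm1 = 1650, amplitude = 0.03)),
    dt = 1, duration = 2000, box = 24, seed = 9
  )
  sch <- build_interval_scheme(2000, layer_partition(7),
                               analysis_window_fs = 2000, interval_fs = 2000,
                               n_intervals = 1)
  mem <- full_members(sch, list("1" = 1L))
  a <- layer_spectrum(fix$trajectory, fix$topology, mem, kind = "ir",
                      layer = 1, ir_mode = "collective")
  b <- layer_spectrum(fix$trajectory, fix$topology, mem, kind = "ir",
                      layer = 1, ir_mode = "molecular")
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
})
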