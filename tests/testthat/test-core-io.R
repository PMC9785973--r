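test_that("topology validation enforces water chemistry", {
  expect_s3_class(water1_topology(), "hydro_topology")

  bad_charge <- data.frame(
    atom_id = 1:3, element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008), charge = c(-0.82, 0.42, 0.41),
    molecule_id = 1L, role = "water"
  )
  expect_error(topology(bad_charge), "net charge")

  two_atom_water <- data.frame(
    atom_id = 1:2, element = c("O", "H"), mass = c(15.999, 1.008),
    charge = c(-0.41, 0.41), molecule_id = 1L, role = "water"
  )
  expect_error(topology(two_atom_water), "1 O and 2 H")

  dup <- data.frame(
    atom_id = c(1, 1, 2), element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008), charge = c(-0.82, 0.41, 0.41),
    molecule_id = 1L, role = "water"
  )
  expect_error(topology(dup), "duplicate atom_id")
})

test_that("topology files round-trip and water is detected by role", {
  path <- withr::local_tempfile(fileext = ".csv")
  topo <- water1_topology()
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(as.data.frame(back), as.data.frame(topo))

  # a protein O-H-H triple with unbalanced charge is fine: the water
  # invariants must not fire on role = protein rows
  prot <- topology(data.frame(
    atom_id = 1:3, element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008), charge = c(-0.3, 0.1, 0.1),
    molecule_id = 1L, role = "protein"
  ))
  expect_s3_class(prot, "hydro_topology")
})

test_that("generator-scale topology has the expected composition", {
  fix <- gen_harmonic_waters(200, mode_spec(1650, 0.02), dt_fs = 1,
                             duration_fs = 10, box = 60, seed = 1)
  expect_equal(nrow(fix$topology), 600)
  expect_equal(length(unique(fix$topology$molecule_id)), 200)
  expect_equal(sum(fix$topology$charge), 0)
})

test_that("fixture trajectory format write -> read is the identity", {
  set.seed(5)
  pos <- lapply(1:3, function(f) matrix(runif(6, 0, 20), 2, 3))
  vel <- lapply(1:3, function(f) matrix(rnorm(6, sd = 0.01), 2, 3))
  traj <- make_traj(pos, vel, dt = 2, box = c(60, 60, 60), atom_ids = c(4L, 9L))
  path <- withr::local_tempfile(fileext = ".traj")
  write_fixture_trajectory(traj, path)
  back <- read_trajectory(path, "fixture")
  expect_equal(back$times, c(0, 2, 4))
  expect_equal(back$positions, traj$positions)
  expect_equal(back$velocities, traj$velocities)
  expect_equal(back$box, traj$box)
  expect_equal(back$atom_ids, traj$atom_ids)
})

test_that("non-uniform frame times are rejected, naming the frame", {
  pos <- array(0, c(1, 3, 3))
  expect_error(trajectory(c(0, 2, 5), pos, NULL, c(10, 10, 10)),
               "non-uniform sampling.*frame 3")
})

test_that("TRR payloads convert from nm/ps to A/fs", {
  path <- withr::local_tempfile(fileext = ".trr")
  frames <- lapply(0:2, function(i) list(
    step = i, t_ps = 0.5 * i, box_nm = c(6, 6, 6),
    x_nm = matrix(c(0.1 + 0.01 * i, 0.2, 0.3), 1, 3),
    v_nmps = matrix(c(0.4, -0.5, 0.6 * (i + 1)), 1, 3)
  ))
  write_trr_oracle(path, frames)
  tr <- read_trajectory(path, "trr")
  expect_equal(tr$times, c(0, 500, 1000), tolerance = 1e-6)
  expect_equal(tr$box[1, ], c(60, 60, 60), tolerance = 1e-6)
  # positions x10 (nm -> A), velocities x 10/1000 (nm/ps -> A/fs)
  expect_equal(tr$positions[1, , 2], c(1.1, 2, 3), tolerance = 1e-6)
  expect_equal(tr$velocities[1, , 3], c(0.4, -0.5, 1.8) * 0.01,
               tolerance = 1e-6)
})

test_that("velocity-free TRR input is rejected for spectral use", {
  path <- withr::local_tempfile(fileext = ".trr")
  write_trr_oracle(path, list(list(step = 0, t_ps = 0, box_nm = c(5, 5, 5),
                                   x_nm = matrix(0.1, 1, 3), v_nmps = NULL)))
  expect_error(read_trajectory(path, "trr"), "no velocities")
  tr <- read_trajectory(path, "trr", require_velocities = FALSE)
  expect_null(tr$velocities)
})

test_that("GRO series with velocity columns reads in internal units", {
  path <- withr::local_tempfile(fileext = ".gro")
  fmt <- function(t, x) c(
    sprintf("frame t= %.3f", t), "    2",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
            1, "SOL", "OW", 1, x, 0.2, 0.3, 0.1, 0.0, -0.1),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
            1, "SOL", "HW1", 2, 0.4, 0.5, 0.6, 0.0, 0.2, 0.0),
    "   6.00000   6.00000   6.00000"
  )
  writeLines(c(fmt(0, 0.1), fmt(1, 0.15)), path)
  tr <- read_trajectory(path, "gro_series")
  expect_equal(tr$times, c(0, 1000))
  expect_equal(tr$positions[1, 1, ], c(1.0, 1.5))
  expect_equal(tr$velocities[1, 3, 1], -0.1 * 0.01)
  expect_equal(tr$box[2, ], c(60, 60, 60))
})

test_that("unit conversions are exact inverses", {
  x <- c(1.23456789, 1e-8, 4321.987)
  expect_equal(angular_to_wavenumber(wavenumber_to_angular(x)), x,
               tolerance = 1e-14)
  # A <-> nm and fs <-> ps round trips
  expect_equal((x * 10) / 10, x, tolerance = 1e-14)
  expect_equal((x * 1000) / 1000, x, tolerance = 1e-14)
})

test_that("spectrum CSV and JSON round-trip with metadata", {
  wn <- seq(0, 1000, by = 12.5)
  s <- hydrolayer:::new_spectrum(wn, exp(-((wn - 400) / 120)^2),
                                 list(kind = "vdos_H", layer = 1,
                                      window = "hann", n_intervals = 10))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_spectrum(s, path)
    back <- read_spectrum(path)
    expect_equal(back$wavenumber, s$wavenumber, tolerance = 1e-12)
    expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
    meta <- spectrum_meta(back)
    expect_equal(meta$kind, "vdos_H")
    expect_equal(as.integer(meta$layer), 1L)
  }
  # CSV column contract
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_equal(body[1], "wavenumber_cm-1,intensity")
})

test_that("triclinic boxes are rejected", {
  path <- withr::local_tempfile(fileext = ".trr")
  con <- file(path, "wb")
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wfl <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")
  wint(1993); wint(13); wint(12); writeBin(charToRaw("GMX_trn_file"), con)
  wint(c(0, 0)); wint(36); wint(c(0, 0, 0, 0)); wint(12); wint(12); wint(0)
  wint(1); wint(0); wint(0); wfl(0); wfl(0)
  wfl(c(5, 0, 0, 1.2, 5, 0, 0, 0, 5)) # off-diagonal element
  wfl(c(0.1, 0.1, 0.1)); wfl(c(0, 0, 0))
  close(con)
  expect_error(read_trajectory(path, "trr"), "triclinic")
})
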