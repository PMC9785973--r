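#' Specify harmonic modes for the synthetic water generator
#'
#' Each mode has a wavenumber (cm^-1), a displacement amplitude (A) and
#' a phase (`"random"`, drawn once per molecule, or a fixed value in
#' radians). The default set {50, 250, 1650, 3300, 3650} cm^-1 mirrors
#' the characteristic bands of liquid water: the two libration features
#' near 50 and 250 cm^-1, the H-O-H bend, the 3300 cm^-1 stretch
#' shoulder and the main O-H stretch.
#'
#' @param wavenumber Wavenumbers, cm^-1 (> 0).
#' @param amplitude Displacement amplitudes, A (recycled).
#' @param phase `"random"` or numeric radians (recycled).
#' @return A tibble with `wavenumber`, `amplitude`, `phase`.
#' @export
mode_spec <- function(wavenumber = c(50, 250, 1650, 3300, 3650),
                      amplitude = 0.05, phase = "random") {
  if (any(wavenumber <= 0)) abort("mode wavenumbers must be positive")
  tibble(
    wavenumber = as.numeric(wavenumber),
    amplitude = rep_len(as.numeric(amplitude), length(wavenumber)),
    phase = rep_len(as.list(phase), length(wavenumber))
  )
}

water_topology <- function(n_molecules, charges = c(qO = -0.82, qH = 0.41),
                           id_offset = 0L, mol_offset = 0L) {
  topology(tibble(
    atom_id = id_offset + seq_len(3L * n_molecules),
    element = rep(c("O", "H", "H"), n_molecules),
    mass = rep(c(15.999, 1.008, 1.008), n_molecules),
    charge = rep(c(charges[[1]], charges[[2]], charges[[2]]), n_molecules),
    molecule_id = mol_offset + rep(seq_len(n_molecules), each = 3L),
    role = "water"
  ))
}

#' Generate water molecules with prescribed harmonic velocity modes
#'
#' Builds a trajectory whose atomic velocities are exact superpositions
#' of cosines at the given wavenumbers — a synthetic stand-in for a
#' flexible-water simulation whose VDOS is a known set of delta
#' functions. For mode `m` with angular frequency `omega_m`,
#' displacement amplitude `A_m`, a per-(molecule, mode) random unit
#' direction `u` and phase `phi`:
#' `v(t) = sum_m A_m omega_m u cos(omega_m t + phi)`, with positions
#' the analytic integrals. Each molecule carries SPC-like neutral
#' charges, so the dipole flux is non-trivial but every rigid
#' translation is IR-silent.
#'
#' @param n_molecules Number of water molecules.
#' @param modes A [mode_spec()] tibble.
#' @param dt_fs Stored sampling interval, fs; must satisfy the Nyquist
#'   bound for the largest mode wavenumber.
#' @param duration_fs Trajectory span, fs.
#' @param box Box edge length(s), A (scalar or length 3).
#' @param charges `c(qO, qH)` partial charges, e.
#' @param seed Integer seed; output is bit-identical for a fixed seed
#'   (R's default Mersenne-Twister generator, recorded in the params).
#' @return A list with `trajectory`, `topology` and `params`.
#' @export
#' @examples
#' fix <- gen_harmonic_waters(5, mode_spec(1650, 0.05), dt_fs = 1,
#'                            duration_fs = 500, box = 20, seed = 1)
gen_harmonic_waters <- function(n_molecules, modes = mode_spec(),
                                dt_fs = 1, duration_fs = 10000,
                                box = 60, charges = c(qO = -0.82, qH = 0.41),
                                seed = 1L) {
  nyq <- nyquist_wavenumber(dt_fs)
  if (max(modes$wavenumber) >= nyq) {
    abort(paste0("Nyquist violation: dt = ", dt_fs,
                 " fs supports wavenumbers below ", round(nyq, 1),
                 " cm^-1, but a mode at ", max(modes$wavenumber),
                 " cm^-1 was requested"))
  }
  box <- rep_len(as.numeric(box), 3)
  set.seed(seed)
  n_atoms <- 3L * n_molecules
  times <- seq(0, duration_fs, by = dt_fs)
  nf <- length(times)
  topo <- water_topology(n_molecules, charges)
  # rigid base geometry: O at a random site, H at fixed offsets
  o_pos <- cbind(runif(n_molecules, 0, box[1]), runif(n_molecules, 0, box[2]),
                 runif(n_molecules, 0, box[3]))
  h1_off <- c(0.9572, 0, 0)
  h2_off <- c(-0.2399872, 0.9266272, 0)
  base <- matrix(NA_real_, n_atoms, 3)
  base[seq(1, n_atoms, 3), ] <- o_pos
  base[seq(2, n_atoms, 3), ] <- sweep(o_pos, 2, h1_off, "+")
  base[seq(3, n_atoms, 3), ] <- sweep(o_pos, 2, h2_off, "+")
  pos <- array(rep(base, nf), c(n_atoms, 3, nf))
  vel <- array(0, c(n_atoms, 3, nf))
  mode_params <- list()
  for (m in seq_len(nrow(modes))) {
    omega <- wavenumber_to_angular(modes$wavenumber[m])
    A <- modes$amplitude[m]
    ph_spec <- modes$phase[[m]]
    phi <- if (identical(ph_spec, "random")) {
      runif(n_molecules, 0, 2 * pi)
    } else {
      rep_len(as.numeric(ph_spec), n_molecules)
    }
    u <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
    u <- u / sqrt(rowSums(u^2))
    phase_atom <- rep(phi, each = 3L)
    # cos/sin tables per molecule-phase, shared by the 3 atoms
    arg <- outer(phase_atom, rep(1, nf)) + outer(rep(1, n_atoms), omega * times)
    cosA <- cos(arg)
    sinA <- sin(arg)
    for (c3 in 1:3) {
      vel[, c3, ] <- vel[, c3, ] + A * omega * u[, c3] * cosA
      pos[, c3, ] <- pos[, c3, ] + A * u[, c3] * sinA
    }
    mode_params[[m]] <- list(wavenumber = modes$wavenumber[m],
                             amplitude = A)
  }
  params <- list(generator = "gen_harmonic_waters", seed = seed,
                 rng = "Mersenne-Twister", n_molecules = n_molecules,
                 dt_fs = dt_fs, duration_fs = duration_fs, box = box,
                 charges = unname(charges), modes = mode_params)
  list(trajectory = trajectory(times, pos, vel, box),
       topology = topo, params = params)
}

#' Generate an Ornstein-Uhlenbeck velocity gas
#'
#' Independent atoms whose velocity components follow the exact OU
#' update `v(t + dt) = v(t) exp(-dt/tau) + xi`, with `xi` Gaussian of
#' variance `kT_over_m (1 - exp(-2 dt/tau))` and stationary variance
#' `kT_over_m` per component. The velocity ACF is analytically
#' `exp(-t/tau)` and the VDOS a Lorentzian of half-width `1/tau` —
#' a diffusive stand-in for translational (oxygen-dominated) motion.
#' Atoms carry zero charge and role `"ion"`, so they enter spectral
#' selections but never layering.
#'
#' @param n_atoms Number of atoms.
#' @param tau_fs Velocity relaxation time, fs.
#' @param kT_over_m Stationary velocity variance per component,
#'   (A/fs)^2.
#' @param dt_fs Sampling interval, fs; must be at most `tau_fs / 10`.
#' @param duration_fs Trajectory span, fs.
#' @param box Box edge length(s), A.
#' @param seed Integer seed (bit-identical output for a fixed seed).
#' @return A list with `trajectory`, `topology` and `params`.
#' @export
gen_ou_gas <- function(n_atoms, tau_fs = 50, kT_over_m = 1e-5,
                       dt_fs = 5, duration_fs = 20000, box = 60,
                       seed = 1L) {
  if (dt_fs > tau_fs / 10 + 1e-12) {
    abort("dt_fs too coarse: must be at most tau_fs / 10")
  }
  box <- rep_len(as.numeric(box), 3)
  set.seed(seed)
  times <- seq(0, duration_fs, by = dt_fs)
  nf <- length(times)
  decay <- exp(-dt_fs / tau_fs)
  noise_sd <- sqrt(kT_over_m * (1 - decay^2))
  v <- array(NA_real_, c(n_atoms, 3, nf))
  v[, , 1] <- rnorm(n_atoms * 3, sd = sqrt(kT_over_m))
  for (f in 2:nf) {
    v[, , f] <- v[, , f - 1] * decay +
      matrix(rnorm(n_atoms * 3, sd = noise_sd), n_atoms, 3)
  }
  pos <- array(NA_real_, c(n_atoms, 3, nf))
  pos[, , 1] <- cbind(runif(n_atoms, 0, box[1]), runif(n_atoms, 0, box[2]),
                      runif(n_atoms, 0, box[3]))
  for (f in 2:nf) pos[, , f] <- pos[, , f - 1] + v[, , f - 1] * dt_fs
  topo <- topology(tibble(
    atom_id = seq_len(n_atoms), element = "O", mass = 15.999,
    charge = 0, molecule_id = seq_len(n_atoms), role = "ion"
  ))
  params <- list(generator = "gen_ou_gas", seed = seed,
                 rng = "Mersenne-Twister", n_atoms = n_atoms,
                 tau_fs = tau_fs, kT_over_m = kT_over_m, dt_fs = dt_fs,
                 duration_fs = duration_fs, box = box)
  list(trajectory = trajectory(times, pos, v, box),
       topology = topo, params = params)
}

#' Generate a static box with a prescribed radial density profile
#'
#' Places water oxygens around a solute proxy (default: one pseudo-atom
#' at the box centre) so that the distance-binned mass density matches
#' a piecewise-constant target profile: each spherical annulus receives
#' a fixed count `round(density * volume / molecular mass)` of
#' molecules, positioned uniformly within it and redrawn independently
#' every frame (a binomial point process with fixed totals, so the
#' realized mean density is exact up to count rounding). The region
#' beyond the last specified annulus is filled at `bulk_density`.
#' Hydrogens ride at fixed offsets and all velocities are zero: this is
#' a geometry-only fixture for the density-profile and
#' boundary-detection stages.
#'
#' @param profile_spec Tibble with `r_lo_A`, `r_hi_A`,
#'   `density_g_cm3`: the target piecewise profile (annuli must not
#'   overlap).
#' @param bulk_density Density outside the specified annuli, g/cm^3
#'   (default 0.997).
#' @param box Box edge length(s), A.
#' @param n_frames Independent frames to draw (more frames average
#'   down the sampling noise of the recovered profile).
#' @param solute_n Number of solute pseudo-atoms (currently 1).
#' @param seed Integer seed.
#' @return A list with `trajectory`, `topology` and `params`.
#' @export
gen_layered_box <- function(profile_spec, bulk_density = 0.997,
                            box = 24, n_frames = 50, solute_n = 1L,
                            seed = 1L) {
  if (solute_n != 1L) abort("gen_layered_box supports a single-atom solute proxy")
  box <- rep_len(as.numeric(box), 3)
  ps <- as_tibble(profile_spec)
  need <- c("r_lo_A", "r_hi_A", "density_g_cm3")
  if (!all(need %in% names(ps))) {
    abort("profile_spec needs columns r_lo_A, r_hi_A, density_g_cm3")
  }
  ps <- ps[order(ps$r_lo_A), ]
  if (any(ps$r_hi_A <= ps$r_lo_A) ||
      any(head(ps$r_hi_A, -1) > tail(ps$r_lo_A, -1) + 1e-9)) {
    abort("profile_spec annuli must be increasing and non-overlapping")
  }
  r_max_spec <- max(ps$r_hi_A)
  if (r_max_spec > min(box) / 2) {
    abort("profile annuli must fit within half the box")
  }
  mol_mass <- 15.999 + 2 * 1.008
  # number densities (molecules / A^3) from mass densities
  num_dens <- ps$density_g_cm3 / .amu_A3_to_g_cm3 / mol_mass
  bulk_num <- bulk_density / .amu_A3_to_g_cm3 / mol_mass
  center <- box / 2
  set.seed(seed)
  # fixed per-region counts: realized density exact up to rounding
  ann_vol <- 4 / 3 * pi * (ps$r_hi_A^3 - ps$r_lo_A^3)
  n_ann <- as.integer(round(num_dens * ann_vol))
  box_vol <- prod(box)
  sphere_vol <- 4 / 3 * pi * r_max_spec^3
  n_bulk <- as.integer(round(bulk_num * (box_vol - sphere_vol)))
  n_mol <- sum(n_ann) + n_bulk
  if (n_mol == 0) abort("profile produced no molecules (infeasible density)")
  draw_annulus <- function(n, r_lo, r_hi) {
    r <- (runif(n) * (r_hi^3 - r_lo^3) + r_lo^3)^(1 / 3)
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    sweep(r * cbind(s * cos(phi), s * sin(phi), z), 2, center, "+")
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pts <- list()
    for (a in seq_len(nrow(ps))) {
      if (n_ann[a] > 0) {
        pts[[length(pts) + 1L]] <- draw_annulus(n_ann[a], ps$r_lo_A[a],
                                                ps$r_hi_A[a])
      }
    }
    if (n_bulk > 0) {
      got <- 0L
      acc <- matrix(NA_real_, n_bulk, 3)
      while (got < n_bulk) {
        cand <- cbind(runif(n_bulk, 0, box[1]), runif(n_bulk, 0, box[2]),
                      runif(n_bulk, 0, box[3]))
        rel <- sweep(cand, 2, center)
        keep <- which(rowSums(rel^2) > r_max_spec^2)
        take <- head(keep, n_bulk - got)
        if (length(take) > 0) {
          acc[got + seq_along(take), ] <- cand[take, , drop = FALSE]
          got <- got + length(take)
        }
      }
      pts[[length(pts) + 1L]] <- acc
    }
    frames[[f]] <- do.call(rbind, pts)
  }
  n_atoms <- 3L * n_mol + 1L
  pos <- array(NA_real_, c(n_atoms, 3, n_frames))
  h1 <- c(0.9572, 0, 0); h2 <- c(-0.2399872, 0.9266272, 0)
  for (f in seq_len(n_frames)) {
    o <- frames[[f]]
    pos[seq(1, 3 * n_mol, 3), , f] <- o
    pos[seq(2, 3 * n_mol, 3), , f] <- sweep(o, 2, h1, "+")
    pos[seq(3, 3 * n_mol, 3), , f] <- sweep(o, 2, h2, "+")
    pos[n_atoms, , f] <- center
  }
  wt <- water_topology(n_mol)
  topo <- topology(rbind(
    as.data.frame(wt),
    data.frame(atom_id = n_atoms, element = "X", mass = 100, charge = 0,
               molecule_id = n_mol + 1L, role = "protein")
  ))
  times <- seq_len(n_frames) - 1
  params <- list(generator = "gen_layered_box", seed = seed,
                 rng = "Mersenne-Twister", bulk_density = bulk_density,
                 box = box, n_frames = n_frames,
                 profile_spec = as.data.frame(ps))
  list(trajectory = trajectory(times, pos, velocities = NULL, box = box),
       topology = topo, params = params)
}

#' Scripted layer labels
#'
#' Turns a per-molecule script of `(frame range, layer)` assignments
#' into a `hydro_labels` matrix; frames a molecule leaves unscripted
#' are bulk (0). Overlapping ranges for one molecule are an error.
#' Used to exercise the residence rule with exactly known occupancies.
#'
#' @param script Tibble with `molecule_id`, `frame_lo`, `frame_hi`
#'   (1-based, inclusive) and `layer`.
#' @param n_frames Number of frames.
#' @param molecule_ids Molecule ids (default: those in the script).
#' @param dt_fs Frame spacing used for the attached times (default 1).
#' @return A `hydro_labels` matrix.
#' @export
gen_scripted_layers <- function(script, n_frames, molecule_ids = NULL,
                                dt_fs = 1) {
  if (is.null(molecule_ids)) {
    molecule_ids <- sort(unique(script$molecule_id))
  }
  lab <- matrix(0L, n_frames, length(molecule_ids))
  touched <- matrix(FALSE, n_frames, length(molecule_ids))
  if (nrow(script) > 0) {
    for (r in seq_len(nrow(script))) {
      j <- match(script$molecule_id[r], molecule_ids)
      if (is.na(j)) abort("script references an unknown molecule_id")
      rows <- script$frame_lo[r]:script$frame_hi[r]
      if (any(rows < 1 | rows > n_frames)) {
        abort("script frame range outside the trajectory")
      }
      if (any(touched[rows, j])) {
        abort(paste0("overlapping script ranges for molecule ",
                     script$molecule_id[r]))
      }
      touched[rows, j] <- TRUE
      lab[rows, j] <- as.integer(script$layer[r])
    }
  }
  new_layer_labels(lab, (seq_len(n_frames) - 1) * dt_fs, molecule_ids)
}
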