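# Two-population fixture: waters at controlled distances from a single
# solute atom, with harmonic velocities at per-population wavenumbers.
# Positions are static, so layer membership is exact (occupancy 1).
make_layered_harmonic_box <- function(pops, dt = 2, duration = 2400,
                                      box = 30, seed = 101) {
  # pops: list of list(n, radius_A, nu_cm1, amplitude)
  set.seed(seed)
  center <- rep(box / 2, 3)
  times <- seq(0, duration, by = dt)
  nf <- length(times)
  n_w <- sum(vapply(pops, function(p) p$n, numeric(1)))
  n_atoms <- 3L * n_w + 1L
  pos <- array(NA_real_, c(n_atoms, 3, nf))
  vel <- array(0, c(n_atoms, 3, nf))
  w <- 0L
  pop_of <- integer(n_w)
  for (pi in seq_along(pops)) {
    p <- pops[[pi]]
    omega <- wavenumber_to_angular(p$nu_cm1)
    for (k in seq_len(p$n)) {
      w <- w + 1L
      pop_of[w] <- pi
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      o <- center + p$radius_A * dir
      base <- 3L * (w - 1L)
      pos[base + 1, , ] <- o
      pos[base + 2, , ] <- o + c(0.96, 0, 0)
      pos[base + 3, , ] <- o + c(-0.24, 0.93, 0)
      for (a in 1:3) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        phi <- runif(1, 0, 2 * pi)
        vel[base + a, , ] <- outer(p$amplitude * omega * u,
                                   cos(omega * times + phi))
      }
    }
  }
  pos[n_atoms, , ] <- center
  wt <- as.data.frame(hydrolayer:::water_topology(n_w))
  topo <- topology(rbind(
    wt,
    data.frame(atom_id = 3L * n_w + 1L, element = "X", mass = 100,
               charge = 0, molecule_id = n_w + 1L, role = "protein")
  ))
  list(
    trajectory = trajectory(times, pos, vel, rep(box, 3)),
    topology = topo,
    population = pop_of,
    molecule_ids = seq_len(n_w)
  )
}

# members table for scripted populations: every listed molecule is a
# full-occupancy member of its layer in every interval of the scheme
full_members <- function(scheme, layer_molecules) {
  purrr::imap_dfr(layer_molecules, function(mols, ly) {
    ly <- as.integer(ly)
    sch <- scheme[scheme$layer == ly, ]
    purrr::pmap_dfr(sch, function(layer, interval, start_fs, end_fs, averaged) {
      if (length(mols) == 0) return(NULL)
      tibble::tibble(layer = layer, interval = interval, start_fs = start_fs,
                     end_fs = end_fs, averaged = averaged,
                     molecule_id = mols, occupancy = 1)
    })
  })
}
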