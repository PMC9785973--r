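# Shared fixtures and independent oracles.

# SPC-like single water topology
water1_topology <- function() {
  topology(data.frame(
    atom_id = 1:3, element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008), charge = c(-0.82, 0.41, 0.41),
    molecule_id = 1L, role = "water"
  ))
}

# small trajectory with explicit per-frame positions/velocities
make_traj <- function(pos_list, vel_list = NULL, dt = 1, box = c(20, 20, 20),
                      atom_ids = NULL) {
  nf <- length(pos_list)
  na <- nrow(pos_list[[1]])
  pos <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) pos[, , f] <- pos_list[[f]]
  vel <- NULL
  if (!is.null(vel_list)) {
    vel <- array(NA_real_, c(na, 3, nf))
    for (f in seq_len(nf)) vel[, , f] <- vel_list[[f]]
  }
  trajectory((seq_len(nf) - 1) * dt, pos, vel, box, atom_ids = atom_ids)
}

# Independent minimal TRR writer (big-endian XDR, single precision,
# nm / ps payload). Written from the format definition, not from the
# package reader, so read-back checks are a true cross-check.
write_trr_oracle <- function(path, frames) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wfl <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")
  for (fr in frames) {
    natoms <- nrow(fr$x_nm)
    wint(1993)               # magic
    wint(13); wint(12)       # version string "GMX_trn_file"
    writeBin(charToRaw("GMX_trn_file"), con)
    wint(c(0, 0))            # ir_size, e_size
    wint(36)                 # box_size (9 floats)
    wint(c(0, 0, 0, 0))      # vir, pres, top, sym
    wint(3 * natoms * 4)     # x_size
    wint(if (is.null(fr$v_nmps)) 0 else 3 * natoms * 4) # v_size
    wint(0)                  # f_size
    wint(natoms); wint(fr$step); wint(0)
    wfl(fr$t_ps); wfl(0)     # t, lambda
    b <- diag(fr$box_nm)
    wfl(as.numeric(t(b)))
    wfl(as.numeric(t(fr$x_nm)))
    if (!is.null(fr$v_nmps)) wfl(as.numeric(t(fr$v_nmps)))
  }
  invisible(path)
}

# brute-force minimum-image distance over all 27 periodic images
brute_surface_distances <- function(o_pos, s_pos, box) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  apply(o_pos, 1, function(o) {
    best <- Inf
    for (s in seq_len(nrow(s_pos))) {
      for (k in seq_len(nrow(offs))) {
        d <- o - (s_pos[s, ] + offs[k, ] * box)
        best <- min(best, sqrt(sum(d^2)))
      }
    }
    best
  })
}

# direct O(n^2) lag-loop ACF of a multi-column series (reference)
brute_acf <- function(x, n_lags) {
  x <- as.matrix(x)
  n <- nrow(x)
  vapply(0:(n_lags - 1), function(k) {
    sum(x[1:(n - k), , drop = FALSE] * x[(1 + k):n, , drop = FALSE]) / (n - k)
  }, numeric(1))
}

# periodic Voronoi volumes via scipy (27-image replication), used as
# the cross-implementation oracle
scipy_voronoi_volumes <- function(points, box) {
  ptf <- tempfile(fileext = ".csv")
  write.table(points, ptf, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- '
import sys, json, numpy as np
from scipy.spatial import Voronoi, ConvexHull
pts = np.loadtxt(sys.argv[1], delimiter=",", ndmin=2)
box = np.array([float(x) for x in sys.argv[2].split(",")])
n = len(pts)
imgs = []
for ox in (-1, 0, 1):
    for oy in (-1, 0, 1):
        for oz in (-1, 0, 1):
            imgs.append(pts + np.array([ox, oy, oz]) * box)
allp = np.vstack(imgs)
vor = Voronoi(allp)
vols = []
for i in range(n):
    reg = vor.regions[vor.point_region[13 * n + i]]
    assert -1 not in reg
    vols.append(ConvexHull(vor.vertices[reg]).volume)
print(json.dumps(vols))
'
  scf <- tempfile(fileext = ".py")
  writeLines(script, scf)
  out <- system2("python", c(scf, ptf, paste(box, collapse = ",")),
                 stdout = TRUE)
  jsonlite::fromJSON(out)
}

solute_water_topo <- function(n_solute, n_water) {
  wt <- as.data.frame(hydrolayer:::water_topology(
    n_water, id_offset = n_solute, mol_offset = 1L
  ))
  topology(rbind(
    data.frame(atom_id = seq_len(n_solute), element = "C", mass = 12.011,
               charge = 0, molecule_id = 0L, role = "protein"),
    wt
  ))
}

place_waters <- function(o_pos, solute_pos, box = c(60, 60, 60)) {
  n_w <- nrow(o_pos)
  n_s <- nrow(solute_pos)
  pos <- matrix(NA_real_, n_s + 3 * n_w, 3)
  pos[seq_len(n_s), ] <- solute_pos
  for (w in seq_len(n_w)) {
    base <- n_s + 3 * (w - 1)
    pos[base + 1, ] <- o_pos[w, ]
    pos[base + 2, ] <- o_pos[w, ] + c(0.96, 0, 0)
    pos[base + 3, ] <- o_pos[w, ] + c(-0.24, 0.93, 0)
  }
  make_traj(list(pos), box = box)
}

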