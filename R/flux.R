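#' Dipole-moment time derivative of a molecule selection
#'
#' For a set of molecules with per-atom partial charges `e_j`, the time
#' derivative of the selection's dipole moment is the charge-weighted
#' velocity sum `J(t) = dM/dt = sum_j e_j v_j(t)`, evaluated per frame.
#' A neutral molecule translating rigidly contributes exactly zero, so
#' `J` isolates internal (vibrational, librational) charge motion. The
#' autocorrelation of `J` (see [flux_acf()]) transforms to the classical
#' IR lineshape.
#'
#' @param traj A `hydro_trajectory` with velocities.
#' @param topo A topology carrying the partial charges.
#' @param molecules Integer molecule ids (non-empty, must exist in
#'   `topo`).
#' @return A tibble of class `hydro_flux` with columns `time_fs`, `Jx`,
#'   `Jy`, `Jz` in e*A/fs.
#' @export
dipole_flux <- function(traj, topo, molecules) {
  require_velocities(traj, "dipole_flux()")
  if (length(molecules) == 0) abort("empty molecule selection")
  missing <- setdiff(molecules, unique(topo$molecule_id))
  if (length(missing) > 0) {
    abort(paste0("molecule id(s) not in topology: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  sel <- topo$molecule_id %in% molecules
  rows <- atom_rows(traj, topo$atom_id[sel])
  q <- topo$charge[sel]
  nf <- n_frames(traj)
  v <- traj$velocities[rows, , , drop = FALSE]
  J <- matrix(NA_real_, nf, 3)
  for (c3 in 1:3) {
    J[, c3] <- as.numeric(crossprod(matrix(v[, c3, ], nrow = length(rows)), q))
  }
  out <- tibble(time_fs = traj$times, Jx = J[, 1], Jy = J[, 2], Jz = J[, 3])
  class(out) <- c("hydro_flux", class(out))
  out
}
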