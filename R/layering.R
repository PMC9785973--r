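#' Distance from each water molecule to the solute surface
#'
#' The layering coordinate: the minimum-image distance from each water
#' oxygen to the nearest solute heavy atom (solute hydrogens excluded
#' by default, since heavy atoms define the effective surface at the
#' ~1.8 A first-peak scale; set `heavy_only = FALSE` to include them).
#'
#' @param traj A `hydro_trajectory`.
#' @param topo The matching topology (must contain at least one solute
#'   atom of the requested kind).
#' @param frame Frame index (1-based).
#' @param heavy_only Exclude solute hydrogens (default TRUE).
#' @return A tibble with `molecule_id` and `distance_A`.
#' @export
surface_distances <- function(traj, topo, frame = 1L, heavy_only = TRUE) {
  sol <- solute_ids(topo, heavy_only = heavy_only)
  if (length(sol) == 0) abort("no solute atoms in topology")
  ox <- water_oxygen_ids(topo)
  box <- traj$box[frame, ]
  o_pos <- traj$positions[atom_rows(traj, ox), , frame, drop = TRUE]
  if (length(ox) == 1) o_pos <- matrix(o_pos, 1, 3)
  s_pos <- traj$positions[atom_rows(traj, sol), , frame, drop = TRUE]
  if (length(sol) == 1) s_pos <- matrix(s_pos, 1, 3)
  d2min <- rep(Inf, nrow(o_pos))
  for (s in seq_len(nrow(s_pos))) {
    rel <- sweep(o_pos, 2, s_pos[s, ])
    rel <- rel - sweep(round(sweep(rel, 2, box, "/")), 2, box, "*")
    d2min <- pmin(d2min, rowSums(rel^2))
  }
  tibble(
    molecule_id = topo$molecule_id[match(ox, topo$atom_id)],
    distance_A = sqrt(d2min)
  )
}

#' Layer partitions of the hydration shell
#'
#' A partition is a set of strictly increasing boundary distances (A)
#' from the solute surface; layer `k` is the half-open interval
#' `[b_{k-1}, b_k)` with `b_0 = 0`, and everything at or beyond the last
#' boundary (the bulk onset) is bulk. The default four-layer partition
#' `{2.2, 3.4, 4.5, 7.0}` A brackets the characteristic hydration-shell
#' features around a solvated protein (first density peak near 1.8 A,
#' second near 2.6 A, a narrow transition zone, and bulk onset near
#' 7 A); it is always user-overridable, and [detect_boundaries()]
#' derives a data-driven partition instead.
#'
#' @param boundaries Strictly increasing positive distances, A; the last
#'   value is the bulk onset.
#' @return A tibble of class `hydro_partition` with columns `layer`,
#'   `lower_A`, `upper_A`.
#' @export
#' @examples
#' layer_partition() # the default four layers
layer_partition <- function(boundaries = c(2.2, 3.4, 4.5, 7.0)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) == 0 || any(boundaries <= 0) ||
      is.unsorted(boundaries, strictly = TRUE)) {
    abort("boundaries must be strictly increasing positive distances")
  }
  out <- tibble(
    layer = seq_along(boundaries),
    lower_A = c(0, head(boundaries, -1)),
    upper_A = boundaries
  )
  class(out) <- c("hydro_partition", class(out))
  out
}

partition_boundaries <- function(partition) partition$upper_A

#' Assign water molecules to layers by distance
#'
#' Label `k` means distance in `[b_{k-1}, b_k)` (half-open: a molecule
#' exactly on a boundary belongs to the outer layer); label `0` means
#' bulk (at or beyond the last boundary).
#'
#' @param distances Tibble from [surface_distances()], or a numeric
#'   vector of distances (A).
#' @param partition A `hydro_partition`.
#' @return A tibble with `molecule_id` (or index) and integer `layer`
#'   (0 = bulk).
#' @export
assign_layers <- function(distances, partition) {
  if (is.data.frame(distances)) {
    d <- distances$distance_A
    ids <- distances$molecule_id
  } else {
    d <- as.numeric(distances)
    ids <- seq_along(d)
  }
  if (any(d < 0)) abort("distances must be non-negative")
  b <- partition_boundaries(partition)
  lab <- findInterval(d, c(0, b), left.open = FALSE, rightmost.closed = FALSE)
  lab[lab > length(b)] <- 0L
  tibble(molecule_id = ids, layer = as.integer(lab))
}

#' Per-frame layer labels for a whole trajectory
#'
#' Runs [surface_distances()] and [assign_layers()] on every frame and
#' returns the labels as an integer matrix (frames x molecules,
#' 0 = bulk) with the frame times and molecule ids attached — the
#' compact form consumed by [residence_membership()].
#'
#' @inheritParams surface_distances
#' @param partition A `hydro_partition`.
#' @param frames Frame indices (default: all).
#' @return An object of class `hydro_labels`: integer matrix with
#'   attributes `times` (fs) and `molecule_ids`.
#' @export
layer_labels <- function(traj, topo, partition, frames = NULL,
                         heavy_only = TRUE) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  first <- surface_distances(traj, topo, frames[1], heavy_only)
  mol_ids <- first$molecule_id
  lab <- matrix(NA_integer_, length(frames), length(mol_ids))
  lab[1, ] <- assign_layers(first, partition)$layer
  if (length(frames) > 1) {
    for (f in 2:length(frames)) {
      d <- surface_distances(traj, topo, frames[f], heavy_only)
      lab[f, ] <- assign_layers(d, partition)$layer
    }
  }
  new_layer_labels(lab, traj$times[frames], mol_ids)
}

new_layer_labels <- function(lab, times, molecule_ids) {
  structure(lab, times = times, molecule_ids = as.integer(molecule_ids),
            class = "hydro_labels")
}

#' @export
print.hydro_labels <- function(x, ...) {
  cat("<hydro_labels> ", nrow(x), " frames x ", ncol(x),
      " molecules (0 = bulk)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.hydro_labels <- function(x, ...) {
  tibble(
    frame = rep(seq_len(nrow(x)), times = ncol(x)),
    time_fs = rep(attr(x, "times"), times = ncol(x)),
    molecule_id = rep(attr(x, "molecule_ids"), each = nrow(x)),
    layer = as.integer(x)
  )
}

#' Residence-based layer membership
#'
#' A molecule belongs to a layer's population for an analysis interval
#' only if it carries that layer's label for at least `threshold` of
#' the interval's frames (default 0.90, the conventional residence
#' criterion). Occupancy is recorded for every molecule, members or
#' not, so the rule is auditable.
#'
#' @param labels A `hydro_labels` matrix covering the interval.
#' @param layer Integer layer index (0 = bulk).
#' @param threshold Occupancy fraction in (0, 1] (default 0.9).
#' @param frames Optional row indices restricting the interval.
#' @return A tibble with `molecule_id`, `occupancy` and logical
#'   `member`, ordered by molecule id.
#' @export
residence_membership <- function(labels, layer, threshold = 0.9,
                                 frames = NULL) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  lab <- unclass(labels)
  if (!is.null(frames)) lab <- lab[frames, , drop = FALSE]
  if (nrow(lab) == 0) abort("empty interval: no frames to evaluate")
  occ <- colMeans(lab == layer)
  tibble(
    molecule_id = attr(labels, "molecule_ids"),
    occupancy = occ,
    member = occ >= threshold
  )
}

#' Tile the analysis window into per-layer intervals
#'
#' The analysis protocol divides the final `analysis_window_fs` of the
#' trajectory into contiguous, non-overlapping intervals, with a
#' per-layer interval length (default 20 ps for layers 1-2, whose
#' populations are slow to exchange, and 5 ps for the outer layers),
#' and marks the first `n_intervals` (default 10) of each layer's tiles
#' for spectrum averaging.
#'
#' @param traj_span_fs Total trajectory span, fs.
#' @param partition A `hydro_partition` (defines the layers), or an
#'   integer number of layers.
#' @param analysis_window_fs Window analysed at the end of the
#'   trajectory, fs (default 200 ps).
#' @param interval_fs Named or positional numeric vector of per-layer
#'   interval lengths, fs; recycled by the default rule "20 ps for
#'   layers 1-2, 5 ps beyond" when `NULL`.
#' @param n_intervals Number of tiles marked for averaging (default 10).
#' @param include_bulk Also emit intervals for the bulk population
#'   (layer 0), using the layer-1 interval length.
#' @return A tibble with `layer`, `interval`, `start_fs`, `end_fs`,
#'   `averaged`. Times are absolute (same origin as the trajectory,
#'   assumed to start at 0 and end at `traj_span_fs`).
#' @export
build_interval_scheme <- function(traj_span_fs, partition,
                                  analysis_window_fs = 200000,
                                  interval_fs = NULL,
                                  n_intervals = 10L,
                                  include_bulk = FALSE) {
  n_layers <- if (is.data.frame(partition)) nrow(partition) else as.integer(partition)
  if (analysis_window_fs > traj_span_fs + 1e-6) {
    abort("analysis window exceeds the trajectory span")
  }
  if (is.null(interval_fs)) {
    interval_fs <- ifelse(seq_len(n_layers) <= 2, 20000, 5000)
  }
  interval_fs <- rep_len(as.numeric(interval_fs), n_layers)
  layers <- seq_len(n_layers)
  if (include_bulk) {
    layers <- c(layers, 0L)
    interval_fs <- c(interval_fs, interval_fs[1])
  }
  window_start <- traj_span_fs - analysis_window_fs
  out <- purrr::map2_dfr(layers, interval_fs, function(ly, iv) {
    if (iv > analysis_window_fs + 1e-9) {
      abort(paste0("interval length ", iv, " fs exceeds the analysis window"))
    }
    n_tiles <- analysis_window_fs / iv
    if (abs(n_tiles - round(n_tiles)) > 1e-9) {
      abort(paste0("interval length ", iv,
                   " fs does not divide the analysis window of ",
                   analysis_window_fs, " fs"))
    }
    n_tiles <- as.integer(round(n_tiles))
    tibble(
      layer = ly,
      interval = seq_len(n_tiles),
      start_fs = window_start + (seq_len(n_tiles) - 1) * iv,
      end_fs = window_start + seq_len(n_tiles) * iv,
      averaged = seq_len(n_tiles) <= n_intervals
    )
  })
  class(out) <- c("hydro_intervals", class(out))
  out
}
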