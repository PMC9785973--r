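#' Interval-resolved layer membership table
#'
#' Applies the residence criterion to every (layer, interval) pair of
#' an interval scheme and returns the member molecules — the join used
#' by the per-layer spectral averages. Member sets of different layers
#' within the same interval are disjoint by construction (each molecule
#' has one label per frame, and the threshold exceeds 1/2).
#'
#' @param labels A `hydro_labels` matrix spanning at least the
#'   scheme's window.
#' @param scheme An interval scheme from [build_interval_scheme()].
#' @param threshold Residence occupancy threshold (default 0.9).
#' @return A tibble with `layer`, `interval`, `start_fs`, `end_fs`,
#'   `averaged`, `molecule_id`, `occupancy` — one row per member.
#' @export
interval_members <- function(labels, scheme, threshold = 0.9) {
  times <- attr(labels, "times")
  purrr::pmap_dfr(
    scheme[c("layer", "interval", "start_fs", "end_fs", "averaged")],
    function(layer, interval, start_fs, end_fs, averaged) {
      rows <- which(times >= start_fs - 1e-9 & times <= end_fs + 1e-9)
      if (length(rows) == 0) {
        abort(paste0("interval [", start_fs, ", ", end_fs,
                     "] fs contains no frames"))
      }
      mem <- residence_membership(labels, layer, threshold, frames = rows)
      mem <- mem[mem$member, ]
      if (nrow(mem) == 0) return(NULL)
      tibble(layer = layer, interval = interval, start_fs = start_fs,
             end_fs = end_fs, averaged = averaged,
             molecule_id = mem$molecule_id, occupancy = mem$occupancy)
    }
  )
}

# atom ids for a spectral kind over a set of molecule ids
select_atoms_for_kind <- function(topo, molecule_ids, kind) {
  rows <- topo$molecule_id %in% molecule_ids
  ids <- switch(kind,
    vdos_H = topo$atom_id[rows & topo$element == "H"],
    vdos_O = topo$atom_id[rows & topo$element == "O"],
    ir = topo$atom_id[rows]
  )
  if (length(ids) == 0) {
    abort(paste0("selection has no ",
                 switch(kind, vdos_H = "H atoms", vdos_O = "O atoms", "atoms"),
                 " for kind '", kind, "'"))
  }
  ids
}

# spectrum of one molecule set over one frame interval
interval_spectrum <- function(traj, topo, molecule_ids, kind, frames,
                              window, zero_pad_factor, max_lag_fs,
                              ir_mode = "collective") {
  sub <- subset_frames(traj, frames)
  if (is.null(max_lag_fs)) {
    max_lag_fs <- (sub$times[length(sub$times)] - sub$times[1]) / 2
  }
  if (kind %in% c("vdos_H", "vdos_O")) {
    atoms <- select_atoms_for_kind(topo, molecule_ids, kind)
    acf <- velocity_acf(sub, atoms, max_lag_fs = max_lag_fs, normalize = TRUE)
    acf_to_spectrum(acf, window = window, zero_pad_factor = zero_pad_factor,
                    meta = list(kind = kind))
  } else if (kind == "ir") {
    select_atoms_for_kind(topo, molecule_ids, "ir")
    if (ir_mode == "collective") {
      J <- dipole_flux(traj = sub, topo = topo, molecules = molecule_ids)
      facf <- flux_acf(J, max_lag_fs = max_lag_fs)
    } else {
      # per-molecule flux ACFs, averaged; equals the mean of the
      # per-molecule spectra by linearity of the transform
      acfs <- lapply(molecule_ids, function(m) {
        flux_acf(dipole_flux(sub, topo, m), max_lag_fs = max_lag_fs)
      })
      facf <- acfs[[1]]
      facf$value <- rowMeans(vapply(acfs, function(a) a$value,
                                    numeric(nrow(facf))))
    }
    ir_spectrum(facf, window = window, zero_pad_factor = zero_pad_factor,
                meta = list(ir_mode = ir_mode))
  } else {
    abort(paste0("unknown spectrum kind: ", kind))
  }
}

#' Average per-layer spectrum over residence intervals
#'
#' For each interval marked for averaging, computes the spectrum of
#' that interval's member molecules only — hydrogen or oxygen VDOS
#' from the normalized velocity ACF, or the IR lineshape from the
#' member set's collective dipole flux — and returns the unweighted
#' mean across intervals. `meta` records the kind, layer, number of
#' intervals averaged and the member counts.
#'
#' @param traj A `hydro_trajectory` with velocities.
#' @param topo The matching topology.
#' @param members A member table from [interval_members()], filtered to
#'   (or containing) the requested layer.
#' @param kind `"vdos_H"`, `"vdos_O"` or `"ir"`.
#' @param layer Layer index; defaults to the single layer present in
#'   `members`.
#' @param window,zero_pad_factor Passed to [acf_to_spectrum()].
#' @param max_lag_fs ACF truncation lag; default half the interval.
#' @param ir_mode `"collective"` (cross-molecular dipole correlations
#'   within the layer retained) or `"molecular"` (per-molecule flux
#'   ACFs averaged). The collective form is the default.
#' @return A `hydro_spectrum`.
#' @export
layer_spectrum <- function(traj, topo, members,
                           kind = c("vdos_H", "vdos_O", "ir"),
                           layer = NULL, window = "hann",
                           zero_pad_factor = 1L, max_lag_fs = NULL,
                           ir_mode = c("collective", "molecular")) {
  kind <- match.arg(kind)
  ir_mode <- match.arg(ir_mode)
  if (is.null(layer)) {
    layer <- unique(members$layer)
    if (length(layer) != 1) {
      abort("members spans several layers; give `layer` explicitly")
    }
  }
  mem <- members[members$layer == layer & members$averaged, ]
  if (nrow(mem) == 0) abort(paste0("no averaged intervals with members for layer ", layer))
  ivs <- unique(mem[c("interval", "start_fs", "end_fs")])
  spectra <- list()
  counts <- integer(0)
  for (r in seq_len(nrow(ivs))) {
    mols <- mem$molecule_id[mem$interval == ivs$interval[r]]
    if (length(mols) == 0) {
      warn(paste0("layer ", layer, " interval ", ivs$interval[r],
                  " has no members; skipped"))
      next
    }
    frames <- frame_window(traj, ivs$start_fs[r], ivs$end_fs[r])
    spectra[[length(spectra) + 1L]] <-
      interval_spectrum(traj, topo, mols, kind, frames, window,
                        zero_pad_factor, max_lag_fs, ir_mode)
    counts <- c(counts, length(mols))
  }
  if (length(spectra) == 0) abort("all intervals empty: no spectra to average")
  average_spectra(spectra, meta = list(
    kind = kind, layer = layer, n_intervals = length(spectra),
    member_counts = counts, window = window, ir_mode = ir_mode
  ))
}

average_spectra <- function(spectra, meta = list()) {
  wn <- spectra[[1]]$wavenumber
  for (s in spectra[-1]) {
    if (length(s$wavenumber) != length(wn) ||
        max(abs(s$wavenumber - wn)) > 1e-9) {
      abort("cannot average spectra on different wavenumber grids")
    }
  }
  intensity <- rowMeans(vapply(spectra, function(s) s$intensity,
                               numeric(length(wn))))
  new_spectrum(wn, intensity,
               modifyList(spectrum_meta(spectra[[1]]), meta))
}

#' Cumulative (summed-layer) spectrum
#'
#' Pools, per interval, the union of the member molecules of layers
#' `1..k` (optionally plus bulk, layer 0), computes the pooled spectrum
#' over that union, and averages across intervals — the "interface with
#' k solvation layers" view. All supplied member sets must share one
#' interval scheme, and member sets of different layers must be
#' disjoint within each interval. With every layer plus the bulk
#' included, the result equals the whole-selection spectrum.
#'
#' @inheritParams layer_spectrum
#' @param members Member table containing all layers to pool.
#' @param k Pool layers `1..k` (default: all layers present).
#' @param include_bulk Also pool the bulk (layer 0) members.
#' @return A `hydro_spectrum` with `meta$layer = "cumulative_1..k"`.
#' @export
cumulative_layer_spectrum <- function(traj, topo, members,
                                      kind = c("vdos_H", "vdos_O", "ir"),
                                      k = NULL, include_bulk = FALSE,
                                      window = "hann", zero_pad_factor = 1L,
                                      max_lag_fs = NULL,
                                      ir_mode = c("collective", "molecular")) {
  kind <- match.arg(kind)
  ir_mode <- match.arg(ir_mode)
  layers_present <- sort(unique(members$layer))
  if (is.null(k)) k <- max(layers_present)
  if (k < 1) abort("k must be at least 1")
  want <- seq_len(k)
  if (include_bulk) want <- c(want, 0L)
  mem <- members[members$layer %in% want & members$averaged, ]
  if (nrow(mem) == 0) abort("no members in the requested layers")
  ivs <- unique(mem[c("interval", "start_fs", "end_fs")])
  if (nrow(unique(mem[c("layer", "interval", "start_fs")])) !=
      nrow(unique(mem[c("layer", "interval")]))) {
    abort("member sets do not share a common interval scheme")
  }
  spectra <- list()
  counts <- integer(0)
  for (r in seq_len(nrow(ivs))) {
    rows <- mem$interval == ivs$interval[r] & mem$start_fs == ivs$start_fs[r]
    mols <- mem$molecule_id[rows]
    if (anyDuplicated(mols)) {
      abort(paste0("overlapping member sets in interval ", ivs$interval[r],
                   ": molecule ", mols[duplicated(mols)][1],
                   " belongs to more than one layer"))
    }
    frames <- frame_window(traj, ivs$start_fs[r], ivs$end_fs[r])
    spectra[[length(spectra) + 1L]] <-
      interval_spectrum(traj, topo, mols, kind, frames, window,
                        zero_pad_factor, max_lag_fs, ir_mode)
    counts <- c(counts, length(mols))
  }
  average_spectra(spectra, meta = list(
    kind = kind,
    layer = paste0("cumulative_1..", k, if (include_bulk) "+bulk" else ""),
    n_intervals = length(spectra), member_counts = counts,
    window = window, ir_mode = ir_mode
  ))
}
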