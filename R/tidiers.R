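#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy spectral and layering results
#'
#' `tidy()` returns the long per-observation table for a result object
#' (spectrum points with their metadata columns, band metrics with
#' shoulders unnested, partition layers); `glance()` returns a one-row
#' summary.
#'
#' @param x A `hydro_spectrum`, `hydro_profile`, `hydro_partition` or
#'   `hydro_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hydro_spectrum <- function(x, ...) {
  meta <- spectrum_meta(x)
  out <- tibble(wavenumber = x$wavenumber, intensity = x$intensity)
  if (!is.null(meta$kind)) out$kind <- meta$kind
  if (!is.null(meta$layer)) out$layer <- as.character(meta$layer)
  out
}

#' @rdname tidy.hydro_spectrum
#' @export
glance.hydro_spectrum <- function(x, ...) {
  meta <- spectrum_meta(x)
  pk <- which.max(x$intensity)
  tibble(
    kind = meta$kind %||% NA_character_,
    layer = as.character(meta$layer %||% NA),
    n_points = nrow(x),
    grid_step_cm1 = x$wavenumber[2] - x$wavenumber[1],
    max_wavenumber_cm1 = max(x$wavenumber),
    peak_cm1 = x$wavenumber[pk],
    peak_intensity = x$intensity[pk],
    window = meta$window %||% NA_character_,
    n_intervals = meta$n_intervals %||% NA_integer_
  )
}

#' @rdname tidy.hydro_spectrum
#' @export
tidy.hydro_partition <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.hydro_spectrum
#' @export
glance.hydro_profile <- function(x, ...) {
  pk <- which.max(x$density_g_cm3)
  tibble(
    n_bins = nrow(x),
    bin_width_A = x$bin_hi_A[1] - x$bin_lo_A[1],
    n_frames = attr(x, "n_frames"),
    method = attr(x, "method"),
    peak_distance_A = x$distance_A[pk],
    peak_density_g_cm3 = x$density_g_cm3[pk],
    far_field_g_cm3 = mean(x$density_g_cm3[ceiling(3 * nrow(x) / 4):nrow(x)])
  )
}

#' @rdname tidy.hydro_spectrum
#' @export
tidy.hydro_run <- function(x, ...) {
  purrr::imap_dfr(x$spectra, function(s, key) {
    out <- tidy(s)
    out$spectrum <- key
    out
  })
}

#' @rdname tidy.hydro_spectrum
#' @export
glance.hydro_run <- function(x, ...) {
  tibble(
    n_layers = nrow(x$partition),
    bulk_onset_A = max(partition_boundaries(x$partition)),
    n_spectra = length(x$spectra),
    n_members = nrow(x$members),
    config_hash = x$config_hash
  )
}
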