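#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_vline
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object A `hydro_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hydro_spectrum <- function(object, ...) {
  meta <- spectrum_meta(object)
  ttl <- paste(c(meta$kind, if (!is.null(meta$layer)) paste("layer", meta$layer)),
               collapse = ", ")
  ggplot(object, aes(x = .data$wavenumber, y = .data$intensity)) +
    geom_line() +
    labs(x = expression(tilde(nu) ~ (cm^-1)), y = "intensity (arb.)",
         title = ttl) +
    theme_minimal()
}

#' Plot a density profile, optionally with layer boundaries
#'
#' @param object A `hydro_profile`.
#' @param partition Optional `hydro_partition` whose boundaries are
#'   drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hydro_profile <- function(object, partition = NULL, ...) {
  p <- ggplot(object, aes(x = .data$distance_A, y = .data$density_g_cm3)) +
    geom_line() +
    labs(x = "distance from solute surface (Å)",
         y = expression(rho ~ (g ~ cm^-3))) +
    theme_minimal()
  if (!is.null(partition)) {
    p <- p + geom_vline(xintercept = partition_boundaries(partition),
                        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Overlay the per-layer spectra of a pipeline run
#'
#' @param run A `hydro_run`.
#' @param kind Spectrum kind to plot.
#' @param cumulative Plot the cumulative series instead of per-layer.
#' @return A ggplot.
#' @export
plot_layer_spectra <- function(run, kind = "vdos_H", cumulative = FALSE) {
  pat <- paste0("^", kind, if (cumulative) "_cumulative" else "_layer")
  keys <- grep(pat, names(run$spectra), value = TRUE)
  if (length(keys) == 0) abort(paste0("run has no spectra matching ", pat))
  df <- purrr::map_dfr(keys, function(k) {
    tibble(wavenumber = run$spectra[[k]]$wavenumber,
           intensity = run$spectra[[k]]$intensity,
           selection = sub(paste0("^", kind, "_"), "", k))
  })
  ggplot(df, aes(x = .data$wavenumber, y = .data$intensity,
                 colour = .data$selection)) +
    geom_line() +
    labs(x = expression(tilde(nu) ~ (cm^-1)), y = "intensity (arb.)",
         title = kind, colour = NULL) +
    theme_minimal()
}
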