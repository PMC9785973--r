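#' Default spectral bands for water
#'
#' The conventional decomposition of water spectra: an acoustic region
#' below 130 cm^-1, the libration-rotational band up to ~1300 cm^-1,
#' the H-O-H bend near 1650 cm^-1, and the O-H stretch between 3250
#' and 3750 cm^-1.
#'
#' @return A tibble with `band`, `lo_cm1`, `hi_cm1`.
#' @export
default_bands <- function() {
  tibble(
    band = c("acoustic", "libration", "bend", "stretch"),
    lo_cm1 = c(0, 130, 1400, 3250),
    hi_cm1 = c(130, 1300, 1800, 3750)
  )
}

# linear-interpolated full width at half maximum within a band;
# NA when either half-max crossing lies outside the band
band_fwhm <- function(wn, intensity, peak_idx) {
  half <- intensity[peak_idx] / 2
  left <- NA_real_
  if (peak_idx > 1) {
    for (i in peak_idx:2) {
      if (intensity[i - 1] <= half && intensity[i] >= half) {
        left <- wn[i - 1] + (half - intensity[i - 1]) /
          (intensity[i] - intensity[i - 1]) * (wn[i] - wn[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  n <- length(wn)
  if (peak_idx < n) {
    for (i in peak_idx:(n - 1)) {
      if (intensity[i] >= half && intensity[i + 1] <= half) {
        right <- wn[i] + (intensity[i] - half) /
          (intensity[i] - intensity[i + 1]) * (wn[i + 1] - wn[i])
        break
      }
    }
  }
  right - left
}

# shoulder candidates: local minima of the smoothed second derivative
# (negative-curvature pockets) away from the main peak
find_shoulders <- function(wn, intensity, peak_idx, sg_window) {
  n <- length(intensity)
  if (n < sg_window + 2) return(numeric(0))
  dx <- wn[2] - wn[1]
  d2 <- signal::sgolayfilt(intensity, p = 3, n = sg_window, m = 2, ts = dx)
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (d2[i] < d2[i - 1] && d2[i] <= d2[i + 1] && d2[i] < 0) {
      idx <- c(idx, i)
    }
  }
  # drop the curvature minimum belonging to the main peak itself
  idx <- idx[abs(idx - peak_idx) > max(2L, sg_window %/% 2)]
  wn[idx]
}

#' Summarise spectral bands
#'
#' For each named band: the argmax peak position and intensity, the
#' full width at half maximum by linear interpolation at half-max
#' (NA when a flank leaves the band), and shoulder positions detected
#' as negative-curvature pockets of the Savitzky-Golay-smoothed second
#' derivative away from the main peak. Bands with all-zero intensity
#' yield NA metrics.
#'
#' @param s A `hydro_spectrum`.
#' @param bands A tibble like [default_bands()] (`band`, `lo_cm1`,
#'   `hi_cm1`); bands must lie within the spectrum range.
#' @param sg_window Odd Savitzky-Golay window length in grid points for
#'   shoulder detection (default 11).
#' @return A tibble with one row per band: `band`, `lo_cm1`, `hi_cm1`,
#'   `peak_cm1`, `peak_intensity`, `fwhm_cm1` and a list-column
#'   `shoulders_cm1`.
#' @export
band_summary <- function(s, bands = default_bands(), sg_window = 11L) {
  if (sg_window %% 2 == 0) abort("sg_window must be odd")
  if (max(bands$hi_cm1) > max(s$wavenumber) + 1e-9) {
    abort("bands extend beyond the spectrum range")
  }
  purrr::pmap_dfr(bands, function(band, lo_cm1, hi_cm1) {
    sel <- which(s$wavenumber >= lo_cm1 & s$wavenumber < hi_cm1)
    wn <- s$wavenumber[sel]
    it <- s$intensity[sel]
    if (length(sel) == 0 || all(it == 0)) {
      return(tibble(band = band, lo_cm1 = lo_cm1, hi_cm1 = hi_cm1,
                    peak_cm1 = NA_real_, peak_intensity = NA_real_,
                    fwhm_cm1 = NA_real_, shoulders_cm1 = list(numeric(0))))
    }
    pk <- which.max(it)
    win <- min(sg_window, if (length(it) %% 2 == 1) length(it) else length(it) - 1L)
    sh <- if (win >= 5) find_shoulders(wn, it, pk, win) else numeric(0)
    tibble(band = band, lo_cm1 = lo_cm1, hi_cm1 = hi_cm1,
           peak_cm1 = wn[pk], peak_intensity = it[pk],
           fwhm_cm1 = band_fwhm(wn, it, pk),
           shoulders_cm1 = list(sh))
  })
}
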