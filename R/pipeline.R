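#' Pipeline run configuration
#'
#' Collects every tunable of the layer-resolved analysis with defaults
#' matching the reference protocol: the last 200 ps of the trajectory
#' analysed, residence threshold 0.90, interval lengths of 20 ps for
#' layers 1-2 and 5 ps for the outer layers, spectra averaged over the
#' first 10 intervals of each layer, boundaries detected from the
#' density profile (`boundaries = "auto"`) or given explicitly.
#'
#' @param analysis_window_fs Analysis window at the end of the
#'   trajectory, fs (default 200 ps).
#' @param interval_fs Per-layer interval lengths, fs; `NULL` applies
#'   the default rule (20 ps for layers 1-2, 5 ps beyond).
#' @param n_intervals Intervals averaged per layer (default 10).
#' @param residence_threshold Occupancy threshold (default 0.90).
#' @param boundaries `"auto"` or an explicit increasing numeric vector
#'   of boundary distances, A.
#' @param bin_width,max_distance Density-profile binning, A.
#' @param density_method `"voronoi"` or `"bin_volume"`.
#' @param smoothing_window,bulk_tolerance Passed to
#'   [detect_boundaries()].
#' @param window,zero_pad_factor,ir_mode Spectral options.
#' @param bands Band table for [band_summary()].
#' @param heavy_only Solute heavy atoms only for distances.
#' @param profile_frames Number of frames sampled for the density
#'   profile (`NULL` = all frames in the window).
#' @param seed Seed recorded with the run.
#' @return A list of class `hydro_config`.
#' @export
hydrolayer_config <- function(analysis_window_fs = 200000,
                              interval_fs = NULL,
                              n_intervals = 10L,
                              residence_threshold = 0.90,
                              boundaries = "auto",
                              bin_width = 0.25,
                              max_distance = 12,
                              density_method = "voronoi",
                              smoothing_window = 5L,
                              bulk_tolerance = 0.05,
                              window = "hann",
                              zero_pad_factor = 1L,
                              ir_mode = "collective",
                              bands = default_bands(),
                              heavy_only = TRUE,
                              profile_frames = NULL,
                              seed = 1L) {
  cfg <- list(
    analysis_window_fs = analysis_window_fs,
    interval_fs = interval_fs,
    n_intervals = as.integer(n_intervals),
    residence_threshold = residence_threshold,
    boundaries = boundaries,
    bin_width = bin_width,
    max_distance = max_distance,
    density_method = density_method,
    smoothing_window = as.integer(smoothing_window),
    bulk_tolerance = bulk_tolerance,
    window = window,
    zero_pad_factor = as.integer(zero_pad_factor),
    ir_mode = ir_mode,
    bands = as.data.frame(bands),
    heavy_only = heavy_only,
    profile_frames = profile_frames,
    seed = as.integer(seed)
  )
  class(cfg) <- "hydro_config"
  cfg
}

#' Serialize / load a configuration as YAML
#'
#' @param cfg A `hydro_config`.
#' @param path File path.
#' @return `read_config()` returns a `hydro_config`.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$bands <- as.list(as.data.frame(x$bands))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- as_tibble(as.data.frame(x$bands))
  if (!is.null(x$boundaries) && is.list(x$boundaries)) {
    x$boundaries <- unlist(x$boundaries)
  }
  do.call(hydrolayer_config, x)
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$bands <- as.data.frame(x$bands)
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 15)),
               collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full layer-resolved spectral pipeline
#'
#' Orchestrates the whole workflow on a trajectory + topology pair:
#' density profile, boundary detection (or explicit boundaries),
#' per-frame layer labels, interval scheme, residence membership,
#' per-layer and cumulative VDOS (H and O) and IR spectra, and band
#' summaries. With `out_dir` set, writes `density_profile.csv`,
#' `layers.json`, `vdos_H_layer{k}.csv`, `vdos_O_layer{k}.csv`,
#' `ir_layer{k}.csv`, the `*_cumulative{1..k}.csv` series,
#' `bands.json`, the effective `config.yaml` and `run.log`; every
#' output carries the config hash. Deterministic given config and
#' inputs.
#'
#' Cumulative spectra pool membership evaluated on the layer-1
#' (coarsest) interval scheme, the only construction under which
#' per-interval unions of layers with different native interval
#' lengths are well defined.
#'
#' @param traj A `hydro_trajectory` with velocities.
#' @param topo The matching topology.
#' @param config A [hydrolayer_config()].
#' @param out_dir Output directory (`NULL` = return results only).
#' @param kinds Spectrum kinds to compute.
#' @param cumulative Also compute cumulative spectra (default TRUE).
#' @return A list of class `hydro_run`: `profile`, `partition`,
#'   `members`, `spectra` (named list), `bands` (tibble), `config`,
#'   `log` (character).
#' @export
run_pipeline <- function(traj, topo, config = hydrolayer_config(),
                         out_dir = NULL,
                         kinds = c("vdos_H", "vdos_O", "ir"),
                         cumulative = TRUE) {
  logline <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    logline <<- c(logline, msg)
    inform(paste0("[hydrolayer] ", msg))
  }
  hash <- config_hash(config)
  note("config hash: ", hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  require_velocities(traj, "run_pipeline()")
  span <- traj$times[n_frames(traj)] - traj$times[1]
  win_start <- traj$times[n_frames(traj)] - config$analysis_window_fs
  win_frames <- which(traj$times >= win_start - 1e-9)
  note("analysis window: last ", config$analysis_window_fs, " fs (",
       length(win_frames), " frames of ", n_frames(traj), ")")

  profile <- stage("density_profile", {
    pf <- win_frames
    if (!is.null(config$profile_frames) &&
        config$profile_frames < length(pf)) {
      pf <- pf[unique(round(seq(1, length(pf),
                                length.out = config$profile_frames)))]
    }
    density_profile(traj, topo, bin_width = config$bin_width,
                    max_distance = config$max_distance,
                    method = config$density_method, frames = pf,
                    heavy_only = config$heavy_only)
  })

  partition <- stage("boundaries", {
    if (identical(config$boundaries, "auto")) {
      detect_boundaries(profile, config$smoothing_window,
                        config$bulk_tolerance)
    } else {
      layer_partition(config$boundaries)
    }
  })
  note("boundaries (A): ",
       paste(round(partition_boundaries(partition), 3), collapse = ", "))

  labels <- stage("layer_labels", {
    layer_labels(traj, topo, partition, frames = win_frames,
                 heavy_only = config$heavy_only)
  })

  scheme <- stage("interval_scheme", {
    build_interval_scheme(span, partition,
                          analysis_window_fs = config$analysis_window_fs,
                          interval_fs = config$interval_fs,
                          n_intervals = config$n_intervals,
                          include_bulk = TRUE)
  })

  members <- stage("residence_membership", {
    interval_members(labels, scheme, config$residence_threshold)
  })
  for (ly in sort(unique(scheme$layer))) {
    cnt <- members[members$layer == ly & members$averaged, ]
    note("layer ", ly, ": members per averaged interval = ",
         paste(table(factor(cnt$interval,
                            levels = unique(cnt$interval))), collapse = ", "))
  }

  spectra <- list()
  n_layers <- nrow(partition)
  for (kind in kinds) {
    for (ly in seq_len(n_layers)) {
      key <- paste0(kind, "_layer", ly)
      has <- any(members$layer == ly & members$averaged)
      if (!has) {
        note("skipping ", key, ": no members")
        next
      }
      spectra[[key]] <- stage(key, layer_spectrum(
        traj, topo, members, kind = kind, layer = ly,
        window = config$window, zero_pad_factor = config$zero_pad_factor,
        ir_mode = config$ir_mode
      ))
    }
    if (cumulative) {
      # common (layer-1) scheme for pooled membership
      base_iv <- if (is.null(config$interval_fs)) 20000 else config$interval_fs[1]
      cum_scheme <- build_interval_scheme(
        span, partition, analysis_window_fs = config$analysis_window_fs,
        interval_fs = rep(base_iv, n_layers),
        n_intervals = config$n_intervals, include_bulk = TRUE
      )
      cum_members <- interval_members(labels, cum_scheme,
                                      config$residence_threshold)
      for (k in seq_len(n_layers)) {
        key <- paste0(kind, "_cumulative", k)
        ok <- any(cum_members$layer %in% seq_len(k) & cum_members$averaged)
        if (!ok) next
        spectra[[key]] <- stage(key, cumulative_layer_spectrum(
          traj, topo, cum_members, kind = kind, k = k,
          window = config$window, zero_pad_factor = config$zero_pad_factor,
          ir_mode = config$ir_mode
        ))
      }
    }
  }
  if (length(spectra) == 0) abort("pipeline produced no spectra")

  bands_tbl <- stage("band_summary", {
    purrr::imap_dfr(spectra, function(s, key) {
      bs <- band_summary(s, bands = as_tibble(config$bands))
      bs$spectrum <- key
      bs
    })
  })

  result <- structure(
    list(profile = profile, partition = partition, members = members,
         scheme = scheme, spectra = spectra, bands = bands_tbl,
         config = config, config_hash = hash, log = logline),
    class = "hydro_run"
  )
  if (!is.null(out_dir)) write_run_bundle(result, out_dir)
  result
}

write_run_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$config_hash
  write_density_profile(result$profile, file.path(out_dir, "density_profile.csv"))
  layers_json <- list(
    config_hash = hash,
    boundaries_A = partition_boundaries(result$partition),
    members = lapply(split(result$members, result$members$layer), function(df) {
      lapply(split(df, df$interval), function(iv) {
        list(start_fs = iv$start_fs[1], end_fs = iv$end_fs[1],
             molecule_ids = iv$molecule_id, occupancy = iv$occupancy)
      })
    })
  )
  jsonlite::write_json(layers_json, file.path(out_dir, "layers.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(result$spectra)) {
    s <- result$spectra[[key]]
    attr(s, "meta") <- modifyList(spectrum_meta(s), list(config_hash = hash))
    write_spectrum(s, file.path(out_dir, paste0(key, ".csv")), "csv")
  }
  bands_out <- result$bands
  bands_out$shoulders_cm1 <- lapply(bands_out$shoulders_cm1, as.numeric)
  jsonlite::write_json(list(config_hash = hash, bands = bands_out),
                       file.path(out_dir, "bands.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(result$config, file.path(out_dir, "config.yaml"))
  writeLines(c(paste0("config_hash: ", hash), result$log),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.hydro_run <- function(x, ...) {
  cat("<hydro_run> ", nrow(x$partition), " layers; ",
      length(x$spectra), " spectra; config ", x$config_hash, "\n", sep = "")
  invisible(x)
}
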