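#' Pipeline run configuration
#'
#' Flat key-value settings covering every stage default; any subset can be
#' overridden.  An effective-config dump is written with every
#' [run_pipeline()] invocation.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1,
    n_series = 2, tilt_min = -60, tilt_max = 60, tilt_step = 1,
    pixel_size = 1, detector_nx = 256, detector_ny = 256,
    n_beads = 50, bead_radius = 3, bead_density = 1, thickness = 60,
    gamma_x = 0.03, gamma_y = 0.03, gamma_z = 0.15, tau_factor = 1.5,
    noise_gaussian_sigma = 0.5, noise_poisson = FALSE,
    detect_sigma = 2, detect_threshold = 0.1, detect_polarity = "bright",
    match_radius = 5, min_track_length = 10,
    align_order = 1,
    recon_nx = 256, recon_ny = 256, recon_nz = 64, recon_voxel = 1,
    recon_bin = 1, recon_filter = "shepp-logan",
    wsirt_iterations = 50, wsirt_alpha = 2,
    series_subset = 0
  )
  cfg <- modifyList(defaults, list(...))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the flat key-value text format.
#' @export
write_run_config <- function(config, path) {
  writeLines(paste(names(config), vapply(config, as.character, character(1))),
             path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  kv <- strsplit(readLines(path), " ", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = " ")
    suppressWarnings(
      if (!is.na(as.numeric(v))) as.numeric(v)
      else if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else v
    )
  })
  do.call(run_config, setNames(vals, vapply(kv, `[[`, character(1), 1)))
}

cfg_scheme <- function(cfg) {
  tilt_scheme(cfg$n_series, cfg$tilt_min, cfg$tilt_max, cfg$tilt_step,
              cfg$pixel_size, c(cfg$detector_nx, cfg$detector_ny))
}

#' Run the synthetic multi-tilt pipeline
#'
#' Executes the requested stages in order, each communicating with the next
#' only through on-disk artifacts in `dir` (MRC stacks, map text files,
#' CSV tables), so stages are independently re-runnable.  Per-stage timing
#' goes to `message()`; a failing stage halts with a stage-named error.
#'
#' @param config A [run_config()].
#' @param dir Run directory for all artifacts.
#' @param stages Character vector from `c("simulate", "detect", "track",
#'   "align", "deform_fit", "recon_fbp", "recon_wsirt", "cv")`.
#' @return Invisibly, a named list of the per-stage summary values.
#' @export
run_pipeline <- function(config = run_config(), dir = "multitilt_run",
                         stages = c("simulate", "detect", "track", "align",
                                    "deform_fit", "recon_fbp", "cv")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(dir, "effective_config.txt"))
  out <- list()
  for (stage in stages) {
    t0 <- Sys.time()
    out[[stage]] <- tryCatch(
      run_stage(stage, config, dir),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(out)
}

run_stage <- function(stage, cfg, dir) {
  pth <- function(f) file.path(dir, f)
  need <- function(f, what) {
    if (!file.exists(pth(f))) {
      stop("missing ", what, " (", f, "); run the producing stage first",
           call. = FALSE)
    }
    pth(f)
  }
  scheme <- cfg_scheme(cfg)
  read_stacks <- function() {
    lapply(seq_len(scheme$n_series), function(s) {
      read_mrc(need(sprintf("series_%02d.mrc", s), "simulated stack"))$data
    })
  }
  switch(stage,
    simulate = {
      ph <- random_phantom(cfg$n_beads,
                           extent = c(cfg$detector_nx * cfg$pixel_size,
                                      cfg$detector_ny * cfg$pixel_size,
                                      cfg$thickness),
                           radius = cfg$bead_radius,
                           density = cfg$bead_density, seed = cfg$seed)
      model <- deformation_model(c(cfg$gamma_x, cfg$gamma_y, cfg$gamma_z),
                                 tau = cfg$tau_factor *
                                   length(scheme$tilt_angles))
      sim <- simulate_tilt_series(ph, scheme, model,
                                  noise = list(
                                    gaussian_sigma = cfg$noise_gaussian_sigma,
                                    poisson = cfg$noise_poisson),
                                  seed = cfg$seed, dir = dir)
      list(n_micrographs = nrow(scheme$micrographs),
           n_beads = nrow(ph$beads))
    },
    detect = {
      det <- detect_beads_stack(read_stacks(), scheme, cfg$detect_sigma,
                                cfg$detect_threshold, cfg$detect_polarity)
      write.csv(det, pth("detections.csv"), row.names = FALSE)
      list(n_detections = nrow(det))
    },
    track = {
      det <- tibble::as_tibble(read.csv(need("detections.csv", "detections")))
      ts <- build_tracks(det, nominal_maps(scheme), scheme,
                         cfg$match_radius, cfg$min_track_length)
      write_tracks(dplyr::rename(ts$tracks, x_px = "x", y_px = "y") |>
                     dplyr::left_join(scheme$micrographs,
                                      by = "i_omega"),
                   pth("tracks.csv"))
      list(n_tracks = sum(ts$positions3d$usable))
    },
    align = {
      tr <- read_tracks(need("tracks.csv", "tracks"))
      ba <- bundle_adjust(tr, scheme, order = cfg$align_order)
      write_projection_maps(ba$maps, pth("aligned_maps.txt"))
      write.csv(ba$residuals, pth("residuals.csv"), row.names = FALSE)
      list(rms_residual = ba$rms_residual)
    },
    deform_fit = {
      maps <- read_projection_maps(need("aligned_maps.txt", "aligned maps"))
      s1 <- scheme$micrographs[scheme$micrographs$series == 1, ]
      pin <- s1$i_omega[which.min(abs(s1$tilt_deg))]
      fit <- fit_deformation(n3_series(maps), scheme, reference = pin)
      writeLines(paste(fit$estimates$term, fit$estimates$estimate,
                       fit$estimates$std.error),
                 pth("deformation_fit.txt"))
      write.csv(fit$n3, pth("n3_series.csv"), row.names = FALSE)
      as.list(setNames(fit$estimates$estimate, fit$estimates$term))
    },
    recon_fbp = ,
    recon_wsirt = {
      maps_file <- if (file.exists(pth("aligned_maps.txt")))
        "aligned_maps.txt" else "ground_truth_maps.txt"
      maps <- read_projection_maps(need(maps_file, "projection maps"))
      stacks <- read_stacks()
      nsub <- if (cfg$series_subset > 0)
        min(cfg$series_subset, scheme$n_series) else scheme$n_series
      mic <- scheme$micrographs[scheme$micrographs$series <= nsub, ]
      images <- purrr::map(mic$i_omega, function(i) {
        s <- mic$series[match(i, mic$i_omega)]
        j <- which(scheme$micrographs$i_omega[
          scheme$micrographs$series == s] == i)
        bin_image(stacks[[s]][, , j], cfg$recon_bin)
      })
      use_maps <- purrr::map(mic$i_omega, ~ bin_map(maps[[.x]],
                                                    cfg$recon_bin))
      spec <- volume_spec(
        c(cfg$recon_nx, cfg$recon_ny, cfg$recon_nz) %/% cfg$recon_bin,
        cfg$recon_voxel * cfg$recon_bin)
      if (stage == "recon_fbp") {
        vol <- fbp(images, use_maps, spec, filter = cfg$recon_filter)
        write_volume(vol, pth("volume_fbp.mrc"))
        list(volume = "volume_fbp.mrc")
      } else {
        vol <- wsirt(images, use_maps, spec,
                     iterations = cfg$wsirt_iterations,
                     alpha = cfg$wsirt_alpha)
        write_volume(vol, pth("volume_wsirt.mrc"))
        write.csv(tibble::tibble(
          iteration = seq_along(vol$residual_history),
          relative_residual = vol$residual_history),
          pth("wsirt_residuals.csv"), row.names = FALSE)
        list(volume = "volume_wsirt.mrc",
             final_residual = vol$residual_history[cfg$wsirt_iterations])
      }
    },
    cv = {
      f <- if (file.exists(pth("volume_wsirt.mrc"))) "volume_wsirt.mrc"
        else "volume_fbp.mrc"
      v <- read_mrc(need(f, "reconstruction"))
      list(cv = coefficient_of_variation(v$data))
    },
    stop("unknown stage '", stage, "'", call. = FALSE)
  )
}

#' Bin an image (or projection map) by an integer factor
#'
#' @param image Image matrix.
#' @param k Binning factor (1 = no binning).
#' @return Binned image (mean pooling).
#' @export
bin_image <- function(image, k = 1) {
  if (k <= 1) return(image)
  nx <- (nrow(image) %/% k) * k; ny <- (ncol(image) %/% k) * k
  im <- image[1:nx, 1:ny]
  im <- rowsum(im, rep(seq_len(nx %/% k), each = k))
  t(rowsum(t(im), rep(seq_len(ny %/% k), each = k))) / k^2
}

#' @rdname bin_image
#' @param map A [projection_map()].
#' @export
bin_map <- function(map, k = 1) {
  if (k <= 1) return(map)
  co <- map$coefficients / k
  co[, 1] <- co[, 1] - (k - 1) / (2 * k)   # binned pixel centres
  projection_map(co, pixel_size = map$pixel_size * k)
}
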