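#' Reconstruction grid specification
#'
#' @param dim Voxel counts `c(nx, ny, nz)`.
#' @param voxel_size Voxel edge, nm.
#' @param origin Specimen-frame coordinate of voxel `(0, 0, 0)`; defaults to
#'   centring the grid on the origin.
#' @return A `volume_spec` object.
#' @export
volume_spec <- function(dim, voxel_size = 1, origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_size > 0)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * voxel_size
  structure(list(dim = dim, voxel_size = voxel_size, origin = origin),
            class = "volume_spec")
}

new_volume <- function(data, spec, coverage = NULL) {
  structure(list(data = data, spec = spec, coverage = coverage),
            class = "mt_volume")
}

#' @export
print.mt_volume <- function(x, ...) {
  cat("<mt_volume>", paste(x$spec$dim, collapse = " x "), "voxels at",
      x$spec$voxel_size, "nm; range [",
      signif(min(x$data), 4), ",", signif(max(x$data), 4), "]\n")
  invisible(x)
}

#' Write a reconstruction to MRC
#' @param volume An `mt_volume`.
#' @param path Output path.
#' @export
write_volume <- function(volume, path) {
  write_mrc(volume$data, path, voxel_size = volume$spec$voxel_size,
            is_stack = FALSE)
}

beam_path_factor <- function(map, voxel_size) {
  # quadrature weight of the voxel-driven line integral: voxel volume over
  # detector pixel area.  The 1/cos(beam, z) obliquity factor arises
  # automatically from voxel crowding (the in-plane-to-detector Jacobian)
  # and must not be applied again.
  voxel_size^3 / map$pixel_size^2
}

#' Reproject a volume through a projection map
#'
#' Voxel-driven forward projection: every voxel is pushed through the map
#' and splatted bilinearly into the detector, weighted by the beam path
#' length per voxel, approximating the density line integral.  This operator
#' and [backproject()] are exact transposes of each other, which is what the
#' iterative reconstruction relies on.  For maps of order > 1 the voxels
#' follow the polynomial map directly, so bent rays emerge naturally
#' (experimental).
#'
#' @param volume An `mt_volume`, or a 3D array together with `spec`.
#' @param map A [projection_map()].
#' @param image_shape Detector dimensions `c(nx, ny)`.
#' @param spec A [volume_spec()] (only needed when `volume` is an array).
#' @return Numeric image matrix.
#' @export
reproject <- function(volume, map, image_shape = c(256L, 256L), spec = NULL) {
  if (inherits(volume, "mt_volume")) {
    spec <- volume$spec; vol <- volume$data
  } else vol <- volume
  stopifnot(inherits(spec, "volume_spec"))
  expo <- monomial_exponents(map$order)
  proj_fwd_cpp(as.numeric(vol), spec$dim, spec$origin, spec$voxel_size,
               map$coefficients, expo, image_shape[1], image_shape[2],
               beam_path_factor(map, spec$voxel_size))
}

#' Backproject micrographs into a volume
#'
#' For each voxel centre, accumulates bilinear samples of every micrograph
#' at the voxel's projection, times the per-micrograph weight and the beam
#' path factor.  A coverage map (number of micrographs whose field of view
#' fully contains each voxel's projection) is attached; optional
#' normalization divides by summed weight times coverage.
#'
#' @param images List of image matrices (global `i_omega` order).
#' @param maps List of [projection_map()]s, same order and length.
#' @param spec A [volume_spec()].
#' @param weights Per-micrograph weights (default 1).
#' @param normalize Divide by total weight per covered voxel.
#' @return An `mt_volume` with a `coverage` integer array.
#' @export
backproject <- function(images, maps, spec, weights = NULL,
                        normalize = FALSE) {
  stopifnot(length(images) == length(maps))
  if (is.null(weights)) weights <- rep(1, length(images))
  vol <- numeric(prod(spec$dim))
  cover <- integer(prod(spec$dim))
  for (i in seq_along(images)) {
    expo <- monomial_exponents(maps[[i]]$order)
    out <- proj_back_cpp(images[[i]] * weights[i], spec$dim, spec$origin,
                         spec$voxel_size, maps[[i]]$coefficients, expo,
                         beam_path_factor(maps[[i]], spec$voxel_size),
                         vol, cover)
    vol <- out$vol; cover <- out$cover
  }
  if (normalize) {
    w <- sum(weights) * pmax(cover, 1) / length(images)
    vol <- vol / w
  }
  new_volume(array(vol, spec$dim), spec, array(cover, spec$dim))
}

ramp_kernel <- function(kind, len) {
  k <- -(len - 1):(len - 1)
  h <- switch(kind,
    "shepp-logan" = 2 / (pi^2 * (1 - 4 * k^2)),
    "ram-lak" = ifelse(k == 0, 1 / 4,
                       ifelse(k %% 2 == 0, 0, -1 / (pi^2 * k^2))),
    stop("unknown filter kind ", kind, call. = FALSE)
  )
  h
}

filter_direction <- function(map) {
  g <- tryCatch(ray_geometry(map), error = function(e) NULL)
  if (is.null(g)) return("x")
  b <- g$b
  if (sqrt(b[1]^2 + b[2]^2) < 1e-9) return("x")  # untilted: convention
  axis3 <- c(-b[2], b[1], 0)                     # lab tilt axis = z x beam
  axis2 <- as.numeric(g$M %*% axis3)
  perp <- c(-axis2[2], axis2[1])
  if (abs(perp[1]) >= abs(perp[2])) "x" else "y"
}

#' Ramp-filter a micrograph for filtered back-projection
#'
#' 1D convolution with the discrete Shepp-Logan kernel
#' `2 / (pi^2 (1 - 4 k^2))` (or the Ram-Lak kernel) along the detector
#' direction perpendicular to the projected tilt axis, derived from the
#' map's beam direction (with this package's acquisition convention the
#' goniometer axis is fixed along detector y, so filtering runs along x).
#' The convolution is done by FFT after zero-padding to the next power of
#' two at least twice the filtered width.
#'
#' @param image Image matrix.
#' @param map The micrograph's [projection_map()] (affine), used only to
#'   derive the filtering direction; may be `NULL` if `axis` is given.
#' @param filter `"shepp-logan"`, `"ram-lak"` or `"none"`.
#' @param axis Optional explicit filtering axis, `"x"` or `"y"`.
#' @return Filtered image matrix.
#' @export
filter_micrograph <- function(image, map = NULL, filter = "shepp-logan",
                              axis = NULL) {
  if (filter == "none") return(image)
  if (is.null(axis)) {
    axis <- if (is.null(map)) "x" else filter_direction(map)
  }
  work <- if (axis == "x") image else t(image)
  n <- nrow(work)
  pad <- 2^ceiling(log2(2 * n))
  h <- ramp_kernel(filter, n)
  hp <- numeric(pad)
  hp[1:n] <- h[n:(2 * n - 1)]            # k = 0 .. n-1
  hp[(pad - n + 2):pad] <- h[1:(n - 1)]  # k = -(n-1) .. -1, wrapped
  Hf <- fft(hp)
  wp <- matrix(0, pad, ncol(work))
  wp[1:n, ] <- work
  conv <- Re(mvfft(mvfft(wp) * Hf, inverse = TRUE)) / pad
  out <- conv[1:n, , drop = FALSE]
  if (axis == "x") out else t(out)
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filters every micrograph and backprojects with weight
#' `pi / n_micrographs`, so reconstructions from different series counts of
#' the same specimen are on a common density scale.  Deterministic and
#' linear in the input stack.
#'
#' @inheritParams backproject
#' @param filter Filter kind for [filter_micrograph()].
#' @return An `mt_volume`.
#' @export
fbp <- function(images, maps, spec, filter = "shepp-logan") {
  if (length(images) == 0) {
    return(new_volume(array(0, spec$dim), spec,
                      array(0L, spec$dim)))
  }
  filtered <- purrr::map2(images, maps,
                          ~ filter_micrograph(.x, .y, filter = filter))
  backproject(filtered, maps, spec,
              weights = rep(pi / length(images), length(images)))
}

#' Weighted SIRT reconstruction
#'
#' Iterative reconstruction with weighting along trajectory paths.  Each
#' sweep visits every micrograph (in a bit-reversed, MAS-style order that
#' maximally spreads consecutive view angles, which speeds convergence) and
#' applies the weighted correction
#'
#'   x <- x + (alpha / 2) * C_w Bt_w R_w (v_w - reproject_w(x))
#'
#' where, per micrograph w, `R_w` divides each ray residual by the ray's
#' path length through the volume, `Bt_w` is the exact transpose of the
#' forward projector, and `C_w` divides each voxel by its ray coverage (the
#' column sums of the weighted projector).  The correction is normalized so
#' that the mixing parameter `alpha = 2` (the reference operating point,
#' with 50 iterations) applies exactly the unit-relaxation weighted
#' correction; the scheme is stable for `alpha` in (0, 4).  The relative
#' projection residual `||v - v_i|| / ||v||` is recorded per sweep;
#' residual growth over 5 consecutive sweeps aborts with an error carrying
#' the history (smaller `alpha` is the remedy).
#'
#' @inheritParams backproject
#' @param iterations Number of sweeps over all micrographs (default 50).
#' @param alpha Mixing (relaxation) parameter (>= 0; default 2).
#' @return An `mt_volume` with the per-sweep `residual_history` attached.
#' @export
wsirt <- function(images, maps, spec, iterations = 50, alpha = 2) {
  stopifnot(iterations >= 1, alpha >= 0, length(images) == length(maps))
  n <- length(images)
  shape <- dim(images[[1]])
  expos <- purrr::map(maps, ~ monomial_exponents(.x$order))
  pf <- vapply(maps, beam_path_factor, numeric(1),
               voxel_size = spec$voxel_size)
  nv <- prod(spec$dim)
  ones_img <- matrix(1, shape[1], shape[2])

  # per-view row weights (1 / ray path length) and column weights
  # (1 / weighted coverage)
  ray_w <- vector("list", n)
  col_w <- vector("list", n)
  cover <- integer(nv)
  for (i in seq_len(n)) {
    L <- proj_fwd_cpp(rep(1, nv), spec$dim, spec$origin, spec$voxel_size,
                      maps[[i]]$coefficients, expos[[i]], shape[1], shape[2],
                      pf[i])
    ray_w[[i]] <- ifelse(L > 1e-6 * spec$voxel_size, 1 / pmax(L, 1e-12), 0)
    out <- proj_back_cpp(ones_img, spec$dim, spec$origin, spec$voxel_size,
                         maps[[i]]$coefficients, expos[[i]], pf[i],
                         numeric(nv), cover)
    cs <- out$vol; cover <- out$cover
    col_w[[i]] <- ifelse(cs > 1e-6 * max(cs), 1 / pmax(cs, 1e-12), 0)
  }

  # MAS-style bit-reversed processing order over the view sequence
  bits <- max(1, ceiling(log2(n)))
  brev <- vapply(0:(n - 1), function(k) {
    b <- 0L
    for (j in seq_len(bits)) {
      b <- b * 2L + k %% 2L
      k <- k %/% 2L
    }
    b
  }, integer(1))
  view_order <- order(brev)

  v_norm <- sqrt(sum(vapply(images, function(im) sum(im^2), numeric(1))))
  x <- numeric(nv)
  history <- numeric(iterations)
  grow <- 0
  for (it in seq_len(iterations)) {
    res2 <- 0
    for (i in view_order) {
      vi <- proj_fwd_cpp(x, spec$dim, spec$origin, spec$voxel_size,
                         maps[[i]]$coefficients, expos[[i]],
                         shape[1], shape[2], pf[i])
      diff <- images[[i]] - vi
      res2 <- res2 + sum(diff^2)
      upd <- proj_back_cpp(diff * ray_w[[i]], spec$dim, spec$origin,
                           spec$voxel_size, maps[[i]]$coefficients,
                           expos[[i]], pf[i], numeric(nv), integer(nv))$vol
      x <- x + (alpha / 2) * col_w[[i]] * upd
    }
    history[it] <- sqrt(res2) / max(v_norm, 1e-300)
    if (it > 1 && history[it] > history[it - 1]) grow <- grow + 1 else grow <- 0
    if (grow >= 5) {
      cond <- structure(
        class = c("mt_wsirt_divergence", "error", "condition"),
        list(message = paste0(
          "wSIRT residual grew for 5 consecutive sweeps (sweep ",
          it, "); try a smaller alpha"),
          call = sys.call(-1), history = history[1:it])
      )
      stop(cond)
    }
  }
  out <- new_volume(array(x, spec$dim), spec, array(cover, spec$dim))
  out$residual_history <- history
  attr(out, "residual_history") <- history
  out
}

#' Coefficient of variation of a tomogram slice
#'
#' The ratio of the standard deviation to the mean of the voxel values in
#' one z slice (the middle slice by default) — the convergence/artifact
#' metric used to monitor reconstruction quality as series accumulate.
#'
#' @param volume An `mt_volume` or 3D array.
#' @param slice_index z index (1-based); defaults to the middle slice.
#' @return Scalar coefficient of variation.
#' @export
coefficient_of_variation <- function(volume, slice_index = NULL) {
  data <- if (inherits(volume, "mt_volume")) volume$data else volume
  if (is.null(slice_index)) slice_index <- ceiling(dim(data)[3] / 2)
  sl <- data[, , slice_index]
  m <- mean(sl)
  if (abs(m) < 1e-12 * max(sd(sl), 1e-300)) {
    stop("slice mean is zero: coefficient of variation undefined",
         call. = FALSE)
  }
  sd(sl) / m
}

#' Voxelize a phantom onto a reconstruction grid
#'
#' Renders beads (and shells) as density indicators on the voxel grid with
#' 2x2x2 subsampling, giving a volume whose reprojection is consistent data
#' for iterative reconstruction experiments.
#'
#' @param phantom A [phantom()].
#' @param spec A [volume_spec()].
#' @return An `mt_volume`.
#' @export
phantom_volume <- function(phantom, spec) {
  d <- spec$dim; vs <- spec$voxel_size
  vol <- array(0, d)
  ax <- spec$origin[1] + (0:(d[1] - 1)) * vs
  ay <- spec$origin[2] + (0:(d[2] - 1)) * vs
  az <- spec$origin[3] + (0:(d[3] - 1)) * vs
  sub <- c(-0.25, 0.25) * vs
  add_sphere <- function(vol, cx, cy, cz, r_in, r_out, dens) {
    ix <- which(abs(ax - cx) <= r_out + vs)
    iy <- which(abs(ay - cy) <= r_out + vs)
    iz <- which(abs(az - cz) <= r_out + vs)
    for (k in iz) for (j in iy) for (i in ix) {
      frac <- 0
      for (ox in sub) for (oy in sub) for (oz in sub) {
        r2 <- (ax[i] + ox - cx)^2 + (ay[j] + oy - cy)^2 + (az[k] + oz - cz)^2
        if (r2 <= r_out^2 && r2 >= r_in^2) frac <- frac + 1
      }
      vol[i, j, k] <- vol[i, j, k] + dens * frac / 8
    }
    vol
  }
  b <- phantom$beads
  for (r in seq_len(nrow(b))) {
    vol <- add_sphere(vol, b$X[r], b$Y[r], b$Z[r], 0, b$radius[r],
                      b$density[r])
  }
  sh <- phantom$shells
  if (!is.null(sh)) {
    for (r in seq_len(nrow(sh))) {
      vol <- add_sphere(vol, sh$X[r], sh$Y[r], sh$Z[r], sh$r_in[r],
                        sh$r_out[r], sh$density[r])
    }
  }
  new_volume(vol, spec)
}

interp_profile_fwhm <- function(profile, spacing = 1, level = 0.5) {
  pk <- which.max(profile)
  # background from the profile median: robust to the oscillating fringe
  # lobes FBP paints around a dense marker
  base <- median(profile)
  half <- base + level * (max(profile) - base)
  left <- NA_real_; right <- NA_real_
  for (i in pk:2) {
    if (profile[i - 1] <= half) {
      left <- i - (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  for (i in pk:(length(profile) - 1)) {
    if (profile[i + 1] <= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  (right - left) * spacing
}

#' Point-spread width of a reconstructed bead
#'
#' Full width of the reconstruction at a fractional amplitude `level` along
#' the x, y and z axes through the bead's voxel position; their ratio
#' `z / x` quantifies the missing-wedge/pyramid elongation of the point
#' response.  The default `level = 0.5` is the classical FWHM.  Note that
#' the half-maximum core width along z is set by the maximum tilt angle
#' alone (the z extent of the covered Fourier region does not change with
#' the number of series), so the progression with series count shows up
#' only at tail-sensitive levels around 0.2: the artifact tails are where
#' the shrinking missing pyramid lives.
#'
#' @param volume An `mt_volume`.
#' @param center Specimen-frame position of the bead (nm), length 3.
#' @param level Fractional amplitude (above the median background) at which
#'   the width is measured.
#' @return Tibble with `fwhm_x`, `fwhm_y`, `fwhm_z`, `ratio_zx` (nm, nm,
#'   nm, dimensionless).
#' @export
bead_psf_fwhm <- function(volume, center = c(0, 0, 0), level = 0.5) {
  spec <- volume$spec
  v <- round((center - spec$origin) / spec$voxel_size) + 1
  d <- spec$dim
  v <- pmin(pmax(v, 1), d)
  fx <- interp_profile_fwhm(volume$data[, v[2], v[3]], spec$voxel_size, level)
  fy <- interp_profile_fwhm(volume$data[v[1], , v[3]], spec$voxel_size, level)
  fz <- interp_profile_fwhm(volume$data[v[1], v[2], ], spec$voxel_size, level)
  tibble::tibble(fwhm_x = fx, fwhm_y = fy, fwhm_z = fz, ratio_zx = fz / fx)
}

#' Bead fringe-artifact energy
#'
#' Mean squared intensity in a spherical-shell annulus around each bead,
#' normalized by the squared mean bead peak value — a measure of the bright
#' and dark fringes the missing wedge paints around dense markers.
#'
#' @param volume An `mt_volume`.
#' @param centers Matrix (or data frame with X, Y, Z) of bead positions, nm.
#' @param r_in,r_out Annulus radii, nm.
#' @return Scalar fringe energy.
#' @export
bead_fringe_energy <- function(volume, centers, r_in = 4, r_out = 8) {
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("X", "Y", "Z")])
  spec <- volume$spec; d <- spec$dim; vs <- spec$voxel_size
  vals <- c(); peaks <- c()
  for (r in seq_len(nrow(centers))) {
    v <- round((centers[r, ] - spec$origin) / vs) + 1
    if (any(v < 1 + ceiling(r_out / vs)) ||
        any(v > d - ceiling(r_out / vs))) next
    rng <- ceiling(r_out / vs)
    ix <- (v[1] - rng):(v[1] + rng)
    iy <- (v[2] - rng):(v[2] + rng)
    iz <- (v[3] - rng):(v[3] + rng)
    block <- volume$data[ix, iy, iz]
    dist <- sqrt(outer(outer((ix - v[1])^2, (iy - v[2])^2, `+`),
                       (iz - v[3])^2, `+`)) * vs
    vals <- c(vals, block[dist >= r_in & dist <= r_out])
    peaks <- c(peaks, volume$data[v[1], v[2], v[3]])
  }
  if (length(vals) == 0) stop("no bead fits inside the volume with the annulus",
                              call. = FALSE)
  mean(vals^2) / mean(peaks)^2
}
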