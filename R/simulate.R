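#' Specimen phantom for multi-tilt simulation
#'
#' A phantom is a collection of electron-dense elements inside a slab of
#' extent `c(Lx, Ly, Lz)` nm centred on the origin: gold beads (spheres),
#' optional spherical shells and optional rectangular slabs.  Densities are
#' non-negative; micrographs store density line integrals (bright = dense),
#' display inversion being a viewer concern.
#'
#' @param beads Data frame with columns `X`, `Y`, `Z` (nm), `radius` (nm),
#'   `density` (a.u.).
#' @param shells Optional data frame with columns `X`, `Y`, `Z`, `r_in`,
#'   `r_out`, `density`.
#' @param slabs Optional data frame with columns `X`, `Y`, `Z`, `lx`, `ly`,
#'   `lz`, `density` (axis-aligned boxes).
#' @param extent Numeric 3-vector `c(Lx, Ly, Lz)` in nm.
#' @return An object of class `phantom`.
#' @export
phantom <- function(beads, shells = NULL, slabs = NULL,
                    extent = c(256, 256, 60)) {
  beads <- tibble::as_tibble(beads)
  stopifnot(all(c("X", "Y", "Z", "radius", "density") %in% names(beads)))
  if (any(beads$radius <= 0)) stop("bead radii must be positive", call. = FALSE)
  if (any(beads$density < 0)) stop("densities must be >= 0", call. = FALSE)
  half <- extent / 2
  inside <- abs(beads$X) <= half[1] & abs(beads$Y) <= half[2] &
    abs(beads$Z) <= half[3]
  if (!all(inside)) stop("all beads must lie inside the extent", call. = FALSE)
  structure(
    list(beads = beads,
         shells = if (!is.null(shells)) tibble::as_tibble(shells),
         slabs = if (!is.null(slabs)) tibble::as_tibble(slabs),
         extent = extent),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", nrow(x$beads), "beads",
      if (!is.null(x$shells)) paste0(", ", nrow(x$shells), " shells"),
      if (!is.null(x$slabs)) paste0(", ", nrow(x$slabs), " slabs"),
      "; extent", paste(x$extent, collapse = " x "), "nm\n")
  invisible(x)
}

#' Random gold-bead phantom
#'
#' Beads are deposited on both faces of the section (as colloidal gold is in
#' practice), laterally uniform over the central `lateral_fill` fraction of
#' the field so that the whole phantom stays inside the detector at the
#' highest tilts.
#'
#' @param n_beads Number of beads.
#' @param extent Slab extent `c(Lx, Ly, Lz)` nm.
#' @param radius Bead radius, nm (5 nm gold at 1 nm/px renders as a
#'   visible few-pixel blob; default 3).
#' @param density Bead density, a.u.
#' @param lateral_fill Fraction of the lateral extent populated.
#' @param min_separation Minimum lateral centre-to-centre distance between
#'   beads on the same face (colloidal particles do not interpenetrate);
#'   enforced by rejection sampling.
#' @param seed RNG seed.
#' @return A [phantom()].
#' @export
random_phantom <- function(n_beads = 50, extent = c(256, 256, 60),
                           radius = 3, density = 1, lateral_fill = 0.8,
                           min_separation = 3 * radius, seed = 1) {
  with_seed(seed, {
    half <- extent / 2 * lateral_fill
    side <- rep_len(c(-1, 1), n_beads)
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < n_beads && tries < 200 * n_beads) {
      tries <- tries + 1
      x <- runif(1, -half[1], half[1]); y <- runif(1, -half[2], half[2])
      if (length(xs) == 0 ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_separation) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n_beads) {
      stop("could not place ", n_beads, " beads with the requested ",
           "minimum separation", call. = FALSE)
    }
    beads <- tibble::tibble(
      X = xs, Y = ys,
      Z = side * (extent[3] / 2 - radius) + runif(n_beads, -1, 1),
      radius = radius,
      density = density
    )
    phantom(beads, extent = extent)
  })
}

#' Dose-dependent specimen compression model
#'
#' Beam exposure compresses the plastic section; the model has one
#' asymptotic fractional compression per axis (`gamma`, dimensionless,
#' `0 <= gamma < 1`) and a saturation constant `tau` in micrograph-index
#' units.  The per-axis scale after `i` micrographs is
#' `s_A(i) = 1 - gamma_A * (1 - exp(-i / tau))`, a transient that levels off
#' to `1 - gamma_A`; with the default `tau` of 1.5 series lengths the
#' stationary state is reached after roughly 3-4 series.
#'
#' @param gamma Length-3 vector of asymptotic compressions (X, Y, Z).
#' @param tau Saturation constant, micrograph-index units.
#' @return An object of class `deformation_model`.
#' @export
deformation_model <- function(gamma = c(0.03, 0.03, 0.15), tau = 181.5) {
  stopifnot(length(gamma) == 3, all(gamma >= 0), all(gamma < 1), tau > 0)
  structure(list(gamma = as.numeric(gamma), tau = tau),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat("<deformation_model> gamma = (",
      paste(x$gamma, collapse = ", "), "), tau =", x$tau, "\n")
  invisible(x)
}

#' Per-micrograph deformation scale factors
#'
#' @param model A [deformation_model()], or `NULL` for no deformation.
#' @param i_omega Vector of micrograph indices (>= 0).
#' @return Matrix with one row per index and columns `sX`, `sY`, `sZ`.
#' @export
deformation_scales <- function(model, i_omega) {
  stopifnot(all(i_omega >= 0))
  if (is.null(model)) {
    s <- matrix(1, length(i_omega), 3)
  } else {
    stopifnot(inherits(model, "deformation_model"))
    f <- 1 - exp(-i_omega / model$tau)
    s <- 1 - outer(f, model$gamma)
  }
  colnames(s) <- c("sX", "sY", "sZ")
  s
}

default_noise <- function(noise = list()) {
  modifyList(list(gaussian_sigma = 0, poisson = FALSE, gain = 10,
                  background = 50), noise)
}

# Compose a diagonal specimen scaling into an affine map: P'(x) = P(S x).
compose_scaling <- function(map, scales) {
  stopifnot(map$order == 1)
  co <- map$coefficients
  co[, 2:4] <- co[, 2:4] %*% diag(as.numeric(scales))
  projection_map(co, pixel_size = map$pixel_size)
}

#' Render one synthetic micrograph
#'
#' Every density element is scaled by `diag(scales)` in the specimen frame,
#' projected through the map, and splatted as its analytic integrated-density
#' footprint (beads and shells: projected-sphere chord-length profiles;
#' slabs: ray-box path lengths).  Noise is applied last: optionally Poisson
#' on expected counts (`gain * density + background`) and additive Gaussian
#' read noise.  Deterministic given `seed`.
#'
#' @param phantom A [phantom()].
#' @param map A [projection_map()] (affine for slab rendering).
#' @param scales Length-3 deformation scale factors.
#' @param shape Image dimensions `c(nx, ny)` px.
#' @param noise List with elements `gaussian_sigma`, `poisson`, `gain`,
#'   `background` (missing entries take defaults).
#' @param seed RNG seed for the noise draws.
#' @return `nx` x `ny` numeric matrix; attribute `clipped_beads` lists beads
#'   whose footprint fell entirely outside the image.
#' @export
render_micrograph <- function(phantom, map, scales = c(1, 1, 1),
                              shape = c(256L, 256L), noise = list(),
                              seed = 1) {
  stopifnot(inherits(phantom, "phantom"), inherits(map, "projection_map"))
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  noise <- default_noise(noise)
  nx <- shape[1]; ny <- shape[2]
  img <- matrix(0, nx, ny)
  clipped <- integer(0)

  b <- phantom$beads
  if (nrow(b) > 0) {
    pos <- cbind(b$X * scales[1], b$Y * scales[2], b$Z * scales[3])
    uv <- project(map, pos)
    r_px <- b$radius / map$pixel_size
    keep <- uv[, 1] > -r_px & uv[, 1] < nx - 1 + r_px &
      uv[, 2] > -r_px & uv[, 2] < ny - 1 + r_px
    clipped <- as.integer(which(!keep))
    if (any(keep)) {
      img <- img + splat_beads_cpp(nx, ny, uv[keep, , drop = FALSE],
                                   r_px[keep], b$density[keep])
    }
  }
  sh <- phantom$shells
  if (!is.null(sh) && nrow(sh) > 0) {
    pos <- cbind(sh$X * scales[1], sh$Y * scales[2], sh$Z * scales[3])
    uv <- project(map, pos)
    img <- img + splat_shells_cpp(nx, ny, uv,
                                  sh$r_in / map$pixel_size,
                                  sh$r_out / map$pixel_size, sh$density)
  }
  sl <- phantom$slabs
  if (!is.null(sl) && nrow(sl) > 0) {
    img <- img + render_slabs(sl, map, scales, nx, ny)
  }

  if (noise$poisson || noise$gaussian_sigma > 0) {
    img <- with_seed(seed, {
      out <- img
      if (noise$poisson) {
        lam <- pmax(noise$gain * out + noise$background, 0)
        out <- (rpois(length(lam), lam) - noise$background) / noise$gain
        out <- matrix(out, nx, ny)
      }
      if (noise$gaussian_sigma > 0) {
        out <- out + matrix(rnorm(nx * ny, 0, noise$gaussian_sigma), nx, ny)
      }
      out
    })
  }
  attr(img, "clipped_beads") <- clipped
  img
}

# Analytic ray-box path lengths for axis-aligned slabs under an affine map.
render_slabs <- function(slabs, map, scales, nx, ny) {
  lp <- linear_part(map)
  M <- lp$M %*% diag(as.numeric(scales))
  t0 <- lp$t
  # beam direction: null space of M in specimen coordinates
  b <- c(
    M[1, 2] * M[2, 3] - M[1, 3] * M[2, 2],
    M[1, 3] * M[2, 1] - M[1, 1] * M[2, 3],
    M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  )
  b <- b / sqrt(sum(b^2))
  Mp <- MASS_ginv(M)
  u <- rep(0:(nx - 1), times = ny)
  v <- rep(0:(ny - 1), each = nx)
  p0 <- cbind(u - t0[1], v - t0[2]) %*% t(Mp)   # least-norm ray anchors
  img <- matrix(0, nx, ny)
  for (s in seq_len(nrow(slabs))) {
    ctr <- c(slabs$X[s], slabs$Y[s], slabs$Z[s]) * scales
    half <- c(slabs$lx[s], slabs$ly[s], slabs$lz[s]) * scales / 2
    tmin <- rep(-Inf, length(u)); tmax <- rep(Inf, length(u))
    ok <- rep(TRUE, length(u))
    for (a in 1:3) {
      if (abs(b[a]) < 1e-12) {
        ok <- ok & abs(p0[, a] - ctr[a]) <= half[a]
      } else {
        t1 <- (ctr[a] - half[a] - p0[, a]) / b[a]
        t2 <- (ctr[a] + half[a] - p0[, a]) / b[a]
        tmin <- pmax(tmin, pmin(t1, t2))
        tmax <- pmin(tmax, pmax(t1, t2))
      }
    }
    len <- pmax(tmax - tmin, 0) * ok
    img <- img + matrix(len * slabs$density[s], nx, ny)
  }
  img
}

# Moore-Penrose pseudoinverse of a full-rank 2x3 matrix.
MASS_ginv <- function(M) t(M) %*% solve(M %*% t(M))

#' Ground-truth geometry for a simulated acquisition
#'
#' Computes, without rendering any image, everything recovery tests need:
#' the per-micrograph ground-truth projection maps (nominal geometry with
#' the dose-dependent scaling composed in), the exact 2D bead tracks, and
#' the per-micrograph deformation scales.
#'
#' @param phantom A [phantom()].
#' @param scheme A [tilt_scheme()].
#' @param model A [deformation_model()] or `NULL`.
#' @return List with `maps` (list by `i_omega`), `tracks` (tibble:
#'   `bead_id`, `i_omega`, `series`, `tilt_deg`, `x_px`, `y_px`,
#'   `in_image`), and `scales` (matrix).
#' @export
simulate_ground_truth <- function(phantom, scheme, model = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(scheme, "tilt_scheme"))
  mic <- scheme$micrographs
  scales <- deformation_scales(model, mic$i_omega)
  nom <- nominal_maps(scheme)
  maps <- purrr::map(mic$i_omega,
                     ~ compose_scaling(nom[[.x]], scales[.x, ]))
  b <- phantom$beads
  pts <- as.matrix(b[, c("X", "Y", "Z")])
  shape <- scheme$detector_shape
  tracks <- purrr::map_dfr(mic$i_omega, function(i) {
    uv <- project(maps[[i]], pts)
    tibble::tibble(
      bead_id = seq_len(nrow(b)),
      i_omega = i,
      series = mic$series[i],
      tilt_deg = mic$tilt_deg[i],
      x_px = uv[, 1], y_px = uv[, 2],
      in_image = uv[, 1] >= 0 & uv[, 1] <= shape[1] - 1 &
        uv[, 2] >= 0 & uv[, 2] <= shape[2] - 1
    )
  })
  list(maps = maps, tracks = tracks, scales = scales)
}

#' Simulate a full n-fold tilt-series acquisition
#'
#' Renders one micrograph stack per series (MAS azimuth order) of the
#' phantom under the nominal geometry, with the dose-dependent specimen
#' compression composed into the ground-truth projection maps and noise
#' applied per micrograph.  Identical seeds give bit-identical stacks.
#'
#' @inheritParams simulate_ground_truth
#' @param noise Noise settings (see [render_micrograph()]).
#' @param seed RNG seed governing all noise draws.
#' @param dir Optional output directory; when given, each series is written
#'   as an MRC stack together with the ground-truth maps, the bead-track CSV
#'   and the scheme metadata.
#' @return An object of class `mt_simulation`: `stacks` (list of
#'   `nx x ny x n_tilt` arrays), `scheme`, `phantom`, `ground_truth`.
#' @export
simulate_tilt_series <- function(phantom, scheme, model = NULL,
                                 noise = list(), seed = 1, dir = NULL) {
  gt <- simulate_ground_truth(phantom, scheme, model)
  mic <- scheme$micrographs
  shape <- scheme$detector_shape
  n_tilt <- length(scheme$tilt_angles)
  stacks <- vector("list", scheme$n_series)
  for (s in seq_len(scheme$n_series)) {
    idx <- mic$i_omega[mic$series == s]
    stack <- array(0, dim = c(shape[1], shape[2], n_tilt))
    for (j in seq_along(idx)) {
      i <- idx[j]
      stack[, , j] <- render_micrograph(
        phantom, gt$maps[[i]], scales = c(1, 1, 1), shape = shape,
        noise = noise, seed = seed * 1000L + i
      )
    }
    stacks[[s]] <- stack
  }
  out <- structure(
    list(stacks = stacks, scheme = scheme, phantom = phantom,
         ground_truth = gt),
    class = "mt_simulation"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(scheme$n_series)) {
      write_mrc(stacks[[s]], file.path(dir, sprintf("series_%02d.mrc", s)),
                voxel_size = scheme$pixel_size, is_stack = TRUE)
    }
    write_projection_maps(gt$maps, file.path(dir, "ground_truth_maps.txt"))
    write_tracks(gt$tracks[gt$tracks$in_image, ],
                 file.path(dir, "ground_truth_tracks.csv"))
    write_tilt_scheme(scheme, file.path(dir, "scheme.txt"))
  }
  out
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat("<mt_simulation>", x$scheme$n_series, "series,",
      length(x$scheme$tilt_angles), "tilts each,",
      nrow(x$phantom$beads), "beads\n")
  invisible(x)
}

#' Write / read bead tracks as CSV
#'
#' Columns: `bead_id`, `i_omega`, `series`, `tilt_deg`, `x_px`, `y_px`.
#'
#' @param tracks Tibble of track observations.
#' @param path File path.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("bead_id", "i_omega", "series", "tilt_deg", "x_px", "y_px")
  write.csv(as.data.frame(tracks)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tibble::as_tibble(read.csv(path))
}
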