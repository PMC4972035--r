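#' Multilevel-access (MAS) azimuth ordering
#'
#' Azimuthal specimen rotations for an n-fold tilt-series acquisition,
#' ordered so that successive tilt axes are maximally spread: the angles
#' `k * 180 / n` are visited in bit-reversed order of `k`.  For `n = 8`
#' the first and last series sit at 0 and 157.5 degrees.  For `n` not a
#' power of two the bit-reversal permutation of the next power of two is
#' used and out-of-range indices are discarded.
#'
#' @param n_series Number of tilt series (positive integer).
#' @return Numeric vector of azimuth angles in degrees, length `n_series`.
#' @examples
#' mas_azimuths(8)
#' @export
mas_azimuths <- function(n_series) {
  if (length(n_series) != 1 || is.na(n_series) || n_series < 1 ||
      n_series != round(n_series)) {
    stop("`n_series` must be a positive integer", call. = FALSE)
  }
  n_series <- as.integer(n_series)
  if (n_series == 1) return(0)
  bits <- ceiling(log2(n_series))
  n2 <- 2L^bits
  k <- 0:(n2 - 1L)
  rev_k <- vapply(k, function(x) {
    r <- 0L
    for (b in seq_len(bits)) {
      r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(x, 1L))
      x <- bitwShiftR(x, 1L)
    }
    r
  }, integer(1))
  rev_k <- rev_k[rev_k < n_series]
  rev_k * 180 / n_series
}

# Graded-lexicographic exponent table for 3-variable monomials up to `order`,
# X > Y > Z within each grade.  Row k gives the (X, Y, Z) exponents of the
# k-th monomial; this ordering is the serialization contract for map files.
monomial_exponents <- function(order) {
  stopifnot(order >= 0)
  out <- list()
  for (g in 0:order) {
    for (ex in g:0) {
      for (ey in (g - ex):0) {
        out[[length(out) + 1L]] <- c(ex, ey, g - ex - ey)
      }
    }
  }
  mat <- do.call(rbind, out)
  storage.mode(mat) <- "integer"
  colnames(mat) <- c("X", "Y", "Z")
  mat
}

n_monomials <- function(order) choose(order + 3, 3)

#' Polynomial projection map
#'
#' A projection map takes a 3D specimen coordinate to a 2D detector pixel
#' coordinate; one map per micrograph is the unknown of the alignment
#' problem.  Coefficients are stored as a 2 x m matrix (one row per detector
#' axis) over the 3-variable monomials of degree <= `order` in
#' graded-lexicographic order, so `m = choose(order + 3, 3)` and the affine
#' case `order = 1` has columns (1, X, Y, Z).
#'
#' @param coefficients 2 x m numeric matrix of polynomial coefficients.
#' @param pixel_size Detector pixel size in nm (kept as metadata; used to
#'   de-dimensionalize the map for [n3()]).
#' @return An object of class `projection_map`.
#' @seealso [nominal_map()], [project()], [n3()]
#' @export
projection_map <- function(coefficients, pixel_size = 1) {
  coefficients <- as.matrix(coefficients)
  dimnames(coefficients) <- NULL
  if (nrow(coefficients) != 2) {
    stop("`coefficients` must have two rows (detector x and y)", call. = FALSE)
  }
  m <- ncol(coefficients)
  order <- NA_integer_
  for (d in 1:8) if (n_monomials(d) == m) order <- d
  if (is.na(order)) {
    stop("coefficient count ", m, " does not match any polynomial order",
         call. = FALSE)
  }
  structure(
    list(order = order, coefficients = coefficients, pixel_size = pixel_size),
    class = "projection_map"
  )
}

#' @export
print.projection_map <- function(x, ...) {
  lp <- linear_part(x)
  cat("<projection_map> order", x$order,
      " pixel_size", x$pixel_size, "nm\n")
  cat("  offset t: [", paste(signif(lp$t, 6), collapse = ", "), "]\n")
  cat("  linear M:\n")
  print(signif(lp$M, 6))
  invisible(x)
}

#' Linear part of a projection map
#'
#' @param map A [projection_map()].
#' @return List with `M` (2 x 3 matrix over X, Y, Z) and `t` (2-vector
#'   offset, the image of the specimen origin).
#' @export
linear_part <- function(map) {
  stopifnot(inherits(map, "projection_map"))
  list(M = map$coefficients[, 2:4, drop = FALSE], t = map$coefficients[, 1])
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Ideal single-axis projection map
#'
#' The nominal (error-free) acquisition geometry: the specimen is first
#' rotated by `azimuth` about its normal Z, then tilted by `tilt` about the
#' (fixed, lab-frame) goniometer y axis, and projected along the beam onto
#' the detector.  The resulting map is affine, with the specimen origin at
#' `detector_center` and an `n3` of exactly 1.
#'
#' @param azimuth Azimuthal specimen rotation in degrees.
#' @param tilt Goniometer tilt in degrees.
#' @param pixel_size Detector pixel size in nm per px (> 0).
#' @param detector_center 2-vector, detector pixel coordinates of the
#'   specimen origin (0-based, (x, y) = (column, row)).
#' @return A [projection_map()] of order 1.
#' @export
nominal_map <- function(azimuth, tilt, pixel_size = 1,
                        detector_center = c(127.5, 127.5)) {
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  R <- rot_y(tilt) %*% rot_z(azimuth)
  M <- R[1:2, , drop = FALSE] / pixel_size
  projection_map(cbind(detector_center, M), pixel_size = pixel_size)
}

#' Project 3D specimen points through a projection map
#'
#' @param map A [projection_map()].
#' @param points Matrix or data frame of 3D specimen coordinates (columns
#'   X, Y, Z, in nm).
#' @return A matrix (or tibble, if `points` is a data frame) of detector
#'   coordinates with columns `x`, `y` in pixels.
#' @export
project <- function(map, points) {
  stopifnot(inherits(map, "projection_map"))
  tabular <- is.data.frame(points)
  pts <- if (tabular) as.matrix(points[, c("X", "Y", "Z")]) else {
    p <- as.matrix(points)
    if (ncol(p) != 3) stop("`points` must have 3 columns", call. = FALSE)
    p
  }
  if (any(!is.finite(pts))) stop("`points` must be finite", call. = FALSE)
  expo <- monomial_exponents(map$order)
  # monomial design matrix, n x m
  A <- vapply(seq_len(nrow(expo)), function(k) {
    pts[, 1]^expo[k, 1] * pts[, 2]^expo[k, 2] * pts[, 3]^expo[k, 3]
  }, numeric(nrow(pts)))
  A <- matrix(A, nrow = nrow(pts))
  uv <- A %*% t(map$coefficients)
  colnames(uv) <- c("x", "y")
  if (tabular) tibble::as_tibble(uv) else uv
}

#' Deformation indicator n3 of a projection map
#'
#' The Euclidean norm of the cross product of the two rows of the map's
#' linear part, after normalizing out the pixel scale.  For an ideal
#' rotation-projection the rows are orthonormal and `n3` is exactly 1;
#' deviations indicate specimen warping.  Under a diagonal specimen scaling
#' `diag(sX, sY, sZ)` composed into the map, `n3` equals `sX * sY` at zero
#' tilt and is dominated by `sZ` at high tilt, which is what makes its
#' oscillation along a multi-tilt acquisition a deformation monitor.
#'
#' @param map A [projection_map()].
#' @return Scalar `n3` value.
#' @export
n3 <- function(map) {
  stopifnot(inherits(map, "projection_map"))
  M <- linear_part(map)$M * map$pixel_size
  cr <- c(
    M[1, 2] * M[2, 3] - M[1, 3] * M[2, 2],
    M[1, 3] * M[2, 1] - M[1, 1] * M[2, 3],
    M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  )
  val <- sqrt(sum(cr^2))
  n1 <- sqrt(sum(M[1, ]^2)); n2 <- sqrt(sum(M[2, ]^2))
  if (val < 1e-12 * n1 * n2 || n1 == 0 || n2 == 0) {
    stop("degenerate geometry: rows of the linear part are collinear",
         call. = FALSE)
  }
  val
}

#' Multi-tilt acquisition scheme
#'
#' Builds the acquisition bookkeeping for an n-fold tilt-series scheme:
#' azimuths in MAS order, a common tilt grid per series (default -60 to +60
#' degrees in 1 degree steps), and the global micrograph index `i_omega`
#' enumerating micrographs series-major in acquisition order.
#'
#' @param n_series Number of tilt series.
#' @param tilt_min,tilt_max,tilt_step Tilt grid in degrees.
#' @param pixel_size Detector pixel size, nm.
#' @param detector_shape Image dimensions in pixels, `c(nx, ny)`.
#' @return A `tilt_scheme` object; its `$micrographs` element is a tibble
#'   with columns `i_omega`, `series`, `azimuth_deg`, `tilt_deg`.
#' @export
tilt_scheme <- function(n_series, tilt_min = -60, tilt_max = 60,
                        tilt_step = 1, pixel_size = 1,
                        detector_shape = c(256L, 256L)) {
  az <- mas_azimuths(n_series)
  tilts <- seq(tilt_min, tilt_max, by = tilt_step)
  mic <- tibble::tibble(
    series = rep(seq_len(n_series), each = length(tilts)),
    azimuth_deg = rep(az, each = length(tilts)),
    tilt_deg = rep(tilts, times = n_series)
  )
  mic$i_omega <- seq_len(nrow(mic))
  structure(
    list(
      n_series = as.integer(n_series),
      azimuths = az,
      tilt_angles = tilts,
      pixel_size = pixel_size,
      detector_shape = as.integer(detector_shape),
      micrographs = mic[, c("i_omega", "series", "azimuth_deg", "tilt_deg")]
    ),
    class = "tilt_scheme"
  )
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat("<tilt_scheme>", x$n_series, "series x", length(x$tilt_angles),
      "tilts =", nrow(x$micrographs), "micrographs\n")
  cat("  azimuths (MAS order):", paste(round(x$azimuths, 2), collapse = ", "),
      "deg\n")
  cat("  tilt:", min(x$tilt_angles), "to", max(x$tilt_angles), "deg,",
      "pixel", x$pixel_size, "nm, detector",
      paste(x$detector_shape, collapse = "x"), "px\n")
  invisible(x)
}

#' Nominal projection maps for a whole scheme
#'
#' @param scheme A [tilt_scheme()].
#' @param detector_center Detector coordinates of the specimen origin;
#'   defaults to the detector centre.
#' @return List of [projection_map()]s indexed by `i_omega`.
#' @export
nominal_maps <- function(scheme, detector_center = NULL) {
  stopifnot(inherits(scheme, "tilt_scheme"))
  if (is.null(detector_center)) {
    detector_center <- (scheme$detector_shape - 1) / 2
  }
  purrr::map2(
    scheme$micrographs$azimuth_deg, scheme$micrographs$tilt_deg,
    ~ nominal_map(.x, .y, pixel_size = scheme$pixel_size,
                  detector_center = detector_center)
  )
}

#' Write / read projection maps as plain text
#'
#' One block per micrograph: the index `i_omega`, the polynomial degree, and
#' one coefficient row per detector axis in graded-lexicographic monomial
#' order (the ordering is recorded in the file header).
#'
#' @param maps List of [projection_map()]s indexed by `i_omega`.
#' @param path File path.
#' @return `write_projection_maps` returns `path` invisibly;
#'   `read_projection_maps` returns the list of maps.
#' @export
write_projection_maps <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# multitilt projection maps",
    "# monomial order: graded lexicographic in (X, Y, Z)",
    paste("n_maps", length(maps)),
    paste("pixel_size_nm", format(maps[[1]]$pixel_size, digits = 17))
  ), con)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    writeLines(paste("map", i, "order", m$order), con)
    for (r in 1:2) {
      writeLines(paste(format(m$coefficients[r, ], digits = 17),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_projection_maps
#' @export
read_projection_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  n <- as.integer(strsplit(lines[1], "\\s+")[[1]][2])
  px <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2])
  maps <- vector("list", n)
  at <- 3
  for (i in seq_len(n)) {
    hdr <- strsplit(lines[at], "\\s+")[[1]]
    stopifnot(hdr[1] == "map")
    r1 <- as.numeric(strsplit(trimws(lines[at + 1]), "\\s+")[[1]])
    r2 <- as.numeric(strsplit(trimws(lines[at + 2]), "\\s+")[[1]])
    maps[[as.integer(hdr[2])]] <- projection_map(rbind(r1, r2), pixel_size = px)
    at <- at + 3
  }
  maps
}

#' Write / read tilt-scheme metadata as flat key-value text
#'
#' @param scheme A [tilt_scheme()].
#' @param path File path.
#' @export
write_tilt_scheme <- function(scheme, path) {
  writeLines(c(
    paste("n_series", scheme$n_series),
    paste("azimuths_deg", paste(format(scheme$azimuths, digits = 17),
                                collapse = ",")),
    paste("tilt_min_deg", min(scheme$tilt_angles)),
    paste("tilt_max_deg", max(scheme$tilt_angles)),
    paste("tilt_step_deg", if (length(scheme$tilt_angles) > 1)
      diff(scheme$tilt_angles)[1] else 1),
    paste("pixel_size_nm", format(scheme$pixel_size, digits = 17)),
    paste("detector_shape_px", paste(scheme$detector_shape, collapse = ",")),
    "acquisition_order series_major_mas"
  ), path)
  invisible(path)
}

#' @rdname write_tilt_scheme
#' @export
read_tilt_scheme <- function(path) {
  kv <- strsplit(readLines(path), " ", fixed = TRUE)
  vals <- setNames(
    vapply(kv, function(x) paste(x[-1], collapse = " "), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  shape <- as.integer(strsplit(vals[["detector_shape_px"]], ",")[[1]])
  tilt_scheme(
    n_series = as.integer(vals[["n_series"]]),
    tilt_min = as.numeric(vals[["tilt_min_deg"]]),
    tilt_max = as.numeric(vals[["tilt_max_deg"]]),
    tilt_step = as.numeric(vals[["tilt_step_deg"]]),
    pixel_size = as.numeric(vals[["pixel_size_nm"]]),
    detector_shape = shape
  )
}
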