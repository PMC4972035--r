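#' Missing Fourier-space fraction of an n-fold tilt scheme
#'
#' Closed-form fraction `q` of Fourier-space information left unsampled by an
#' n-fold tilt-series acquisition with maximum tilt `theta_max` on a slab of
#' thickness-to-width ratio `aspect = L_z / L`:
#'
#'   q(n) = (n/6) * tan(pi / (2 n)) * (aspect / tan(theta_max))^2
#'
#' valid for `n` a power of two, `aspect < 1` and `theta_max > 45` degrees.
#' The n = 2 case is the classical double-tilt missing pyramid and the
#' `n = Inf` limit, `(pi/12) * (aspect / tan(theta_max))^2`, is the conical
#' missing cone.
#'
#' @param n Number of tilt series; `Inf` gives the conical limit.
#' @param aspect Thickness-to-width ratio `L_z / L` of the sample (> 0).
#' @param theta_max Maximum tilt angle, degrees (must exceed 45).
#' @return Missing fraction in `[0, 1]`.
#' @examples
#' missing_fraction(2)            # 0.1111 (double tilt)
#' missing_fraction(Inf)          # 0.0873 (conical limit)
#' @export
missing_fraction <- function(n, aspect = 1, theta_max = 60) {
  stopifnot(n >= 1, aspect > 0)
  if (theta_max <= 45 || theta_max >= 90) {
    stop("`theta_max` must lie in (45, 90) degrees for the closed form",
         call. = FALSE)
  }
  x2 <- (aspect / tan(theta_max * pi / 180))^2
  if (is.infinite(n)) return(pi / 12 * x2)
  if (n > 1 && abs(log2(n) - round(log2(n))) > 1e-9) {
    warning("closed form is only valid when `n` is a power of 2",
            call. = FALSE)
  }
  n / 6 * tan(pi / (2 * n)) * x2
}

#' Minimum tilt increment from the 2D sampling rule
#'
#' The angular increment needed to sample a width-`L` detector at full pixel
#' resolution: `delta_theta = (2 / L) * 180 / pi` degrees.  For a 4k detector
#' this is about 0.03 degrees, far below practical increments.
#'
#' @param L Detector width in pixels (>= 2).
#' @return Increment in degrees.
#' @export
required_increment <- function(L) {
  stopifnot(L >= 2)
  (2 / L) * 180 / pi
}

#' Monte-Carlo estimate of the missing Fourier-space fraction
#'
#' Independent geometric oracle for [missing_fraction()]: points are drawn
#' uniformly in the Fourier box `[-1, 1]^2 x [-aspect, aspect]` and tested
#' for membership in every one of the `n` double wedges
#' `|k_z| > tan(theta_max) * |k_xy . w_j|` (in-plane normals `w_j` spaced
#' `pi / n`); the uncovered fraction is returned with its binomial standard
#' error.
#'
#' @inheritParams missing_fraction
#' @param samples Number of Monte-Carlo points (>= 1000).
#' @param seed RNG seed.
#' @return Tibble with columns `fraction`, `stderr`, `samples`.
#' @export
monte_carlo_missing_fraction <- function(n, aspect = 1, theta_max = 60,
                                         samples = 1e6, seed = 1) {
  stopifnot(n >= 1, samples >= 1e3, theta_max > 0, theta_max <= 90)
  frac <- with_seed(seed, {
    kx <- runif(samples, -1, 1)
    ky <- runif(samples, -1, 1)
    kz <- runif(samples, -aspect, aspect)
    phi <- (seq_len(n) - 1) * pi / n
    mc_missing_count_cpp(kx, ky, kz, phi, tan(theta_max * pi / 180)) / samples
  })
  tibble::tibble(
    fraction = frac,
    stderr = sqrt(frac * (1 - frac) / samples),
    samples = samples
  )
}

#' Voxelized Fourier-coverage mask
#'
#' Classifies each voxel of a Fourier-space grid over
#' `[-1, 1]^2 x [-aspect, aspect]` as covered (TRUE) or missing (FALSE) by
#' the union of the n tilt wedges.
#'
#' @inheritParams missing_fraction
#' @param grid_n Grid points per axis.
#' @return Logical 3D array, `TRUE` where Fourier space is covered.
#' @export
coverage_map <- function(n, aspect = 1, theta_max = 60, grid_n = 64) {
  stopifnot(n >= 1, grid_n >= 2)
  kx <- seq(-1, 1, length.out = grid_n)
  kz <- seq(-aspect, aspect, length.out = grid_n)
  phi <- (seq_len(n) - 1) * pi / n
  t <- tan(theta_max * pi / 180)
  g <- array(0, dim = c(grid_n, grid_n))
  for (j in seq_len(n)) {
    proj <- abs(outer(kx * cos(phi[j]), kx * sin(phi[j]), `+`))
    g <- pmax(g, proj)
  }
  mask <- array(FALSE, dim = c(grid_n, grid_n, grid_n))
  for (k in seq_len(grid_n)) mask[, , k] <- abs(kz[k]) <= t * g
  mask
}

#' Missing-fraction table over series counts
#'
#' @inheritParams missing_fraction
#' @param n_values Series counts to tabulate (may include `Inf`).
#' @return Tibble with columns `n`, `missing_fraction`, `missing_percent`.
#' @export
missing_fraction_table <- function(n_values = c(1, 2, 4, 8, 16, Inf),
                                   aspect = 1, theta_max = 60) {
  q <- vapply(n_values, function(n) {
    if (n == 1) NA_real_ else missing_fraction(n, aspect, theta_max)
  }, numeric(1))
  tibble::tibble(n = n_values, missing_fraction = q,
                 missing_percent = 100 * q)
}
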