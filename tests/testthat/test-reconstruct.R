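vol_of <- function(dim = c(48, 48, 20), vs = 1) volume_spec(dim, vs)

centre_map <- function(az, tilt, det = 48) {
  nominal_map(az, tilt, detector_center = c((det - 1) / 2, (det - 1) / 2))
}

test_that("ramp filters kill DC and match the discrete kernel forms", {
  img <- matrix(3, 32, 32)
  out <- filter_micrograph(img, filter = "ram-lak", axis = "x")
  # DC suppressed to the truncated-kernel tail (~1 % of the input level)
  expect_lt(max(abs(out[8:24, ])), 0.01 * 3)
  # delta line source reproduces the discrete Shepp-Logan sequence
  delta <- matrix(0, 33, 8); delta[17, ] <- 1
  sl <- filter_micrograph(delta, filter = "shepp-logan", axis = "x")
  k <- -10:10
  expect_equal(sl[17 + k, 1], 2 / (pi^2 * (1 - 4 * k^2)), tolerance = 1e-10)
  # "none" is the identity
  expect_identical(filter_micrograph(img, filter = "none"), img)
})

test_that("filtering direction follows the goniometer-fixed tilt axis", {
  # with the specimen rotated in the holder the tilt axis stays along
  # detector y, so filtering runs along detector x at any azimuth
  expect_equal(multitilt:::filter_direction(centre_map(0, 30)), "x")
  expect_equal(multitilt:::filter_direction(centre_map(90, 30)), "x")
  expect_equal(multitilt:::filter_direction(centre_map(0, 0)), "x")
})

test_that("reproject and backproject are exact adjoints", {
  spec <- vol_of(c(24, 20, 10))
  set.seed(1)
  x <- array(rnorm(prod(spec$dim)), spec$dim)
  y <- matrix(rnorm(30 * 28), 30, 28)
  for (geom in list(c(0, 0), c(0, 55), c(45, -30))) {
    mp <- nominal_map(geom[1], geom[2], detector_center = c(14.5, 13.5))
    Ax <- reproject(x, mp, c(30, 28), spec = spec)
    Aty <- backproject(list(y), list(mp), spec)
    lhs <- sum(Ax * y); rhs <- sum(x * Aty$data)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
  }
})

test_that("single-view backprojection smears along the beam", {
  spec <- vol_of(c(32, 32, 16))
  img <- matrix(runif(32 * 32), 32, 32)
  v <- backproject(list(img), list(centre_map(0, 0, 32)), spec)
  # untilted: constant along z
  expect_lt(max(apply(v$data, c(1, 2), sd)), 1e-10)
})

test_that("uniform volume reprojects to the slab path length", {
  spec <- vol_of(c(48, 48, 20))
  ones <- array(1, spec$dim)
  img <- reproject(ones, centre_map(0, 0), c(48, 48), spec = spec)
  expect_equal(img[24, 24], 20, tolerance = 1e-10)
  # tilted: path length through the slab grows as 1 / cos(theta)
  img60 <- reproject(ones, centre_map(0, 60), c(48, 48), spec = spec)
  expect_equal(img60[24, 24], 20 / cos(pi / 3), tolerance = 0.05)
})

test_that("reprojection matches the analytic forward model", {
  ph <- phantom(data.frame(X = c(-10, 8), Y = c(6, -12), Z = c(3, -3),
                           radius = 8, density = 1), extent = c(64, 64, 24))
  spec <- volume_spec(c(64, 64, 24))
  xt <- phantom_volume(ph, spec)
  for (tilt in c(0, 30, 60)) {
    m <- nominal_map(0, tilt, detector_center = c(31.5, 31.5))
    ana <- render_micrograph(ph, m, shape = c(64L, 64L))
    rp <- reproject(xt, m, c(64, 64))
    expect_lt(sqrt(sum((ana - rp)^2) / sum(ana^2)), 0.02)
  }
})

test_that("FBP localizes a bead and is linear and empty-safe", {
  spec <- vol_of(c(64, 64, 24))
  ph <- phantom(data.frame(X = 5.5, Y = -3.5, Z = 2.5, radius = 2.5,
                           density = 1), extent = c(64, 64, 24))
  sch <- tilt_scheme(1, tilt_step = 2, detector_shape = c(64L, 64L))
  maps <- nominal_maps(sch)
  imgs <- lapply(maps, function(m) render_micrograph(ph, m,
                                                     shape = c(64L, 64L)))
  v <- fbp(imgs, maps, spec)
  am <- which(v$data == max(v$data), arr.ind = TRUE)
  truth <- (c(5.5, -3.5, 2.5) - spec$origin) / spec$voxel_size + 1
  expect_true(all(abs(am[1, ] - truth) <= 1))
  # linearity: doubling the stack doubles the volume
  v2 <- fbp(lapply(imgs, `*`, 2), maps, spec)
  expect_equal(v2$data, 2 * v$data, tolerance = 1e-10)
  # empty input: zero volume
  v0 <- fbp(list(), list(), spec)
  expect_equal(max(abs(v0$data)), 0)
})

test_that("FBP reprojections correlate with the input micrographs", {
  spec <- vol_of(c(64, 64, 24))
  sch <- tilt_scheme(2, tilt_step = 5, detector_shape = c(64L, 64L))
  ph <- random_phantom(10, extent = c(64, 64, 24), radius = 2.5, seed = 4)
  maps <- nominal_maps(sch)
  imgs <- lapply(maps, function(m) render_micrograph(ph, m,
                                                     shape = c(64L, 64L)))
  v <- fbp(imgs, maps, spec)
  cors <- vapply(seq_along(imgs), function(i) {
    cor(as.numeric(imgs[[i]]), as.numeric(reproject(v, maps[[i]],
                                                    c(64, 64))))
  }, numeric(1))
  expect_gt(min(cors), 0.9)
})

test_that("one wSIRT sweep is linear in the data and alpha 0 is inert", {
  spec <- vol_of(c(32, 32, 12))
  sch <- tilt_scheme(1, tilt_step = 20, detector_shape = c(32L, 32L))
  maps <- nominal_maps(sch)
  ph <- random_phantom(4, extent = c(32, 32, 12), radius = 2, seed = 2)
  xt <- phantom_volume(ph, spec)
  imgs <- lapply(maps, function(m) reproject(xt, m, c(32, 32)))
  v1 <- wsirt(imgs, maps, spec, iterations = 1)
  v2 <- wsirt(lapply(imgs, `*`, 2), maps, spec, iterations = 1)
  expect_equal(v2$data, 2 * v1$data, tolerance = 1e-10)
  v0 <- wsirt(imgs, maps, spec, iterations = 3, alpha = 0)
  expect_equal(max(abs(v0$data)), 0)
  expect_equal(v0$residual_history, rep(1, 3))
})

test_that("wSIRT converges monotonically on consistent data", {
  spec <- vol_of(c(48, 48, 20))
  sch <- tilt_scheme(2, tilt_step = 6, detector_shape = c(48L, 48L))
  ph <- random_phantom(8, extent = c(48, 48, 20), radius = 2.5, seed = 4)
  xt <- phantom_volume(ph, spec)
  maps <- nominal_maps(sch)
  imgs <- lapply(sch$micrographs$i_omega,
                 function(i) reproject(xt, maps[[i]], c(48, 48)))
  v <- wsirt(imgs, maps, spec, iterations = 20)
  h <- v$residual_history
  expect_true(all(diff(h[3:20]) <= 0))
  expect_lt(h[20], 0.05)
  # volume error shrinks with more sweeps on the well-covered region
  v5 <- wsirt(imgs, maps, spec, iterations = 5)
  mask <- v$coverage >= max(v$coverage) - 1
  e5 <- sqrt(sum((v5$data[mask] - xt$data[mask])^2))
  e20 <- sqrt(sum((v$data[mask] - xt$data[mask])^2))
  expect_lt(e20, e5)
  # a small relaxation decays strictly in the early sweeps
  vs <- wsirt(imgs, maps, spec, iterations = 8, alpha = 0.5)
  expect_true(all(diff(vs$residual_history) < 0))
})

test_that("reconstructions at rotated azimuths are rotations of each other", {
  spec <- vol_of(c(64, 64, 24))
  ph <- phantom(data.frame(X = c(-10, 8), Y = c(6, -12), Z = c(3, -3),
                           radius = 3, density = 1), extent = c(64, 64, 24))
  rot_ph <- phantom(data.frame(X = -ph$beads$Y, Y = ph$beads$X,
                               Z = ph$beads$Z, radius = 3, density = 1),
                    extent = c(64, 64, 24))
  tilts <- seq(-60, 60, 5)
  mapsA <- lapply(tilts, function(t) centre_map(0, t, 64))
  mapsB <- lapply(tilts, function(t) centre_map(90, t, 64))
  # same physical views: specimen at azimuth 90 vs pre-rotated specimen
  imgsB <- lapply(mapsB, function(m) render_micrograph(ph, m,
                                                       shape = c(64L, 64L)))
  imgsA <- lapply(mapsA, function(m) render_micrograph(rot_ph, m,
                                                       shape = c(64L, 64L)))
  vB <- fbp(imgsB, mapsB, spec)
  vA <- fbp(imgsA, mapsA, spec)
  rot <- array(0, dim(vB$data))
  for (k in seq_len(dim(vB$data)[3])) {
    rot[, , k] <- t(vB$data[, , k])[64:1, ]   # in-plane +90 degrees
  }
  expect_lt(sqrt(sum((rot - vA$data)^2) / sum(vA$data^2)), 0.05)
})

test_that("coefficient of variation behaves as std over mean", {
  v <- new_vol <- structure(
    list(data = array(2, c(8, 8, 4)),
         spec = volume_spec(c(8, 8, 4))), class = "mt_volume")
  expect_equal(coefficient_of_variation(v), 0)
  set.seed(3)
  noise <- array(rnorm(40 * 40 * 3, mean = 10, sd = 2), c(40, 40, 3))
  expect_equal(coefficient_of_variation(noise, 2), 2 / 10, tolerance = 0.05)
  zero <- array(0, c(8, 8, 4))
  expect_error(coefficient_of_variation(zero), "undefined")
})

test_that("volumes round-trip through MRC", {
  spec <- volume_spec(c(12, 10, 6), voxel_size = 1.5)
  ph <- phantom(data.frame(X = 0, Y = 0, Z = 0, radius = 3, density = 1),
                extent = c(12, 10, 6))
  v <- phantom_volume(ph, spec)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_volume(v, f)
  back <- read_mrc(f)
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$voxel_size, 1.5, tolerance = 1e-6)
  expect_false(back$is_stack)
})
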