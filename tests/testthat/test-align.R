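make_gt_tracks <- function(scheme, phantom, model = NULL, sigma = 0,
                           seed = 7) {
  gt <- simulate_ground_truth(phantom, scheme, model)
  tr <- gt$tracks[gt$tracks$in_image, ]
  if (sigma > 0) {
    tr <- withr::with_seed(seed, {
      tr$x_px <- tr$x_px + rnorm(nrow(tr), 0, sigma)
      tr$y_px <- tr$y_px + rnorm(nrow(tr), 0, sigma)
      tr
    })
  }
  tr
}

test_that("noiseless affine tracks are recovered to machine precision", {
  sch <- small_scheme(2, tilt_step = 5)
  ph <- small_phantom(20)
  tr <- make_gt_tracks(sch, ph)
  ba <- bundle_adjust(tr, sch)
  expect_lt(ba$rms_residual, 1e-8)
  expect_true(ba$converged)
  # ground truth here is the nominal geometry, so with the pinned gauge the
  # maps come back identically
  nom <- nominal_maps(sch)
  err <- max(vapply(seq_along(nom), function(i) {
    max(abs(ba$maps[[i]]$coefficients - nom[[i]]$coefficients))
  }, numeric(1)))
  expect_lt(err, 1e-8)
  # and the bead positions match the phantom
  expect_equal(as.matrix(ba$positions3d[, c("X", "Y", "Z")]),
               unname(as.matrix(ph$beads[, c("X", "Y", "Z")])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noisy residual matches the chi-square noise floor", {
  sch <- small_scheme(2, tilt_step = 5)
  ph <- small_phantom(20)
  tr <- make_gt_tracks(sch, ph, sigma = 0.5)
  ba <- bundle_adjust(tr, sch)
  n_obs <- nrow(tr)
  n_mic <- length(unique(tr$i_omega))
  expected <- 0.5 * sqrt(1 - (8 * (n_mic - 1) + 3 * 20) / (2 * n_obs))
  expect_lt(abs(ba$rms_residual - expected) / expected, 0.1)
})

test_that("bundle-adjustment cost is non-increasing across rounds", {
  sch <- small_scheme(2, tilt_step = 10)
  tr <- make_gt_tracks(sch, small_phantom(12, seed = 5),
                       model = deformation_model(), sigma = 0.5)
  ba <- bundle_adjust(tr, sch, max_rounds = 40)
  expect_true(all(diff(ba$cost_history) <= 1e-9 * ba$cost_history[1]))
})

test_that("deformation is absorbed by per-micrograph affine maps", {
  sch <- small_scheme(2, tilt_step = 5)
  model <- deformation_model(c(0.03, 0.03, 0.15), tau = 40)
  tr <- make_gt_tracks(sch, small_phantom(20), model = model, sigma = 0.5)
  ba <- bundle_adjust(tr, sch, max_rounds = 100)
  # rms at the noise floor, not inflated by the deformation
  n_obs <- nrow(tr)
  n_mic <- length(unique(tr$i_omega))
  floor <- 0.5 * sqrt(1 - (8 * (n_mic - 1) + 3 * 20) / (2 * n_obs))
  expect_lt(ba$rms_residual, 1.15 * floor)
  # no tilt-systematic trend in the residuals
  res <- dplyr::left_join(ba$residuals, sch$micrographs,
                          by = c("i_omega", "series"))
  expect_lt(abs(cor(res$residual_px^2, abs(res$tilt_deg))), 0.1)
})

test_that("cost is invariant under a global similarity re-gauging", {
  sch <- small_scheme(2, tilt_step = 15)
  ph <- small_phantom(10, seed = 9)
  tr <- make_gt_tracks(sch, ph, sigma = 0.5)
  maps <- nominal_maps(sch)
  X <- as.matrix(ph$beads[, c("X", "Y", "Z")])
  cost <- function(maps, X) {
    tot <- 0
    for (r in seq_len(nrow(tr))) {
      uv <- project(maps[[tr$i_omega[r]]], X[tr$bead_id[r], , drop = FALSE])
      tot <- tot + sum((uv - c(tr$x_px[r], tr$y_px[r]))^2)
    }
    tot
  }
  # similarity transform: rotation about z, scale, translation
  s <- 1.3
  R <- multitilt:::rot_z(25) * s
  b <- c(4, -7, 2)
  maps_g <- lapply(maps, function(m) {
    co <- m$coefficients
    M <- co[, 2:4]
    co[, 2:4] <- M %*% R
    co[, 1] <- co[, 1] + M %*% b
    projection_map(co, m$pixel_size)
  })
  X_g <- t(solve(R, t(X) - b))
  expect_equal(cost(maps, X), cost(maps_g, X_g), tolerance = 1e-8)
})

test_that("underdetermined maps raise a named error", {
  sch <- small_scheme(2, tilt_step = 5)
  tr <- make_gt_tracks(sch, small_phantom(5, seed = 12))
  expect_error(bundle_adjust(tr, sch, order = 2), "underdetermined")
  # too few multi-series tracks
  tr1 <- tr[tr$bead_id <= 2, ]
  expect_error(bundle_adjust(tr1, sch), "4 tracks")
})

test_that("order promotion embeds lower-order solutions", {
  m <- nominal_map(10, 20)
  m2 <- multitilt:::promote_order(m, 2)
  pts <- matrix(rnorm(15), 5, 3)
  expect_equal(project(m, pts), project(m2, pts), tolerance = 1e-12)
})

test_that("quadratic maps are recovered from exact quadratic tracks", {
  sch <- small_scheme(2, tilt_step = 10, det = 128L)
  ph <- small_phantom(20, seed = 13)
  nom <- nominal_maps(sch)
  # ground truth: nominal maps plus a small X^2 distortion term
  gt_maps <- lapply(nom, function(m) {
    m2 <- multitilt:::promote_order(m, 2)
    m2$coefficients[1, 5] <- 2e-4
    m2
  })
  pts <- as.matrix(ph$beads[, c("X", "Y", "Z")])
  tr <- purrr::map_dfr(seq_along(gt_maps), function(i) {
    uv <- project(gt_maps[[i]], pts)
    tibble::tibble(bead_id = seq_len(nrow(pts)), i_omega = i,
                   x = uv[, 1], y = uv[, 2])
  })
  ba <- bundle_adjust(tr, sch, order = 2, max_rounds = 60)
  expect_lt(ba$rms_residual, 0.02)
})

test_that("iterative refinement stabilizes and propagates empty input errors", {
  sch <- small_scheme(2, tilt_step = 10, det = 128L)
  ph <- small_phantom(12, seed = 4)
  sim <- simulate_tilt_series(ph, sch, noise = list(gaussian_sigma = 0.3),
                              seed = 2)
  ir <- iterative_refine(sim$stacks, sch, min_track_length = 5)
  expect_lte(nrow(ir$cycles), 5)
  expect_false(ir$cycles$assignments_changed[nrow(ir$cycles)])
  expect_lt(ir$rms_residual, 0.5)
  # stacks with no signal: the detection error propagates
  blank <- lapply(sim$stacks, function(s) array(0, dim(s)))
  expect_error(iterative_refine(blank, sch), "no detections")
})

test_that("n3 series of an undeformed alignment sits at 1", {
  sch <- small_scheme(2, tilt_step = 5)
  tr <- make_gt_tracks(sch, small_phantom(20))
  ba <- bundle_adjust(tr, sch)
  n3s <- n3_series(ba)
  expect_equal(n3s$n3, rep(1, nrow(sch$micrographs)), tolerance = 1e-6)
})

test_that("n3 series oscillates with one period per tilt series", {
  sch <- tilt_scheme(4, tilt_step = 5)
  model <- deformation_model(c(0.02, 0.02, 0.15), tau = 1)  # fast saturation
  gt <- simulate_ground_truth(random_phantom(4, seed = 1), sch, model)
  n3s <- n3_series(gt$maps)$n3
  mic <- sch$micrographs
  # stationary bound at zero tilt depends only on the lateral compressions
  zero_val <- (1 - 0.02)^2
  expect_equal(unname(n3s[mic$tilt_deg == 0]), rep(zero_val, 4),
               tolerance = 1e-4)
  # peaks recur once per series: zero-tilt is the per-series maximum
  for (ser in 1:4) {
    idx <- mic$i_omega[mic$series == ser]
    expect_equal(which.max(n3s[idx]), which(mic$tilt_deg[idx] == 0))
  }
})

test_that("deformation fit recovers the generating parameters", {
  sch <- tilt_scheme(8, tilt_step = 2)
  model <- deformation_model(c(0.03, 0.03, 0.15), tau = 150)
  gt <- simulate_ground_truth(random_phantom(4, seed = 1), sch, model)
  clean <- n3_series(gt$maps)
  fit <- fit_deformation(clean, sch)
  expect_equal(fit$estimates$estimate[1:3], c(0.03, 0.03, 0.15),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$estimates$estimate[4], 150, tolerance = 1e-3,
               ignore_attr = TRUE)
  # flat input: all rates collapse to zero
  flat <- clean; flat$n3 <- rep(1, nrow(flat))
  f0 <- fit_deformation(flat, sch)
  expect_lt(max(f0$estimates$estimate[1:3]), 1e-6)
  # single series cannot separate lateral from normal compression
  expect_error(fit_deformation(clean[1:61, ], tilt_scheme(1, tilt_step = 2)),
               "2 series")
})

test_that("deformation estimates stay within 10 percent under noise", {
  sch <- tilt_scheme(16, tilt_step = 2)
  model <- deformation_model(c(0.03, 0.03, 0.15), tau = 90)
  gt <- simulate_ground_truth(random_phantom(4, seed = 1), sch, model)
  clean <- n3_series(gt$maps)
  biases <- matrix(0, 8, 3)
  for (k in 1:8) {
    noisy <- clean
    noisy$n3 <- withr::with_seed(100 + k,
                                 noisy$n3 + rnorm(nrow(noisy), 0, 0.002))
    fit <- fit_deformation(noisy, sch)
    biases[k, ] <- fit$estimates$estimate[1:3] / c(0.03, 0.03, 0.15) - 1
  }
  # Monte-Carlo bias well under 10 % of the true rates
  expect_lt(max(abs(colMeans(biases))), 0.1)
})

test_that("alignment and deformation objects expose tidy interfaces", {
  sch <- small_scheme(2, tilt_step = 15)
  tr <- make_gt_tracks(sch, small_phantom(10, seed = 2), sigma = 0.3)
  ba <- bundle_adjust(tr, sch)
  td <- tidy(ba)
  expect_true(all(c("bead_id", "i_omega", "residual_px") %in% names(td)))
  gl <- glance(ba)
  expect_equal(gl$n_obs, nrow(tr))
  expect_s3_class(autoplot(ba), "ggplot")

  model <- deformation_model(c(0.02, 0.02, 0.1), tau = 30)
  gt <- simulate_ground_truth(random_phantom(4, seed = 1), sch, model)
  fit <- fit_deformation(n3_series(gt$maps), sch)
  expect_equal(tidy(fit)$term, c("gamma_X", "gamma_Y", "gamma_Z", "tau"))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
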