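test_that("detector returns nothing on blank images and guards sigma", {
  expect_equal(nrow(detect_beads(matrix(0, 64, 64))), 0)
  expect_error(detect_beads(matrix(0, 64, 64), sigma = 0.5), "0.8")
})

test_that("single bead is localized to subpixel accuracy", {
  ph <- phantom(data.frame(X = 100.3 - 127.5, Y = 57.7 - 127.5, Z = 0,
                           radius = 3, density = 1))
  img <- render_micrograph(ph, nominal_map(0, 0), shape = c(256L, 256L))
  det <- detect_beads(img, sigma = 3 / sqrt(2), threshold = 0.1)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 100.3), 0.3)
  expect_lt(abs(det$y - 57.7), 0.3)
})

test_that("two beads ten sigma apart are both found within half a pixel", {
  sigma <- 3 / sqrt(2)
  ph <- phantom(data.frame(X = c(-5 * sigma, 5 * sigma), Y = 0, Z = 0,
                           radius = 3, density = 1))
  img <- render_micrograph(ph, nominal_map(0, 0), shape = c(256L, 256L))
  det <- detect_beads(img, sigma = sigma, threshold = 0.1)
  expect_equal(nrow(det), 2)
  gt <- project(nominal_map(0, 0), as.matrix(ph$beads[, c("X", "Y", "Z")]))
  for (b in 1:2) {
    expect_lt(min(sqrt((det$x - gt[b, 1])^2 + (det$y - gt[b, 2])^2)), 0.5)
  }
})

test_that("detection count is monotone non-increasing in the threshold", {
  ph <- small_phantom(15, seed = 6)
  img <- render_micrograph(ph, centred_map(0, 0), shape = c(128L, 128L),
                           noise = list(gaussian_sigma = 0.5), seed = 3)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.5, 2), function(th) {
    nrow(detect_beads(img, sigma = 2, threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection precision and recall exceed 0.95 at the default threshold", {
  ph <- small_phantom(20, seed = 4)
  hits <- 0; fas <- 0; total <- 0
  for (tilt in c(-40, 0, 40)) {
    m <- centred_map(0, tilt)
    img <- render_micrograph(ph, m, shape = c(128L, 128L),
                             noise = list(gaussian_sigma = 0.5),
                             seed = 50 + tilt)
    det <- detect_beads(img, sigma = 2, threshold = 0.1)
    gt <- project(m, as.matrix(ph$beads[, c("X", "Y", "Z")]))
    inside <- gt[, 1] >= 0 & gt[, 1] <= 127 & gt[, 2] >= 0 & gt[, 2] <= 127
    gt <- gt[inside, , drop = FALSE]
    d <- sqrt(outer(det$x, gt[, 1], `-`)^2 + outer(det$y, gt[, 2], `-`)^2)
    hits <- hits + sum(apply(d, 2, min) < 1.5)
    fas <- fas + sum(apply(d, 1, min) >= 1.5)
    total <- total + nrow(gt)
  }
  expect_gte(hits / total, 0.95)                 # recall
  expect_gte(1 - fas / (hits + fas), 0.95)       # precision
})

test_that("two exact views triangulate a bead to numerical precision", {
  bead <- c(7.3, -11.2, 9.8)
  maps <- list(nominal_map(0, -30), nominal_map(0, 25))
  det <- purrr::map_dfr(1:2, function(i) {
    uv <- project(maps[[i]], rbind(bead))
    tibble::tibble(i_omega = i, x = uv[1, 1], y = uv[1, 2])
  })
  geo <- lapply(maps, multitilt:::ray_geometry)
  X <- multitilt:::triangulate_obs(det, geo)
  expect_equal(X, bead, tolerance = 1e-6)
})

test_that("track building on exact geometry recovers every bead", {
  sch <- small_scheme(2, tilt_step = 5)
  ph <- small_phantom(20)
  gt <- simulate_ground_truth(ph, sch)
  det <- gt$tracks[gt$tracks$in_image, ]
  det <- tibble::tibble(i_omega = det$i_omega, x = det$x_px, y = det$y_px,
                        true_bead = det$bead_id)
  ts <- build_tracks(det, nominal_maps(sch), sch)
  expect_equal(sum(ts$positions3d$usable), 20)
  # zero mis-assignments: each track is pure in its ground-truth identity
  joined <- dplyr::inner_join(ts$tracks, det, by = c("i_omega", "x", "y"))
  purity <- dplyr::summarise(
    dplyr::group_by(joined, .data$bead_id),
    pure = dplyr::n_distinct(.data$true_bead) == 1)
  expect_true(all(purity$pure))
  # triangulated positions match the phantom
  pos <- ts$positions3d[ts$positions3d$usable, ]
  d <- sqrt(outer(pos$X, ph$beads$X, `-`)^2 +
              outer(pos$Y, ph$beads$Y, `-`)^2 +
              outer(pos$Z, ph$beads$Z, `-`)^2)
  expect_lt(max(apply(d, 2, min)), 0.5)
})

test_that("assignment is injective over detections", {
  sch <- small_scheme(2, tilt_step = 10)
  gt <- simulate_ground_truth(small_phantom(12, seed = 8), sch)
  det <- gt$tracks[gt$tracks$in_image, ]
  det <- tibble::tibble(i_omega = det$i_omega, x = det$x_px, y = det$y_px)
  ts <- build_tracks(det, nominal_maps(sch), sch)
  key <- paste(ts$tracks$i_omega, ts$tracks$x, ts$tracks$y)
  expect_false(any(duplicated(key)))
  # no two tracks share a detection, and each track has <= 1 per micrograph
  per_mic <- dplyr::count(ts$tracks, .data$bead_id, .data$i_omega)
  expect_true(all(per_mic$n == 1))
})

test_that("track building needs at least two micrographs", {
  det <- tibble::tibble(i_omega = 1, x = 1, y = 1)
  sch <- small_scheme(1)
  expect_error(build_tracks(det, nominal_maps(sch), sch), "2 micrographs")
})

test_that("tracking stays reliable under systematic map error", {
  sch <- small_scheme(2, tilt_step = 5)
  ph <- small_phantom(20)
  sim <- simulate_tilt_series(ph, sch, noise = list(gaussian_sigma = 0.3),
                              seed = 2)
  det <- detect_beads_stack(sim$stacks, sch, sigma = 2, threshold = 0.1)
  maps <- nominal_maps(sch)
  recov <- vapply(5:7, function(sd) {
    tsp <- build_tracks(det, shift_maps(maps, 2, seed = sd), sch,
                        match_radius = 5)
    track_recovery(tsp, det, sim$ground_truth$tracks)
  }, numeric(1))
  expect_gte(mean(recov), 0.95)
})

test_that("merging across series deduplicates and degenerates correctly", {
  sch <- small_scheme(2, tilt_step = 5)
  gt <- simulate_ground_truth(small_phantom(15, seed = 10), sch)
  det <- gt$tracks[gt$tracks$in_image, ]
  det <- tibble::tibble(i_omega = det$i_omega, x = det$x_px, y = det$y_px)
  maps <- nominal_maps(sch)
  n1 <- sum(sch$micrographs$series == 1)
  t1 <- build_tracks(det[det$i_omega <= n1, ], maps, sch,
                     min_track_length = 5)
  t2 <- build_tracks(det[det$i_omega > n1, ], maps, sch,
                     min_track_length = 5)
  merged <- merge_tracks_across_series(list(t1, t2), maps, merge_radius = 5)
  expect_equal(sum(merged$positions3d$usable), 15)   # not 2 x 15
  # merge radius 0: plain concatenation
  merged0 <- merge_tracks_across_series(list(t1, t2), maps, merge_radius = 0)
  expect_equal(nrow(merged0$positions3d),
               nrow(t1$positions3d) + nrow(t2$positions3d))
  # disjoint bead sets are preserved as a union
  tA <- build_tracks(det[det$i_omega <= n1, ], maps, sch,
                     min_track_length = 5)
  mAA <- merge_tracks_across_series(list(tA), maps, merge_radius = 5)
  expect_equal(nrow(mAA$tracks), nrow(tA$tracks))
})

test_that("IMOD-style point lists round-trip track observations", {
  tr <- tibble::tibble(bead_id = c(1L, 1L, 2L), i_omega = c(1L, 2L, 1L),
                       x = c(10.25, 11.5, 80.125), y = c(5.5, 6.75, 90))
  f <- withr::local_tempfile(fileext = ".txt")
  write_imod_points(tr, f)
  back <- read_imod_points(f)
  expect_equal(back$bead_id, tr$bead_id)
  expect_equal(back$i_omega, tr$i_omega)
  expect_equal(back$x, tr$x, tolerance = 1e-6)
  expect_equal(back$y, tr$y, tolerance = 1e-6)
})
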