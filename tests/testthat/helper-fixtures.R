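# Shared fixtures: small desk-scale geometries so the whole suite stays fast.

small_scheme <- function(n_series = 2, tilt_step = 5, det = 128L) {
  tilt_scheme(n_series, tilt_step = tilt_step,
              detector_shape = c(det, det))
}

# 20 well-separated beads on the two faces of a 40 nm slab
small_phantom <- function(n_beads = 20, seed = 3) {
  random_phantom(n_beads, extent = c(128, 128, 40), radius = 3, seed = seed)
}

centre_of <- function(det) c((det - 1) / 2, (det - 1) / 2)

# fraction of detected ground-truth observations that ended up in the track
# majority-identified with their bead
track_recovery <- function(ts, detections, gt_tracks, tol = 1.5) {
  gtt <- gt_tracks[gt_tracks$in_image, ]
  usable <- ts$positions3d$bead_id[ts$positions3d$usable]
  tr <- ts$tracks[ts$tracks$bead_id %in% usable, ]
  m <- dplyr::inner_join(tr, gtt, by = "i_omega",
                         relationship = "many-to-many")
  m <- m[abs(m$x - m$x_px) < tol & abs(m$y - m$y_px) < tol, ]
  tab <- table(m$bead_id.x, m$bead_id.y)
  track2bead <- as.integer(colnames(tab))[apply(tab, 1, which.max)]
  names(track2bead) <- rownames(tab)
  ok <- 0; detected <- 0
  for (r in seq_len(nrow(gtt))) {
    d_i <- detections[detections$i_omega == gtt$i_omega[r], ]
    if (nrow(d_i) == 0 ||
        min(sqrt((d_i$x - gtt$x_px[r])^2 + (d_i$y - gtt$y_px[r])^2)) > tol) {
      next    # bead not detected in this view: not an assignment failure
    }
    detected <- detected + 1
    tid <- names(track2bead)[track2bead == gtt$bead_id[r]]
    if (length(tid) == 0) next
    sub <- tr[tr$bead_id %in% as.integer(tid) & tr$i_omega == gtt$i_omega[r], ]
    if (nrow(sub) > 0 &&
        any(sqrt((sub$x - gtt$x_px[r])^2 + (sub$y - gtt$y_px[r])^2) < tol)) {
      ok <- ok + 1
    }
  }
  ok / detected
}

# maps shifted by a fixed-magnitude in-plane offset in a random direction
shift_maps <- function(maps, magnitude = 2, seed = 5) {
  withr::with_seed(seed, lapply(maps, function(m) {
    co <- m$coefficients
    d <- rnorm(2); d <- magnitude * d / sqrt(sum(d^2))
    co[, 1] <- co[, 1] + d
    projection_map(co, m$pixel_size)
  }))
}

# nominal map centred for a square detector of side `det`
centred_map <- function(az, tilt, det = 128) {
  nominal_map(az, tilt, detector_center = c((det - 1) / 2, (det - 1) / 2))
}
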