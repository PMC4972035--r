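gauss_kernels <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- (-r):r
  g0 <- exp(-x^2 / (2 * sigma^2)); g0 <- g0 / sum(g0)
  g1 <- -x / sigma^2 * g0
  g2 <- (x^2 - sigma^2) / sigma^4 * g0
  list(g0 = g0, g1 = g1, g2 = g2)
}

#' Detect gold beads in a micrograph
#'
#' Blob detection with a second-order Gaussian-derivative operator: the
#' scale-normalized determinant of the Hessian at scale `sigma`,
#' `sigma^4 * (Lxx * Lyy - Lxy^2)`.  Local maxima of the response above
#' `threshold` whose Laplacian sign matches the requested polarity are
#' refined to subpixel positions by a quadratic fit of the response in a
#' 3 x 3 neighbourhood.  For a bead of radius `r` px the matched scale is
#' about `r/sqrt(2)`.
#'
#' @param image Numeric matrix (`img[x + 1, y + 1]`, 0-based pixel coords).
#' @param sigma Detection scale in px (>= 0.8).
#' @param threshold Response threshold (a.u.; response scales like the
#'   squared blob contrast).
#' @param polarity `"bright"` for dense-bright images (this package's
#'   simulator convention) or `"dark"`.
#' @return Tibble with columns `x`, `y` (subpixel, 0-based), `response`,
#'   `sigma`, sorted by descending response.
#' @export
detect_beads <- function(image, sigma = 2, threshold = 0.1,
                         polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (sigma < 0.8) stop("`sigma` must be >= 0.8 px", call. = FALSE)
  nx <- nrow(image); ny <- ncol(image)
  k <- gauss_kernels(sigma)
  Lxx <- conv_sep_cpp(image, k$g2, k$g0)
  Lyy <- conv_sep_cpp(image, k$g0, k$g2)
  Lxy <- conv_sep_cpp(image, k$g1, k$g1)
  resp <- sigma^4 * (Lxx * Lyy - Lxy^2)
  trace_ok <- if (polarity == "bright") (Lxx + Lyy) < 0 else (Lxx + Lyy) > 0

  # strict 3x3 local maxima, excluding a 1 px frame
  cand <- which(resp > threshold & trace_ok, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nx & cand[, 2] > 1 & cand[, 2] < ny,
               , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          response = numeric(0), sigma = numeric(0)))
  }
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    v <- resp[i, j]
    nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v < max(nb)) return(FALSE)
    # response plateaus (exact symmetry) keep only their first pixel in
    # column-major order, so ties stay deterministic
    ties <- which(nb == v)
    ties[1] == 5 || all(ties >= 5)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          response = numeric(0), sigma = numeric(0)))
  }
  sub <- t(vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    dxx <- resp[i + 1, j] - 2 * resp[i, j] + resp[i - 1, j]
    dyy <- resp[i, j + 1] - 2 * resp[i, j] + resp[i, j - 1]
    ox <- if (dxx < 0) -(resp[i + 1, j] - resp[i - 1, j]) / (2 * dxx) else 0
    oy <- if (dyy < 0) -(resp[i, j + 1] - resp[i, j - 1]) / (2 * dyy) else 0
    c(i - 1 + max(-1, min(1, ox)), j - 1 + max(-1, min(1, oy)))
  }, numeric(2)))
  out <- tibble::tibble(
    x = sub[, 1], y = sub[, 2],
    response = resp[cand], sigma = sigma
  )
  dplyr::arrange(out, dplyr::desc(.data$response))
}

#' Detect beads across a whole multi-tilt acquisition
#'
#' @param stacks List of `nx x ny x n_tilt` arrays, one per series (e.g.
#'   `mt_simulation$stacks`).
#' @param scheme The matching [tilt_scheme()].
#' @inheritParams detect_beads
#' @return Tibble of detections with an `i_omega` column.
#' @export
detect_beads_stack <- function(stacks, scheme, sigma = 2, threshold = 0.1,
                               polarity = "bright") {
  mic <- scheme$micrographs
  purrr::map_dfr(mic$i_omega, function(i) {
    s <- mic$series[i]
    j <- which(mic$i_omega[mic$series == s] == i)
    det <- detect_beads(stacks[[s]][, , j], sigma, threshold, polarity)
    if (nrow(det)) det$i_omega <- i
    det
  })
}

# ---- ray utilities (affine maps) -------------------------------------------

ray_geometry <- function(map) {
  lp <- linear_part(map)
  M <- lp$M
  b <- c(
    M[1, 2] * M[2, 3] - M[1, 3] * M[2, 2],
    M[1, 3] * M[2, 1] - M[1, 1] * M[2, 3],
    M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  )
  list(M = M, t = lp$t, Mp = MASS_ginv(M), b = b / sqrt(sum(b^2)))
}

# Least-squares 3D position from affine observations; obs is a data frame
# with i_omega, x, y; geo a list of ray_geometry by i_omega.
triangulate_obs <- function(obs, geo) {
  A <- matrix(0, 3, 3); rhs <- numeric(3)
  for (r in seq_len(nrow(obs))) {
    g <- geo[[obs$i_omega[r]]]
    A <- A + crossprod(g$M)
    rhs <- rhs + crossprod(g$M, c(obs$x[r], obs$y[r]) - g$t)
  }
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(out)) {
    # views do not constrain all three coordinates (e.g. two zero-tilt
    # rays); regularize towards the origin plane
    out <- solve(A + diag(1e-9 * max(diag(A)) + 1e-12, 3), rhs)
  }
  as.numeric(out)
}

#' Build fiducial tracks from per-micrograph detections
#'
#' Cluster-analysis track building: each detection is back-projected to a 3D
#' ray through its micrograph's (initial, typically nominal) map; candidate
#' 3D bead positions are seeded by closest-approach triangulation of ray
#' pairs between a low-tilt anchor micrograph and an oblique partner in each
#' series; candidates then grow greedily, assigning each detection (at most
#' once, ties broken by ascending `i_omega`) to the candidate whose
#' reprojection falls nearest within `match_radius`; one pass of
#' re-triangulation and re-assignment refines the clusters.  Detections left
#' unassigned remain singleton tracks.
#'
#' @param detections Tibble with columns `i_omega`, `x`, `y`.
#' @param maps List of affine [projection_map()]s by `i_omega`.
#' @param scheme The [tilt_scheme()].
#' @param match_radius Assignment radius in detector px.
#' @param min_track_length Minimum observations for a track to be considered
#'   usable for alignment (shorter tracks are kept but flagged).
#' @param partner_tilt Tilt offset (deg) used to pick the triangulation
#'   partner micrograph in each series.
#' @return A `marker_track_set`: `tracks` (tibble `bead_id`, `i_omega`,
#'   `x`, `y`), `positions3d` (tibble `bead_id`, `X`, `Y`, `Z`, `n_obs`,
#'   `usable`), `residuals` (per-observation reprojection errors, px).
#' @export
build_tracks <- function(detections, maps, scheme, match_radius = 5,
                         min_track_length = 10, partner_tilt = 30) {
  detections <- tibble::as_tibble(detections)
  mics <- sort(unique(detections$i_omega))
  if (length(mics) < 2) {
    stop("need detections in at least 2 micrographs to triangulate",
         call. = FALSE)
  }
  geo <- vector("list", max(mics))
  for (i in mics) geo[[i]] <- ray_geometry(maps[[i]])
  mic <- scheme$micrographs

  # --- seeding + growth; leftover detections re-seed new candidates so
  # beads whose first candidate was merged away or out-competed recover
  P <- NULL
  assign <- rep(NA_integer_, nrow(detections))
  for (round in 1:3) {
    leftover <- detections[is.na(assign), ]
    newP <- seed_candidates(leftover, geo, mic, mics, match_radius,
                            partner_tilt, scheme$pixel_size)
    if (!is.null(newP) && nrow(newP) > 0) {
      P <- dedup_positions(rbind(P, newP), match_radius * scheme$pixel_size)
    }
    if (is.null(P) || nrow(P) == 0) {
      stop("no 3D candidates could be triangulated from the detections",
           call. = FALSE)
    }
    # greedy growth + re-triangulation; between passes, estimate a common
    # per-micrograph offset from the matched residuals (systematic map
    # error is shared by every detection of a micrograph) and fold it into
    # the ray geometry
    for (pass in 1:3) {
      assign <- grow_tracks(P, detections, geo, mics, match_radius)
      for (cid in seq_len(nrow(P))) {
        obs <- detections[which(assign == cid), ]
        if (nrow(obs) >= 2) P[cid, ] <- triangulate_obs(obs, geo)
      }
      if (pass < 3) geo <- correct_map_offsets(geo, P, assign, detections,
                                               mics)
    }
    # relaxed-gate absorption: re-attach still-unassigned detections to
    # established clusters (at twice the match radius) before re-seeding,
    # so systematic map error does not spawn duplicate candidates
    cnt <- tabulate(assign[!is.na(assign)], nbins = nrow(P))
    big <- which(cnt >= max(min_track_length, 2))
    if (length(big) > 0) {
      locked <- match(assign, big)
      sub <- grow_tracks(P[big, , drop = FALSE], detections, geo, mics,
                         2 * match_radius, locked = locked)
      assign <- ifelse(is.na(sub), assign, big[sub])
    }
    if (!anyNA(assign)) break
  }

  # merge duplicate candidates: a systematically mis-tracked bead shows up
  # as two nearby candidates with *complementary* observation sets (a real
  # close bead pair conflicts in nearly every micrograph instead); drop the
  # smaller of such a pair and let the final absorption pass re-attach its
  # observations
  cnt <- tabulate(assign[!is.na(assign)], nbins = nrow(P))
  ord <- order(-cnt)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (cnt[i] == 0) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (cnt[j] == 0) next
      close_3d <- sqrt(sum((P[i, ] - P[j, ])^2)) <
        3 * match_radius * scheme$pixel_size
      if (!close_3d) next
      mi <- detections$i_omega[which(assign == i)]
      mj <- detections$i_omega[which(assign == j)]
      overlap <- length(intersect(mi, mj)) / max(length(mj), 1L)
      if (overlap < 0.2) {
        assign[which(assign == j)] <- NA_integer_
        cnt[j] <- 0L
      }
    }
  }
  big <- which(cnt >= max(min_track_length, 2))
  if (length(big) > 0 && anyNA(assign)) {
    locked <- match(assign, big)
    sub <- grow_tracks(P[big, , drop = FALSE], detections, geo, mics,
                       2 * match_radius, locked = locked)
    assign <- ifelse(is.na(sub), assign, big[sub])
  }

  tracks <- detections[!is.na(assign), c("i_omega", "x", "y")]
  tracks$bead_id <- assign[!is.na(assign)]
  # singletons: unassigned detections keep their own identity
  singles <- detections[is.na(assign), c("i_omega", "x", "y")]
  if (nrow(singles) > 0) {
    singles$bead_id <- nrow(P) + seq_len(nrow(singles))
    tracks <- dplyr::bind_rows(tracks, singles)
  }
  tracks <- dplyr::arrange(tracks, .data$bead_id, .data$i_omega)
  finalize_track_set(tracks, P, geo, min_track_length)
}

# Median residual vector per micrograph over assigned detections, folded
# into the map offsets; a cheap one-parameter-per-image alignment that makes
# track growth robust to systematic initial-map error.
correct_map_offsets <- function(geo, P, assign, detections, mics) {
  for (i in mics) {
    rows <- which(detections$i_omega == i & !is.na(assign))
    if (length(rows) < 3) next
    g <- geo[[i]]
    uv <- P[assign[rows], , drop = FALSE] %*% t(g$M) +
      matrix(g$t, length(rows), 2, byrow = TRUE)
    off <- c(median(detections$x[rows] - uv[, 1]),
             median(detections$y[rows] - uv[, 2]))
    g$t <- g$t + off
    geo[[i]] <- g
  }
  geo
}

seed_candidates <- function(detections, geo, mic, mics, match_radius,
                            partner_tilt, pixel_size) {
  cand <- list()
  for (s in unique(mic$series[mic$i_omega %in% mics])) {
    sm <- mic[mic$series == s & mic$i_omega %in% mics, ]
    anchor <- sm$i_omega[which.min(abs(sm$tilt_deg))]
    partner <- sm$i_omega[which.min(abs(abs(sm$tilt_deg -
      sm$tilt_deg[which.min(abs(sm$tilt_deg))]) - partner_tilt))]
    if (partner == anchor) next
    da <- detections[detections$i_omega == anchor, ]
    db <- detections[detections$i_omega == partner, ]
    if (nrow(da) == 0 || nrow(db) == 0) next
    ga <- geo[[anchor]]; gb <- geo[[partner]]
    pa <- cbind(da$x - ga$t[1], da$y - ga$t[2]) %*% t(ga$Mp)
    pb <- cbind(db$x - gb$t[1], db$y - gb$t[2]) %*% t(gb$Mp)
    for (ia in seq_len(nrow(da))) {
      best <- NULL; bestd <- Inf
      for (ib in seq_len(nrow(db))) {
        ca <- ray_closest_points(pa[ia, ], ga$b, pb[ib, ], gb$b)
        if (!is.null(ca) && ca$dist < bestd) { bestd <- ca$dist; best <- ca$mid }
      }
      tol <- 2 * match_radius * pixel_size
      if (!is.null(best) && bestd < tol) cand[[length(cand) + 1L]] <- best
    }
  }
  if (length(cand) == 0) return(NULL)
  do.call(rbind, cand)
}

ray_closest_points <- function(p1, d1, p2, d2) {
  w <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * cc - b * b
  if (den < 1e-12) return(NULL)  # parallel rays
  s <- (b * e - cc * d) / den
  t <- (a * e - b * d) / den
  q1 <- p1 + s * d1; q2 <- p2 + t * d2
  list(dist = sqrt(sum((q1 - q2)^2)), mid = (q1 + q2) / 2)
}

dedup_positions <- function(P, radius) {
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P))) {
    if (!keep[i]) next
    if (i < nrow(P)) {
      d <- sqrt(rowSums((P[(i + 1):nrow(P), , drop = FALSE] -
                           matrix(P[i, ], nrow(P) - i, 3, byrow = TRUE))^2))
      keep[(i + 1):nrow(P)][d < radius] <- FALSE
    }
  }
  P[keep, , drop = FALSE]
}

# Greedy detection-to-candidate assignment by ascending reprojection
# distance; each detection used at most once, at most one detection per
# (candidate, micrograph).  Returns a candidate id (or NA) per detection row.
grow_tracks <- function(P, detections, geo, mics, match_radius,
                        locked = NULL) {
  pairs <- list()
  for (i in mics) {
    det_rows <- which(detections$i_omega == i)
    if (length(det_rows) == 0) next
    g <- geo[[i]]
    uv <- P %*% t(g$M) + matrix(g$t, nrow(P), 2, byrow = TRUE)
    dmat <- sqrt(outer(uv[, 1], detections$x[det_rows], `-`)^2 +
                   outer(uv[, 2], detections$y[det_rows], `-`)^2)
    hit <- which(dmat < match_radius, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        cand = hit[, 1], det = det_rows[hit[, 2]],
        i_omega = i, dist = dmat[hit]
      )
    }
  }
  assign <- rep(NA_integer_, nrow(detections))
  slot_used <- matrix(FALSE, nrow(P), max(detections$i_omega))
  if (!is.null(locked)) {
    lock_rows <- which(!is.na(locked))
    assign[lock_rows] <- locked[lock_rows]
    slot_used[cbind(locked[lock_rows], detections$i_omega[lock_rows])] <- TRUE
  }
  if (length(pairs) == 0) return(assign)
  pairs <- dplyr::arrange(dplyr::bind_rows(pairs), .data$dist, .data$i_omega,
                          .data$det)
  for (r in seq_len(nrow(pairs))) {
    d <- pairs$det[r]; cid <- pairs$cand[r]; i <- pairs$i_omega[r]
    if (is.na(assign[d]) && !slot_used[cid, i]) {
      assign[d] <- cid
      slot_used[cid, i] <- TRUE
    }
  }
  assign
}

finalize_track_set <- function(tracks, P, geo, min_track_length) {
  sizes <- dplyr::count(tracks, .data$bead_id, name = "n_obs")
  pos <- tibble::tibble(
    bead_id = sizes$bead_id,
    X = NA_real_, Y = NA_real_, Z = NA_real_,
    n_obs = sizes$n_obs,
    usable = sizes$n_obs >= max(min_track_length, 2)
  )
  res <- rep(NA_real_, nrow(tracks))
  for (r in seq_len(nrow(pos))) {
    obs <- tracks[tracks$bead_id == pos$bead_id[r], ]
    if (pos$n_obs[r] >= 2) {
      X <- triangulate_obs(obs, geo)
      pos[r, c("X", "Y", "Z")] <- as.list(X)
      for (k in which(tracks$bead_id == pos$bead_id[r])) {
        g <- geo[[tracks$i_omega[k]]]
        uv <- as.numeric(g$M %*% X + g$t)
        res[k] <- sqrt(sum((uv - c(tracks$x[k], tracks$y[k]))^2))
      }
    }
  }
  structure(
    list(tracks = tracks, positions3d = pos, residuals = res),
    class = "marker_track_set"
  )
}

#' @export
print.marker_track_set <- function(x, ...) {
  cat("<marker_track_set>", nrow(x$positions3d), "tracks (",
      sum(x$positions3d$usable), "usable ),", nrow(x$tracks),
      "observations\n")
  if (any(!is.na(x$residuals))) {
    cat("  rms reprojection residual:",
        signif(sqrt(mean(x$residuals^2, na.rm = TRUE)), 4), "px\n")
  }
  invisible(x)
}

#' Merge marker track sets across tilt series
#'
#' Tracks whose triangulated 3D positions (all series share one specimen
#' frame via the azimuths in their maps) agree within `merge_radius` become
#' one bead identity; observations are indexed by global `i_omega`
#' throughout so the union is well defined.  A `merge_radius` of 0 disables
#' merging (the output is the concatenation).
#'
#' @param track_sets List of `marker_track_set`s.
#' @param maps List of affine maps by `i_omega` (for recomputing residuals).
#' @param merge_radius 3D merge radius in specimen units (nm).
#' @param min_track_length See [build_tracks()].
#' @return A merged `marker_track_set`.
#' @export
merge_tracks_across_series <- function(track_sets, maps, merge_radius = 5,
                                       min_track_length = 10) {
  all_tracks <- list(); all_pos <- list()
  offset <- 0L
  for (ts in track_sets) {
    tr <- ts$tracks; tr$bead_id <- tr$bead_id + offset
    po <- ts$positions3d; po$bead_id <- po$bead_id + offset
    all_tracks[[length(all_tracks) + 1L]] <- tr
    all_pos[[length(all_pos) + 1L]] <- po
    offset <- offset + max(ts$positions3d$bead_id)
  }
  tracks <- dplyr::bind_rows(all_tracks)
  pos <- dplyr::bind_rows(all_pos)

  # union-find by greedy 3D agreement
  parent <- pos$bead_id
  if (merge_radius > 0) {
    located <- pos[!is.na(pos$X), ]
    if (nrow(located) > 1) {
      for (i in 1:(nrow(located) - 1)) {
        for (j in (i + 1):nrow(located)) {
          d <- sqrt(sum((as.numeric(located[i, c("X", "Y", "Z")]) -
                           as.numeric(located[j, c("X", "Y", "Z")]))^2))
          if (d < merge_radius) {
            ri <- find_root(parent, pos$bead_id, located$bead_id[i])
            rj <- find_root(parent, pos$bead_id, located$bead_id[j])
            if (ri != rj) parent[match(max(ri, rj), pos$bead_id)] <- min(ri, rj)
          }
        }
      }
    }
  }
  root <- vapply(pos$bead_id, function(b) find_root(parent, pos$bead_id, b),
                 numeric(1))
  relabel <- match(root, sort(unique(root)))
  tracks$bead_id <- relabel[match(tracks$bead_id, pos$bead_id)]
  tracks <- dplyr::arrange(tracks, .data$bead_id, .data$i_omega)

  mics <- sort(unique(tracks$i_omega))
  geo <- vector("list", max(mics))
  for (i in mics) geo[[i]] <- ray_geometry(maps[[i]])
  finalize_track_set(tracks, matrix(0, max(relabel), 3), geo,
                     min_track_length)
}

find_root <- function(parent, ids, b) {
  repeat {
    p <- parent[match(b, ids)]
    if (p == b) return(b)
    b <- p
  }
}

#' IMOD-style fiducial point-list adapter
#'
#' Optional interchange format: one point per line, `contour x y z`, where
#' the contour id groups the observations of one bead and `z` is the
#' 0-based view (micrograph) index — the layout of fiducial models exported
#' from interactive tomography tools as plain text.
#'
#' @param tracks Track observation tibble with columns `bead_id`,
#'   `i_omega`, `x`, `y` (or a `marker_track_set`).
#' @param path File path.
#' @return `write_imod_points` returns `path` invisibly;
#'   `read_imod_points` returns a tibble with columns `bead_id`,
#'   `i_omega`, `x`, `y`.
#' @export
write_imod_points <- function(tracks, path) {
  tr <- if (inherits(tracks, "marker_track_set")) tracks$tracks
    else tibble::as_tibble(tracks)
  lines <- sprintf("%d %.6f %.6f %d", tr$bead_id, tr$x, tr$y,
                   tr$i_omega - 1L)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_imod_points
#' @export
read_imod_points <- function(path) {
  m <- do.call(rbind, lapply(strsplit(trimws(readLines(path)), "\\s+"),
                             as.numeric))
  tibble::tibble(
    bead_id = as.integer(m[, 1]),
    i_omega = as.integer(m[, 4]) + 1L,
    x = m[, 2], y = m[, 3]
  )
}
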