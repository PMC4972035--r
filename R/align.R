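as_track_table <- function(tracks) {
  if (inherits(tracks, "marker_track_set")) {
    usable <- tracks$positions3d$bead_id[tracks$positions3d$usable]
    tr <- tracks$tracks[tracks$tracks$bead_id %in% usable, ]
  } else {
    tr <- tibble::as_tibble(tracks)
  }
  if (all(c("x_px", "y_px") %in% names(tr)) && !("x" %in% names(tr))) {
    tr <- dplyr::rename(tr, x = "x_px", y = "y_px")
  }
  stopifnot(all(c("bead_id", "i_omega", "x", "y") %in% names(tr)))
  tr[, c("bead_id", "i_omega", "x", "y")]
}

monomial_design <- function(pts, expo) {
  A <- vapply(seq_len(nrow(expo)), function(k) {
    pts[, 1]^expo[k, 1] * pts[, 2]^expo[k, 2] * pts[, 3]^expo[k, 3]
  }, numeric(nrow(pts)))
  matrix(A, nrow = nrow(pts))
}

# 2x3 Jacobian of a polynomial map at a 3D point
poly_jacobian <- function(coef, expo, X) {
  J <- matrix(0, 2, 3)
  for (a in 1:3) {
    e <- expo
    keep <- e[, a] > 0
    if (!any(keep)) next
    fac <- e[keep, a]
    e2 <- e[keep, , drop = FALSE]
    e2[, a] <- e2[, a] - 1L
    mono <- X[1]^e2[, 1] * X[2]^e2[, 2] * X[3]^e2[, 3] * fac
    J[, a] <- coef[, keep, drop = FALSE] %*% mono
  }
  J
}

#' Simultaneous multi-series bundle adjustment
#'
#' Joint least-squares estimation of one polynomial projection map per
#' micrograph and one 3D position per bead, minimizing the total squared
#' reprojection error over all series simultaneously.  The solver
#' alternates two closed-form blocks: (a) per-micrograph linear least
#' squares for the map coefficients given the positions (a polynomial map
#' is linear in its coefficients) and (b) per-bead refinement of the 3D
#' position given the maps (exactly linear for order 1, Gauss-Newton
#' otherwise), iterated until the relative cost change drops below `tol`.
#' The global affine gauge freedom is fixed by pinning the zero-tilt map of
#' series 1 to its initial (nominal) value.  Orders above 1 are warm-started
#' from the next-lower-order solution.
#'
#' @param tracks A `marker_track_set` (only usable tracks are used) or a
#'   tibble with columns `bead_id`, `i_omega`, `x`, `y`.
#' @param scheme The [tilt_scheme()].
#' @param order Polynomial map order (1, 2 or 3); order 1 (affine) is the
#'   default and is exact for rigid geometry plus uniform compression.
#' @param init Optional list of initial maps by `i_omega` (default nominal).
#' @param max_rounds Maximum alternation rounds.
#' @param tol Relative cost-change convergence threshold.
#' @param huber Optional Huber robust weighting; `FALSE` (default) keeps the
#'   problem exactly least-squares, `TRUE` uses delta = 3 x MAD of the
#'   current residuals.
#' @return An `mt_alignment`: `maps` (list by `i_omega`), `positions3d`
#'   (tibble), `residuals` (tibble with per-observation errors),
#'   `rms_residual` (px), `cost_history`, `gauge`, `converged`.
#' @export
bundle_adjust <- function(tracks, scheme, order = 1, init = NULL,
                          max_rounds = 200, tol = 1e-10, huber = FALSE) {
  stopifnot(order %in% 1:3)
  tr <- as_track_table(tracks)
  counts <- dplyr::count(tr, .data$bead_id)
  tr <- tr[tr$bead_id %in% counts$bead_id[counts$n >= 2], ]
  mic <- scheme$micrographs
  tr <- dplyr::left_join(tr, mic[, c("i_omega", "series")], by = "i_omega")
  if (scheme$n_series > 1) {
    span <- dplyr::summarise(dplyr::group_by(tr, .data$bead_id),
                             ns = dplyr::n_distinct(.data$series))
    if (sum(span$ns >= 2) < 4) {
      stop("need at least 4 tracks spanning >= 2 series", call. = FALSE)
    }
  }
  if (is.null(init)) init <- nominal_maps(scheme)
  if (order > 1) {
    warm <- bundle_adjust(tr, scheme, order - 1, init = init,
                          max_rounds = max_rounds, tol = tol, huber = huber)
    init <- purrr::map(warm$maps, ~ promote_order(.x, order))
  } else {
    init <- purrr::map(init, ~ promote_order(.x, 1))
  }

  expo <- monomial_exponents(order)
  m <- nrow(expo)
  bead_ids <- sort(unique(tr$bead_id))
  bead_idx <- match(tr$bead_id, bead_ids)
  nb <- length(bead_ids)
  obs_mic <- sort(unique(tr$i_omega))

  # gauge: zero-tilt micrograph of series 1
  s1 <- mic[mic$series == 1, ]
  pin <- s1$i_omega[which.min(abs(s1$tilt_deg))]

  maps <- init
  coefs <- purrr::map(maps, "coefficients")
  geo <- vector("list", max(obs_mic))
  for (i in obs_mic) geo[[i]] <- ray_geometry(maps[[i]])
  # positions are defined in the (nearly) pristine specimen state, so they
  # are initialized from the lowest-dose views; triangulating from all views
  # would average over the deformation trajectory and leave the solver a
  # slowly-converging global mode
  early <- ceiling(length(scheme$tilt_angles) / 3)
  X <- matrix(0, nb, 3)
  for (r in seq_len(nb)) {
    rows <- which(bead_idx == r & tr$i_omega <= early)
    if (length(rows) < 3) rows <- which(bead_idx == r)
    X[r, ] <- triangulate_obs(tr[rows, ], geo)
  }

  cost_history <- numeric(0)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    w <- rep(1, nrow(tr))
    if (huber && length(cost_history) > 0) {
      res <- obs_residual_norms(tr, coefs, expo, X, bead_idx)
      delta <- 3 * stats::mad(res)
      w <- ifelse(res <= delta, 1, delta / res)
    }
    # (a) map step: per-micrograph normal equations, accumulated by rowsum
    A_all <- monomial_design(X[bead_idx, , drop = FALSE], expo)
    cross_cols <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
    AtA <- rowsum(A_all[, cross_cols[, 1], drop = FALSE] *
                    A_all[, cross_cols[, 2], drop = FALSE] * w, tr$i_omega)
    Atx <- rowsum(A_all * (tr$x * w), tr$i_omega)
    Aty <- rowsum(A_all * (tr$y * w), tr$i_omega)
    nobs_mic <- rowsum(rep(1L, nrow(tr)), tr$i_omega)
    mic_ids <- as.integer(rownames(AtA))
    for (g in seq_along(mic_ids)) {
      i <- mic_ids[g]
      if (i == pin) next
      if (nobs_mic[g] < m) {
        stop("underdetermined map for micrograph ", i, ": ", nobs_mic[g],
             " observations for ", m, " coefficients", call. = FALSE)
      }
      N <- matrix(0, m, m)
      N[cross_cols] <- AtA[g, ]
      N[cross_cols[, 2:1]] <- AtA[g, ]
      sol <- tryCatch(solve(N, cbind(Atx[g, ], Aty[g, ])),
                      error = function(e)
                        stop("underdetermined map for micrograph ", i,
                             call. = FALSE))
      coefs[[i]] <- t(sol)
    }
    # (b) bead step
    if (order == 1) {
      X <- solve_beads_affine(tr, coefs, bead_idx, nb, w)
    } else {
      for (r in seq_len(nb)) {
        rows <- which(bead_idx == r)
        X[r, ] <- gauss_newton_bead(X[r, ], tr[rows, ], coefs, expo,
                                    w[rows])
      }
    }
    cost <- sum(w * obs_residual_norms(tr, coefs, expo, X, bead_idx)^2)
    cost_history <- c(cost_history, cost)
    if (cost < 1e-16 * nrow(tr)) {
      converged <- TRUE
      break
    }
    if (round > 1) {
      prev <- cost_history[round - 1]
      if (abs(prev - cost) / max(prev, 1e-300) < tol) {
        converged <- TRUE
        break
      }
    }
  }

  for (i in seq_along(maps)) {
    maps[[i]] <- projection_map(coefs[[i]], pixel_size = scheme$pixel_size)
  }
  res_norm <- obs_residual_norms(tr, coefs, expo, X, bead_idx)
  residuals <- tibble::tibble(
    bead_id = tr$bead_id, i_omega = tr$i_omega, series = tr$series,
    x = tr$x, y = tr$y, residual_px = res_norm
  )
  structure(
    list(
      maps = maps,
      positions3d = tibble::as_tibble(data.frame(
        bead_id = bead_ids, X = X[, 1], Y = X[, 2], Z = X[, 3])),
      residuals = residuals,
      rms_residual = sqrt(mean(res_norm^2) / 2),
      cost_history = cost_history,
      gauge = paste0("map of micrograph i_omega=", pin,
                     " (series 1, zero tilt) pinned to its initial value"),
      gauge_i_omega = pin,
      order = order,
      scheme = scheme,
      converged = converged
    ),
    class = "mt_alignment"
  )
}

promote_order <- function(map, order) {
  if (map$order == order) return(map)
  stopifnot(map$order < order)
  m_new <- n_monomials(order)
  co <- matrix(0, 2, m_new)
  # graded-lex: lower-order monomials are a prefix of the higher-order table
  co[, seq_len(ncol(map$coefficients))] <- map$coefficients
  projection_map(co, pixel_size = map$pixel_size)
}

obs_residual_norms <- function(tr, coefs, expo, X, bead_idx) {
  A <- monomial_design(X[bead_idx, , drop = FALSE], expo)
  m <- nrow(expo)
  comat <- t(vapply(coefs, as.numeric, numeric(2 * m)))
  co <- comat[tr$i_omega, , drop = FALSE]
  # as.numeric(2 x m) interleaves rows: odd entries are x, even are y
  pred_x <- rowSums(A * co[, 2 * seq_len(m) - 1, drop = FALSE])
  pred_y <- rowSums(A * co[, 2 * seq_len(m), drop = FALSE])
  sqrt((pred_x - tr$x)^2 + (pred_y - tr$y)^2)
}

# Vectorized per-bead linear solve for affine maps via per-observation
# normal-equation accumulation.
solve_beads_affine <- function(tr, coefs, bead_idx, nb, w) {
  comat <- t(vapply(coefs, as.numeric, numeric(8)))
  co <- comat[tr$i_omega, , drop = FALSE]
  # column order of as.numeric(2x4): t_x, t_y, a11, a21, a12, a22, a13, a23
  a11 <- co[, 3]; a21 <- co[, 4]; a12 <- co[, 5]; a22 <- co[, 6]
  a13 <- co[, 7]; a23 <- co[, 8]
  rx <- tr$x - co[, 1]; ry <- tr$y - co[, 2]
  g <- function(v) rowsum(v * w, bead_idx)
  n11 <- g(a11^2 + a21^2); n12 <- g(a11 * a12 + a21 * a22)
  n13 <- g(a11 * a13 + a21 * a23); n22 <- g(a12^2 + a22^2)
  n23 <- g(a12 * a13 + a22 * a23); n33 <- g(a13^2 + a23^2)
  b1 <- g(a11 * rx + a21 * ry); b2 <- g(a12 * rx + a22 * ry)
  b3 <- g(a13 * rx + a23 * ry)
  X <- matrix(0, nb, 3)
  for (r in seq_len(nb)) {
    N <- matrix(c(n11[r], n12[r], n13[r],
                  n12[r], n22[r], n23[r],
                  n13[r], n23[r], n33[r]), 3, 3)
    X[r, ] <- solve(N, c(b1[r], b2[r], b3[r]))
  }
  X
}

gauss_newton_bead <- function(X0, obs, coefs, expo, w, iters = 3) {
  X <- X0
  for (it in seq_len(iters)) {
    J <- matrix(0, 2 * nrow(obs), 3)
    r <- numeric(2 * nrow(obs))
    for (k in seq_len(nrow(obs))) {
      co <- coefs[[obs$i_omega[k]]]
      A <- monomial_design(matrix(X, 1), expo)
      pred <- as.numeric(A %*% t(co))
      J[(2 * k - 1):(2 * k), ] <- poly_jacobian(co, expo, X) * sqrt(w[k])
      r[(2 * k - 1):(2 * k)] <- (c(obs$x[k], obs$y[k]) - pred) * sqrt(w[k])
    }
    step <- tryCatch(qr.solve(J, r), error = function(e) rep(0, 3))
    X <- X + step
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  X
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("<mt_alignment> order", x$order, ",", length(x$maps), "maps,",
      nrow(x$positions3d), "beads,", nrow(x$residuals), "observations\n")
  cat("  rms reprojection residual:", signif(x$rms_residual, 6), "px",
      if (x$converged) "(converged)" else "(round cap reached)", "\n")
  cat("  gauge:", x$gauge, "\n")
  invisible(x)
}

#' @rdname bundle_adjust
#' @param x An `mt_alignment`.
#' @param ... Unused.
#' @method tidy mt_alignment
#' @export
tidy.mt_alignment <- function(x, ...) x$residuals

#' @rdname bundle_adjust
#' @method glance mt_alignment
#' @export
glance.mt_alignment <- function(x, ...) {
  tibble::tibble(
    rms_residual = x$rms_residual,
    n_obs = nrow(x$residuals),
    n_beads = nrow(x$positions3d),
    n_maps = length(x$maps),
    order = x$order,
    rounds = length(x$cost_history),
    converged = x$converged
  )
}

#' @rdname bundle_adjust
#' @param object An `mt_alignment`.
#' @method autoplot mt_alignment
#' @export
autoplot.mt_alignment <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$i_omega, y = .data$residual_px)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = "micrograph index", y = "reprojection residual (px)")
}

#' Iteratively refine detection-based alignment
#'
#' Alternates track building (with the current maps) and bundle adjustment
#' until the track assignments stop changing or `max_cycles` is reached.
#'
#' @param stacks List of per-series image arrays.
#' @param scheme The [tilt_scheme()].
#' @param order Map polynomial order.
#' @param sigma,threshold,polarity Passed to [detect_beads_stack()].
#' @param match_radius,min_track_length Passed to [build_tracks()].
#' @param max_cycles Cycle cap (a warning is issued if assignments are still
#'   changing when it is hit).
#' @return The final `mt_alignment`, with a `cycles` tibble attached
#'   describing each refinement cycle.
#' @export
iterative_refine <- function(stacks, scheme, order = 1, sigma = 2,
                             threshold = 0.1, polarity = "bright",
                             match_radius = 5, min_track_length = 10,
                             max_cycles = 10) {
  detections <- detect_beads_stack(stacks, scheme, sigma, threshold, polarity)
  if (nrow(detections) == 0) stop("no detections in any micrograph",
                                  call. = FALSE)
  maps <- nominal_maps(scheme)
  prev_sig <- NULL
  log <- list()
  ba <- NULL
  for (cycle in seq_len(max_cycles)) {
    ts <- build_tracks(detections, maps, scheme, match_radius,
                       min_track_length)
    sig <- assignment_signature(ts, detections)
    changed <- is.null(prev_sig) || !identical(sig, prev_sig)
    ba <- bundle_adjust(ts, scheme, order = order, init = maps)
    maps <- ba$maps
    log[[cycle]] <- tibble::tibble(
      cycle = cycle, n_tracks = sum(ts$positions3d$usable),
      rms_residual = ba$rms_residual, assignments_changed = changed
    )
    if (!changed) break
    prev_sig <- sig
  }
  if (cycle == max_cycles && changed) {
    warning("track assignments still changing at the cycle cap",
            call. = FALSE)
  }
  ba$cycles <- dplyr::bind_rows(log)
  ba
}

# canonical partition signature of detections into tracks (stable under
# bead relabeling)
assignment_signature <- function(ts, detections) {
  key <- paste(ts$tracks$i_omega, round(ts$tracks$x, 6),
               round(ts$tracks$y, 6))
  groups <- split(key, ts$tracks$bead_id)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

#' Deformation indicator series from an alignment
#'
#' Applies [n3()] to every aligned projection map in acquisition order.
#' For an undeformed specimen the series stays at 1; dose-dependent
#' compression makes it oscillate with one period per tilt series, between
#' an upper bound set by the lateral compressions (zero tilt) and a lower
#' bound dominated by the normal-axis compression (high tilt).
#'
#' @param result An `mt_alignment`, or a plain list of maps by `i_omega`.
#' @return Tibble with columns `i_omega`, `n3`.
#' @export
n3_series <- function(result) {
  maps <- if (inherits(result, "mt_alignment")) result$maps else result
  tibble::tibble(
    i_omega = seq_along(maps),
    n3 = vapply(maps, n3, numeric(1))
  )
}

n3_predict <- function(gamma, tau, i_omega, tilt_deg, azimuth_deg,
                       reference = 0) {
  s <- 1 - outer(1 - exp(-i_omega / tau), gamma)
  if (reference > 0) {
    # maps gauged to the state at micrograph `reference` show deformation
    # relative to that dose, not to the pristine specimen
    s_ref <- 1 - gamma * (1 - exp(-reference / tau))
    s <- sweep(s, 2, s_ref, "/")
  }
  th <- tilt_deg * pi / 180; ph <- azimuth_deg * pi / 180
  sqrt((s[, 2] * s[, 3] * sin(th) * cos(ph))^2 +
         (s[, 1] * s[, 3] * sin(th) * sin(ph))^2 +
         (s[, 1] * s[, 2] * cos(th))^2)
}

#' Fit the three-rate compression model to an n3 series
#'
#' Nonlinear least squares of the closed-form n3 prediction under the
#' exponential-saturation compression model (rates `gamma_X`, `gamma_Y`,
#' `gamma_Z` and saturation constant `tau`) against an observed n3 series.
#' Levenberg-Marquardt with box constraints, multi-started over
#' `tau in {0.5, 1, 2, 4} x` series length; asymptotic standard errors come
#' from the numerically differentiated Jacobian at the optimum.  At least
#' two series are needed to separate lateral from normal contributions.
#'
#' @param n3_obs Tibble from [n3_series()] (columns `i_omega`, `n3`), or a
#'   numeric vector ordered by `i_omega`.
#' @param scheme The [tilt_scheme()].
#' @param reference Gauge reference: 0 (default) for ground-truth-style
#'   absolute n3 series, or the `i_omega` of the alignment's pinned map
#'   (see `gauge_i_omega` of [bundle_adjust()]) so that the fitted rates
#'   refer to the pristine specimen even though the aligned maps are
#'   expressed relative to the pin-time deformation state.
#' @param tau_starts Multi-start factors applied to the series length.
#' @return An `mt_deformation_fit`: `estimates` (tibble `term`,
#'   `estimate`, `std.error`), `n3` (tibble `i_omega`, `observed`,
#'   `predicted`), `deviance`, `converged`.
#' @export
fit_deformation <- function(n3_obs, scheme, reference = 0,
                            tau_starts = c(0.5, 1, 2, 4)) {
  if (is.numeric(n3_obs)) {
    n3_obs <- tibble::tibble(i_omega = seq_along(n3_obs), n3 = n3_obs)
  }
  if (scheme$n_series < 2) {
    stop("need >= 2 series to separate lateral from normal compression",
         call. = FALSE)
  }
  mic <- scheme$micrographs[match(n3_obs$i_omega, scheme$micrographs$i_omega), ]
  obs <- n3_obs$n3
  series_len <- length(scheme$tilt_angles)
  resid_fn <- function(p) {
    n3_predict(p[1:3], p[4], n3_obs$i_omega, mic$tilt_deg,
               mic$azimuth_deg, reference) - obs
  }
  best <- NULL
  for (f in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(0.05, 0.05, 0.1, f * series_len),
        fn = resid_fn,
        lower = c(0, 0, 0, 1),
        upper = c(0.9, 0.9, 0.9, 100 * series_len),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("deformation fit failed for all starting values",
                          call. = FALSE)
  p <- best$par
  # asymptotic standard errors from a central-difference Jacobian
  J <- vapply(seq_along(p), function(k) {
    h <- max(1e-6, 1e-6 * abs(p[k]))
    pp <- p; pm <- p; pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(length(obs)))
  dof <- length(obs) - length(p)
  sigma2 <- best$deviance / max(dof, 1)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * sigma2),
                 error = function(e) rep(NA_real_, length(p)))
  pred <- n3_predict(p[1:3], p[4], n3_obs$i_omega, mic$tilt_deg,
                     mic$azimuth_deg, reference)
  structure(
    list(
      estimates = tibble::tibble(
        term = c("gamma_X", "gamma_Y", "gamma_Z", "tau"),
        estimate = p, std.error = se
      ),
      n3 = tibble::tibble(i_omega = n3_obs$i_omega, observed = obs,
                          predicted = pred),
      deviance = best$deviance,
      converged = best$info %in% 1:4,
      scheme = scheme
    ),
    class = "mt_deformation_fit"
  )
}

#' @export
print.mt_deformation_fit <- function(x, ...) {
  cat("<mt_deformation_fit>\n")
  est <- x$estimates
  for (r in seq_len(nrow(est))) {
    cat(sprintf("  %-8s %10.5f  (se %.5f)\n", est$term[r], est$estimate[r],
                est$std.error[r]))
  }
  cat("  deviance:", signif(x$deviance, 4), "over", nrow(x$n3),
      "micrographs\n")
  invisible(x)
}

#' @rdname fit_deformation
#' @param x,object An `mt_deformation_fit`.
#' @param ... Unused.
#' @method tidy mt_deformation_fit
#' @export
tidy.mt_deformation_fit <- function(x, ...) x$estimates

#' @rdname fit_deformation
#' @method glance mt_deformation_fit
#' @export
glance.mt_deformation_fit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance,
    rmse = sqrt(mean((x$n3$observed - x$n3$predicted)^2)),
    n = nrow(x$n3),
    converged = x$converged
  )
}

#' @rdname fit_deformation
#' @method autoplot mt_deformation_fit
#' @export
autoplot.mt_deformation_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$n3, c("observed", "predicted"),
                            names_to = "kind", values_to = "n3")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i_omega, y = .data$n3,
                                   colour = .data$kind)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "micrograph index", y = "n3")
}
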