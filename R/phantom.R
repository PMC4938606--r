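#' Synthetic dynamic lung phantom specification
#'
#' Defines a lung-shaped closed surface undergoing expiration-like motion
#' with analytic ground truth. The reference shape (frame `T`, full
#' expiration) is an ellipsoid truncated below by a raised diaphragm dome
#' (elliptic-cap profile across x, parabolic across y, tilted about the
#' LR axis), with a sphere subtracted on the medial face (cardiac
#' indentation). The dome is strictly concave and steep near its lateral
#' rim (the costophrenic angle), so it lies well inside the convex hull,
#' as a real diaphragm dome does relative to the costal surface.
#'
#' The motion maps reference positions to any earlier time: toward full
#' inspiration the dome descends by `d_max` and its tilt steepens to
#' `theta_start`; during exhalation the tilt relaxes to `theta_end` on a
#' schedule contained strictly inside the 10-90% volume-change window,
#' and after the window closes the dome tilts backward again by
#' `grad_posterior / a_y` (partly transient), so that the posterior
#' diaphragm gains `grad_posterior` mm of maximal cranial excursion (per
#' unit normalised y) over the anterior part without disturbing the dome
#' orientation measured inside the window. The chest wall above the dome
#' contracts by `ap_contraction` in the AP and LR directions.
#'
#' @param half_axes ellipsoid half axes (a_x, a_y, a_z) in mm.
#' @param cut_z cap-plane height of the diaphragm dome base (mm, negative).
#' @param dome_height dome apex height above the cap plane (mm).
#' @param dome_rx,dome_ry dome footprint half widths along x and y (mm):
#'   elliptic-cap profile across x, parabolic across y.
#' @param indent_center,indent_radius medial (cardiac) indentation sphere.
#' @param T number of frames (frame 1 = full inspiration, `T` = reference
#'   full expiration).
#' @param d_max diaphragm cranial displacement amplitude (mm).
#' @param grad_posterior posterior-greater excursion gradient (mm per
#'   normalised y), delivered after the 10-90% volume window as a
#'   permanent tilt return plus a transient tilt bump.
#' @param ap_contraction fractional AP/LR chest expansion at inspiration.
#' @param theta_start,theta_end dome tilt (deg) at inspiration and at the
#'   end of the main exhalation phase.
#' @param spacing voxel spacing for rasterised masks (mm).
#' @param rng_seed integer seed controlling the geometry jitter.
#' @param jitter relative geometry jitter amplitude (0 disables).
#' @param motion_support `"global"` (vertical motion weighted only by a
#'   z-ramp) or `"dome_column"` (vertical motion confined to the dome's
#'   footprint column, leaving the chest wall exactly static; requires
#'   `ap_contraction = 0`).
#' @return A `phantom_spec` object (list of validated parameters plus
#'   derived motion-ramp constants).
#' @export
phantom_spec <- function(half_axes = c(60, 50, 95), cut_z = -60,
                         dome_height = 40, dome_rx = 46, dome_ry = 42,
                         indent_center = c(-57, 10, -5), indent_radius = 28,
                         T = 12L, d_max = 20, grad_posterior = 55,
                         ap_contraction = 0.15, theta_start = 20,
                         theta_end = 5, spacing = 2.8, rng_seed = 1L,
                         jitter = 0,
                         motion_support = c("global", "dome_column")) {
  motion_support <- match.arg(motion_support)
  if (jitter > 0) {
    rng <- local_rng(rng_seed)
    jit <- function(x, frac) x * (1 + frac * (2 * rng$sample(1e6, length(x)) / 1e6 - 1))
    half_axes <- jit(half_axes, jitter)
    dome_height <- jit(dome_height, jitter / 2)
    dome_rx <- jit(dome_rx, jitter)
    indent_center <- indent_center +
      half_axes * 0.05 * jitter * (2 * rng$sample(1e6, 3) / 1e6 - 1)
    indent_radius <- jit(indent_radius, jitter)
  }
  spec <- list(half_axes = half_axes, cut_z = cut_z,
               dome_height = dome_height, dome_rx = dome_rx,
               dome_ry = dome_ry,
               indent_center = indent_center,
               indent_radius = indent_radius, T = as.integer(T),
               d_max = d_max, grad_posterior = grad_posterior,
               ap_contraction = ap_contraction, theta_start = theta_start,
               theta_end = theta_end, spacing = spacing,
               rng_seed = as.integer(rng_seed),
               motion_support = motion_support)
  if (any(half_axes <= 0) || dome_height <= 0 || dome_rx <= 0 ||
      dome_ry <= 0 || indent_radius <= 0 || spacing <= 0)
    stop("all phantom lengths must be positive")
  if (spec$T < 2L) stop("need T >= 2 frames")
  if (motion_support == "dome_column" && ap_contraction > 0)
    stop("dome-column motion support requires ap_contraction = 0")
  if (-cut_z >= half_axes[3L])
    stop("self-intersecting spec: cap plane below the ellipsoid")
  # The dome's y-curvature spreads the triangle normals, so the
  # area-weighted mean dome orientation differs slightly from the plane
  # tilt (the angle mean is a nonlinear transform of the slopes). The
  # plane slopes behind theta_start/theta_end are therefore calibrated
  # numerically so that the area-weighted mean orientation equals the
  # requested angles exactly. The posterior excursion gradient is split
  # into a permanent late tilt return (up to the start-end tilt
  # difference) and a transient late bump carrying the remainder.
  spec$tan_geo <- tanpi(theta_start / 180)
  cal <- function(theta) tryCatch(phantom_calibrate_tilt(spec, theta),
    error = function(e) stop("self-intersecting spec: dome tilt ",
                             "calibration failed (dome too extreme)",
                             call. = FALSE))
  for (pass in 1:2) {
    spec$tan_start_cal <- cal(theta_start)
    spec$tan_end_cal <- cal(theta_end)
    dcc <- spec$tan_start_cal - spec$tan_end_cal
    gtot <- grad_posterior / half_axes[2L]
    spec$rho <- if (dcc > 0) min(1, gtot / dcc) else 0
    spec$gamma_bump <- max(0, gtot - spec$rho * dcc)
    spec$tan_geo <- spec$tan_end_cal + spec$rho * dcc
  }
  dome_top <- phantom_dome_top(spec)
  if (dome_top >= -8)
    stop("self-intersecting spec: dome apex reaches the equator")
  spec$dome_top <- dome_top
  spec$w_ramp <- c(dome_top + 2, dome_top + 60)
  spec$q_ramp <- c(dome_top + 3, -2)
  if (diff(spec$q_ramp) < 4)
    stop("dome too tall for the chest-contraction ramp")
  amp_max <- phantom_max_amplitude(spec)
  if (amp_max * pi / (2 * diff(spec$w_ramp)) >= 0.95)
    stop("self-intersecting spec: dome displacement too large for the ",
         "lung height")
  spec$amp_max <- amp_max
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> half axes %s mm, dome %g mm, ",
                     "d_max %g mm, AP contraction %g%%, tilt %g->%g deg, ",
                     "posterior gradient %g mm, T = %d\n"),
              paste(round(x$half_axes, 1), collapse = "x"), round(x$dome_height, 1),
              x$d_max, 100 * x$ap_contraction, x$theta_start, x$theta_end,
              x$grad_posterior, x$T))
  invisible(x)
}

# worst-case |vertical displacement| over the dome footprint at full
# inspiration (the largest excursion from the reference frame)
phantom_max_amplitude <- function(spec) {
  a <- spec$half_axes
  ts <- seq(1, spec$T, length.out = 60)
  m <- 0
  for (t in ts) {
    sc <- phantom_schedules(spec, t)
    m <- max(m, abs(phantom_dome_dz(spec, sc, c(-a[2L], a[2L]))))
  }
  m
}

# dome quadrature shared by tilt calibration and the truth integrals:
# grid points on the active dome footprint outside the 2 mm boundary
# band, with reference-frame area weights
phantom_dome_quadrature <- function(spec, grid_mm = 1) {
  a <- spec$half_axes
  gr <- as.matrix(expand.grid(x = seq(-a[1L], a[1L], by = grid_mm),
                              y = seq(-a[2L], a[2L], by = grid_mm)))
  act <- phantom_dome_active(spec, gr[, 1L], gr[, 2L])
  dx <- gr[act, 1L]; dy <- gr[act, 2L]
  band <- truth_boundary_band(spec, cbind(dx, dy,
                                          phantom_dome_z(spec, dx, dy)))
  dx <- dx[!band]; dy <- dy[!band]
  gB <- phantom_dome_grad(spec, dx, dy)
  list(x = dx, y = dy, Bx = gB[, 1L], By = gB[, 2L],
       area = sqrt(1 + gB[, 1L]^2 + gB[, 2L]^2) * grid_mm^2)
}

# solve for the plane slope whose area-weighted mean dome orientation
# equals the requested angle (the dome y-curvature biases the mean);
# uses the same quadrature and reference-area weights as phantom_truth
phantom_calibrate_tilt <- function(spec, theta_deg) {
  q <- phantom_dome_quadrature(spec, grid_mm = 1)
  u <- -(q$By + spec$tan_geo)          # shape slope without the tilt plane
  mean_angle <- function(c)
    sum(atan(c + u) * q$area) / sum(q$area) * 180 / pi
  stats::uniroot(function(c) mean_angle(c) - theta_deg,
                 interval = tanpi(c(theta_deg - 15, theta_deg + 15) / 180),
                 tol = 1e-10)$root
}

# numeric max of the reference dome height over its footprint
phantom_dome_top <- function(spec) {
  g <- as.matrix(expand.grid(x = seq(-spec$half_axes[1L], spec$half_axes[1L],
                                     length.out = 81),
                             y = seq(-spec$half_axes[2L], spec$half_axes[2L],
                                     length.out = 81)))
  B <- phantom_dome_z(spec, g[, 1L], g[, 2L])
  zl <- phantom_shell_lower(spec, g[, 1L], g[, 2L])
  act <- !is.na(zl) & B > zl
  max(B[act])
}

# reference (frame T) dome surface height z = B(x, y): elliptic-cap
# profile across x (steep near the lateral rim, like the costophrenic
# angle), parabolic across y, plus the tilt plane
phantom_dome_z <- function(spec, x, y) {
  Sx <- sqrt(pmax(0, 1 - (x / spec$dome_rx)^2))
  gy <- pmax(0, 1 - (y / spec$dome_ry)^2)
  spec$cut_z + spec$dome_height * Sx * gy - spec$tan_geo * y
}

# analytic dome surface gradient (Bx, By)
phantom_dome_grad <- function(spec, x, y) {
  x2 <- (x / spec$dome_rx)^2
  Sx <- sqrt(pmax(0, 1 - x2))
  gy <- pmax(0, 1 - (y / spec$dome_ry)^2)
  Bx <- ifelse(x2 < 1,
               -spec$dome_height * x * gy / (spec$dome_rx^2 * pmax(Sx, 0.1)),
               0)
  By <- ifelse(abs(y) < spec$dome_ry,
               -2 * spec$dome_height * Sx * y / spec$dome_ry^2, 0) -
    spec$tan_geo
  cbind(Bx = Bx, By = By)
}

# lower ellipsoid shell height (NA outside the footprint)
phantom_shell_lower <- function(spec, x, y) {
  a <- spec$half_axes
  r2 <- 1 - (x / a[1L])^2 - (y / a[2L])^2
  out <- rep(NA_real_, length(x))
  ok <- r2 > 0
  out[ok] <- -a[3L] * sqrt(r2[ok])
  out
}

# is (x, y) inside the diaphragm-dome footprint (dome above lower shell)?
phantom_dome_active <- function(spec, x, y) {
  zl <- phantom_shell_lower(spec, x, y)
  B <- phantom_dome_z(spec, x, y)
  !is.na(zl) & B > zl & B < 0
}

# time schedules ------------------------------------------------------------

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Time schedules of the maneuver. `p` is the main motion progress (dome
# descent and chest contraction): it reaches 90% early and completes in
# the final phase, so the 10-90% volume window closes before the late
# posterior-tilt events. The effective dome tilt starts at the calibrated
# inspiration slope, relaxes to the calibrated end slope strictly inside
# the window, then returns toward the reference slope (the permanent part
# of the posterior gradient) with a transient extra backward-tilt bump
# peaking at frame T-1 (the remainder of the gradient); the per-point
# maximum excursion of posterior diaphragm points is attained on this
# bump, realising the posterior-greater excursion without disturbing the
# orientation measured inside the window.
phantom_schedules <- function(spec, t) {
  s <- (t - 1) / (spec$T - 1)
  p <- 0.9 * smoothstep(s / 0.75) + 0.1 * smoothstep((s - 0.8) / 0.2)
  tau <- smoothstep((s - 0.2) / 0.4)
  lt <- smoothstep((s - 0.82) / 0.18)
  bump <- sin(pi * pmin(pmax((s - 0.82) / 0.18, 0), 1))^2
  tT <- spec$tan_end_cal
  t1 <- spec$tan_start_cal
  tan_eff <- t1 + (tT - t1) * tau + spec$rho * (t1 - tT) * lt +
    spec$gamma_bump * bump
  list(s = s, p = p, tau = tau, lt = lt, bump = bump, tan_eff = tan_eff,
       lambda0 = 1 + spec$ap_contraction * (1 - p))
}

# vertical-motion and contraction weights as functions of reference z
phantom_w <- function(spec, z) {
  r <- spec$w_ramp
  u <- (r[2L] - z) / (r[2L] - r[1L])
  ifelse(z <= r[1L], 1,
         ifelse(z >= r[2L], 0, sin(pmin(pmax(u, 0), 1) * pi / 2)^2))
}

phantom_q <- function(spec, z) {
  r <- spec$q_ramp
  smoothstep((z - r[1L]) / (r[2L] - r[1L]))
}

# horizontal support of the vertical motion: 1 everywhere for the global
# field; for dome-column support, 1 over the dome footprint decaying to 0
# just outside it, so the chest wall is exactly static
phantom_S <- function(spec, x, y) {
  if (spec$motion_support == "global") return(rep(1, length(x)))
  rf <- sqrt((x / spec$dome_rx)^2 + (y / spec$dome_ry)^2)
  s <- smoothstep((1.03 - rf) / 0.03)
  # only where the dome stands clear of the shell: the anterior-inferior
  # shell under the tilted dome plane must stay static
  zl <- phantom_shell_lower(spec, x, y)
  clear <- phantom_dome_z(spec, x, y) - zl
  act <- ifelse(is.na(zl), 1, smoothstep(clear / 6))
  s * act
}

# vertical displacement of a dome point (w = 1) at schedule sc
phantom_dome_dz <- function(spec, sc, y) {
  -(1 - sc$p) * spec$d_max - (sc$tan_eff - spec$tan_geo) * y
}

# vertical displacement of reference point (x, y, z) at schedule sc
phantom_dz <- function(spec, sc, x, y, z) {
  phantom_w(spec, z) * phantom_S(spec, x, y) * phantom_dome_dz(spec, sc, y)
}

#' Analytic phantom displacement provider
#'
#' Returns the function mapping reference (frame `T`) positions to their
#' positions at any time `t` (identity at `t = T`); the provider plays the
#' role that a groupwise-registration deformation field plays for real
#' data.
#'
#' @param spec a [phantom_spec()].
#' @return function `(points, t) -> points` (N x 3 matrices, mm).
#' @export
phantom_displacement <- function(spec) {
  force(spec)
  function(points, t) {
    sc <- phantom_schedules(spec, t)
    x <- points[, 1L]; y <- points[, 2L]; z <- points[, 3L]
    lam <- 1 + (sc$lambda0 - 1) * phantom_q(spec, z)
    cbind(x * lam, y * lam, z + phantom_dz(spec, sc, x, y, z))
  }
}

# reference-solid membership test (frame T)
phantom_inside_ref <- function(spec, pts) {
  a <- spec$half_axes
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  inside <- (x / a[1L])^2 + (y / a[2L])^2 + (z / a[3L])^2 <= 1
  inside <- inside & z >= phantom_dome_z(spec, x, y)
  d2 <- (x - spec$indent_center[1L])^2 + (y - spec$indent_center[2L])^2 +
    (z - spec$indent_center[3L])^2
  inside & d2 >= spec$indent_radius^2
}

# membership at frame t by fixed-point inversion of the forward map
phantom_inside_at <- function(spec, pts, t, iters = 30L) {
  sc <- phantom_schedules(spec, t)
  xp <- pts[, 1L]; yp <- pts[, 2L]; zp <- pts[, 3L]
  z <- zp
  for (i in seq_len(iters)) {
    lam <- 1 + (sc$lambda0 - 1) * phantom_q(spec, z)
    y <- yp / lam
    z <- zp - phantom_dz(spec, sc, xp / lam, y, z)
  }
  lam <- 1 + (sc$lambda0 - 1) * phantom_q(spec, z)
  phantom_inside_ref(spec, cbind(xp / lam, yp / lam, z))
}

#' Generate the dynamic phantom
#'
#' Rasterises the phantom at the spec's voxel spacing for the requested
#' frames, and returns the analytic displacement provider plus ground
#' truth (analytic volumes, dome integrals and the label oracle).
#'
#' @param spec a [phantom_spec()].
#' @param mask_frames which frames to rasterise (default all `1..T`; the
#'   reference frame `T` is always included).
#' @param truth compute [phantom_truth()] (set `FALSE` to skip the
#'   volume integrals when only masks are needed).
#' @return list with `masks` (a [dynamic_sequence()] when all frames are
#'   rasterised, else a named list of [binary_mask()]), `reference_mask`,
#'   `field` (displacement provider), `truth`, and `spec`.
#' @export
generate_phantom <- function(spec, mask_frames = seq_len(spec$T),
                             truth = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask_frames <- sort(unique(c(as.integer(mask_frames), spec$T)))
  a <- spec$half_axes; h <- spec$spacing
  lam_max <- 1 + spec$ap_contraction
  lo <- c(-a[1L] * lam_max - 2 * h, -a[2L] * lam_max - 2 * h,
          spec$cut_z - spec$amp_max - 2 * h)
  hi <- c(a[1L] * lam_max + 2 * h, a[2L] * lam_max + 2 * h, a[3L] + 2 * h)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / h)))
  origin <- lo + h / 2
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * h)
  pts <- cbind(rep(ax[[1L]], times = dims[2L] * dims[3L]),
               rep(rep(ax[[2L]], each = dims[1L]), times = dims[3L]),
               rep(ax[[3L]], each = dims[1L] * dims[2L]))
  masks <- list()
  for (t in mask_frames) {
    inside <- if (t == spec$T) phantom_inside_ref(spec, pts) else
      phantom_inside_at(spec, pts, t)
    masks[[as.character(t)]] <- binary_mask(array(as.integer(inside), dims),
                                            spacing = rep(h, 3),
                                            origin = origin)
  }
  seq_out <- if (length(mask_frames) == spec$T)
    dynamic_sequence(unname(masks)) else masks
  list(masks = seq_out, reference_mask = masks[[as.character(spec$T)]],
       field = phantom_displacement(spec),
       truth = if (truth) phantom_truth(spec) else NULL, spec = spec)
}

#' Analytic ground truth of a phantom
#'
#' Numeric integrals over the closed-form phantom surfaces: per-frame
#' volumes `V(t)` (Jacobian-weighted reference-grid integration),
#' dome-region excursion and orientation integrals (2 mm boundary band
#' excluded, as in label scoring), and per-step swept volumes of the
#' diaphragmatic surface.
#'
#' @param spec a [phantom_spec()].
#' @param grid_mm dome-integration grid step (mm).
#' @param volume_grid_mm volume-integration grid step (mm).
#' @return list with `V_t_mm3`, `A4_mm`, `A5_mm`, `A6_deg`, `A7_deg`,
#'   `t_start`, `t_end`, `orientation_deg`, `dV_D_t_mm3`, `CC_mm`,
#'   `AP_mm` and the anterior/posterior mean excursions.
#' @export
phantom_truth <- function(spec, grid_mm = 1, volume_grid_mm = 1.5) {
  a <- spec$half_axes
  # ---- dome integrals (dome carries w = 1, lambda = 1) --------------------
  q <- phantom_dome_quadrature(spec, grid_mm)
  dx <- q$x; dy <- q$y; area <- q$area
  gB <- cbind(q$Bx, q$By)
  # per-point cranial excursion relative to full inspiration, maximised
  # over frames (anterior points peak before the late posterior tilt)
  Sq <- phantom_S(spec, dx, dy)
  zs0 <- sapply(seq_len(spec$T), function(t)
    Sq * phantom_dome_dz(spec, phantom_schedules(spec, t), dy))
  e_max <- apply((zs0 - zs0[, 1L])[, -1L, drop = FALSE], 1L, max)
  A4 <- sum(e_max * area) / sum(area)
  ant <- dy >= 0
  amean <- sum(e_max[ant] * area[ant]) / sum(area[ant])
  pmean <- sum(e_max[!ant] * area[!ant]) / sum(area[!ant])
  A5 <- pmean - amean
  # orientation(t): area-weighted mean angle over the deformed dome,
  # with reference-frame area weights
  u_y <- -(q$By + spec$tan_geo)        # shape slope without the tilt plane
  orient <- vapply(seq_len(spec$T), function(t) {
    sc <- phantom_schedules(spec, t)
    sum(atan(sc$tan_eff + u_y) * area) / sum(area) * 180 / pi
  }, numeric(1))
  # per-step dome flux (projected area; the motion is vertical)
  zs <- sapply(seq_len(spec$T), function(t)
    Sq * phantom_dome_dz(spec, phantom_schedules(spec, t), dy))
  dV_D_t <- vapply(seq_len(spec$T - 1L), function(t)
    sum((zs[, t + 1L] - zs[, t]) * grid_mm^2), numeric(1))
  # ---- per-frame volumes via Jacobian integration -------------------------
  hb <- volume_grid_mm
  pts <- as.matrix(expand.grid(x = seq(-a[1L], a[1L], by = hb),
                               y = seq(-a[2L], a[2L], by = hb),
                               z = seq(spec$cut_z - spec$dome_height - 1,
                                       a[3L], by = hb)))
  ref <- pts[phantom_inside_ref(spec, pts), , drop = FALSE]
  fld <- phantom_displacement(spec)
  d <- 0.25
  V_t <- vapply(seq_len(spec$T), function(t) {
    J <- lapply(1:3, function(axis) {
      e <- c(0, 0, 0); e[axis] <- d
      off <- matrix(e, nrow(ref), 3L, byrow = TRUE)
      (fld(ref + off, t) - fld(ref - off, t)) / (2 * d)
    })
    det <- J[[1L]][, 1L] * (J[[2L]][, 2L] * J[[3L]][, 3L] -
                              J[[2L]][, 3L] * J[[3L]][, 2L]) -
      J[[2L]][, 1L] * (J[[1L]][, 2L] * J[[3L]][, 3L] -
                         J[[1L]][, 3L] * J[[3L]][, 2L]) +
      J[[3L]][, 1L] * (J[[1L]][, 2L] * J[[2L]][, 3L] -
                         J[[1L]][, 3L] * J[[2L]][, 2L])
    sum(det) * hb^3
  }, numeric(1))
  # A7: signed extremum of orientation change inside the 10-90% window
  dV <- abs(V_t - V_t[1L])
  if (max(dV) <= 0) {
    t_start <- 1L; t_end <- spec$T; A7 <- 0
  } else {
    cum <- dV / max(dV)
    t_start <- which(cum >= 0.1)[1L]
    t_end <- which(cum >= 0.9)[1L]
    diffs <- orient[t_start:t_end] - orient[t_start]
    A7 <- diffs[which.max(abs(diffs))]
  }
  # CC(t), AP(t) from the analytic surfaces
  all_y <- dy
  Ball <- phantom_dome_z(spec, dx, dy)
  CC <- AP <- numeric(spec$T)
  for (t in seq_len(spec$T)) {
    sc <- phantom_schedules(spec, t)
    zt <- Ball + phantom_S(spec, dx, dy) * phantom_dome_dz(spec, sc, all_y)
    CC[t] <- a[3L] - max(zt)
    AP[t] <- 2 * a[2L] * sc$lambda0
  }
  list(V_t_mm3 = V_t, A4_mm = A4, A5_mm = A5,
       anterior_mean_mm = amean, posterior_mean_mm = pmean,
       A6_deg = orient[1L], A7_deg = A7, t_start = t_start, t_end = t_end,
       orientation_deg = orient, dV_D_t_mm3 = dV_D_t, CC_mm = CC, AP_mm = AP)
}

#' Analytic surface labels of the phantom
#'
#' Classifies surface points by their nearest analytic primitive:
#' diaphragmatic (dome), medial (indentation sphere) or costal (ellipsoid
#' shell). Points within `band_mm` of a second primitive lie on a region
#' border and are flagged `boundary = TRUE`; they are excluded from
#' agreement scoring.
#'
#' @param spec a [phantom_spec()].
#' @param points N x 3 surface points (mm, reference frame).
#' @param band_mm boundary band half width (mm).
#' @param tol_mm maximum allowed distance from the analytic surface
#'   (`Inf` to skip the check).
#' @return data.frame with `label` and `boundary`.
#' @export
truth_labels <- function(spec, points, band_mm = 2, tol_mm = Inf) {
  d <- truth_distances(spec, points)
  lab <- c("costal", "diaphragmatic", "medial")[apply(abs(d), 1L, which.min)]
  if (is.finite(tol_mm)) {
    best <- apply(abs(d), 1L, min)
    if (any(best > tol_mm))
      stop("point(s) further than tol_mm from the analytic surface")
  }
  second <- apply(abs(d), 1L, function(r) sort(r)[2L])
  data.frame(label = lab, boundary = second < band_mm)
}

truth_boundary_band <- function(spec, points, band_mm = 2) {
  d <- truth_distances(spec, points)
  apply(abs(d), 1L, function(r) sort(r)[2L]) < band_mm
}

# approximate signed distances to (shell, dome, indent sphere)
truth_distances <- function(spec, points) {
  a <- spec$half_axes
  x <- points[, 1L]; y <- points[, 2L]; z <- points[, 3L]
  f <- sqrt((x / a[1L])^2 + (y / a[2L])^2 + (z / a[3L])^2)
  gn <- sqrt((x / a[1L]^2)^2 + (y / a[2L]^2)^2 + (z / a[3L]^2)^2)
  d_shell <- (f - 1) * f / pmax(gn, 1e-12)
  gB <- phantom_dome_grad(spec, x, y)
  d_dome <- (z - phantom_dome_z(spec, x, y)) /
    sqrt(1 + gB[, 1L]^2 + gB[, 2L]^2)
  d_ind <- sqrt((x - spec$indent_center[1L])^2 +
                  (y - spec$indent_center[2L])^2 +
                  (z - spec$indent_center[3L])^2) - spec$indent_radius
  cbind(shell = d_shell, dome = d_dome, indent = d_ind)
}

#' Stock phantom specifications
#'
#' `"control"`: large dome excursion, posterior-greater excursion
#' gradient, backwards-tilted dome at inspiration flattening during
#' exhalation. `"patient"`: minimal dome excursion, AP-dominated
#' contraction, nearly flat dome, anterior-greater excursion.
#' `"diaphragm_only"` freezes the chest wall; `"chest_only"` freezes the
#' diaphragm.
#'
#' @param type stock spec name.
#' @param rng_seed geometry-jitter seed.
#' @param jitter relative geometry jitter (default 4%).
#' @param ... overrides passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
stock_phantom <- function(type = c("control", "patient", "diaphragm_only",
                                   "chest_only"),
                          rng_seed = 1L, jitter = 0.04, ...) {
  type <- match.arg(type)
  args <- switch(type,
    control = list(),
    patient = list(d_max = 2, grad_posterior = 0, theta_start = 5,
                   theta_end = 3),
    diaphragm_only = list(ap_contraction = 0,
                          motion_support = "dome_column"),
    chest_only = list(d_max = 0, grad_posterior = 0, theta_start = 5,
                      theta_end = 5))
  args$rng_seed <- rng_seed
  args$jitter <- jitter
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}
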