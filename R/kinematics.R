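#' Tracked mesh: one connectivity, T vertex-position snapshots
#'
#' Realizes a 3D+t lung segmentation in which surface points are directly
#' traceable through the maneuver. Frame `T` (full expiration) is the
#' reference whose connectivity all frames share.
#'
#' @param mesh reference [surface_mesh()] (frame `T` positions).
#' @param positions list of `T` vertex matrices (N x 3), element `T`
#'   equal to `mesh$vertices`.
#' @return A `tracked_mesh` object.
#' @export
tracked_mesh <- function(mesh, positions) {
  Tn <- length(positions)
  if (Tn < 2L) stop("need at least 2 time points")
  nv <- nrow(mesh$vertices)
  for (t in seq_len(Tn)) {
    if (!identical(dim(positions[[t]]), as.integer(c(nv, 3L))) &&
        !identical(dim(positions[[t]]), c(nv, 3L)))
      stop("frame ", t, " has wrong vertex-matrix shape")
  }
  vols <- vapply(positions, function(p) mesh_volume(mesh, p), numeric(1))
  flipped <- which(vols <= 0)
  if (length(flipped) > 0L)
    warning("non-positive signed volume at frame(s) ",
            paste(flipped, collapse = ", "))
  structure(list(mesh = mesh, positions = positions, T = Tn,
                 flipped = flipped), class = "tracked_mesh")
}

#' @export
print.tracked_mesh <- function(x, ...) {
  cat(sprintf("<tracked_mesh> %d vertices, %d triangles, %d frames\n",
              nrow(x$mesh$vertices), nrow(x$mesh$triangles), x$T))
  invisible(x)
}

#' Propagate a reference mesh through a displacement field
#'
#' Applies a displacement provider mapping reference (full-expiration,
#' frame `T`) positions to each time point; connectivity is unchanged.
#' The provider must be the identity at `t = T`.
#'
#' @param reference a [surface_mesh()] at frame `T`.
#' @param field function `(points, t) -> points` returning the N x 3
#'   positions at time `t` of reference points (e.g. the inverse+forward
#'   concatenation of a groupwise registration, or
#'   [phantom_displacement()]).
#' @param T number of time points.
#' @return A [tracked_mesh()].
#' @export
propagate_mesh <- function(reference, field, T) {
  T <- as.integer(T)
  if (T < 2L) stop("need T >= 2")
  pos <- lapply(seq_len(T), function(t) {
    p <- field(reference$vertices, t)
    if (!is.matrix(p) || !identical(dim(p), dim(reference$vertices)))
      stop("field returned wrong shape at t = ", t)
    if (any(!is.finite(p)))
      stop("vertex outside field domain at t = ", t)
    p
  })
  if (max(abs(pos[[T]] - reference$vertices)) > 1e-6)
    warning("field is not the identity at the reference frame t = T")
  tracked_mesh(reference, pos)
}

#' Basic geometry features B1-B6 and time curves
#'
#' Computes per-frame lung volume `V(t)`, cranio-caudal size
#' `CC(t) = z(lung apex) - z(diaphragm apex)` (both apexes recomputed per
#' frame; the diaphragm apex is the most cranial vertex of the
#' diaphragmatic surface) and antero-posterior size
#' `AP(t) = max y - min y`, and derives: B1 residual volume `V(T)`,
#' B2 vital capacity `V(1) - V(T)`, B3 `V(1)/V(T)`, B4 `CC(1)/CC(T)`,
#' B5 `AP(1)/AP(T)`, B6 `B4/B5`.
#'
#' @param tracked a [tracked_mesh()].
#' @param partition a `surface_partition` on the same connectivity (or any
#'   list with element `D` of diaphragmatic triangle indices).
#' @return list with `features` (named list B1..B6, volumes in L) and
#'   `curves` (data.frame t, V_L, CC_mm, AP_mm).
#' @export
basic_features <- function(tracked, partition) {
  Tn <- tracked$T
  tr <- tracked$mesh$triangles
  D <- partition$D
  if (length(D) == 0L) warning("empty diaphragmatic region: CC undefined")
  dia_verts <- unique(as.vector(tr[D, , drop = FALSE]))
  V <- vapply(tracked$positions, function(p) mesh_volume(tracked$mesh, p),
              numeric(1))
  CC <- vapply(tracked$positions, function(p) {
    if (length(dia_verts) == 0L) return(NA_real_)
    max(p[, 3L]) - max(p[dia_verts, 3L])
  }, numeric(1))
  AP <- vapply(tracked$positions, function(p) max(p[, 2L]) - min(p[, 2L]),
               numeric(1))
  feats <- list(B1 = V[Tn] / 1e6, B2 = (V[1L] - V[Tn]) / 1e6,
                B3 = V[1L] / V[Tn], B4 = CC[1L] / CC[Tn],
                B5 = AP[1L] / AP[Tn])
  feats$B6 <- feats$B4 / feats$B5
  list(features = feats,
       curves = data.frame(t = seq_len(Tn), V_L = V / 1e6, CC_mm = CC,
                           AP_mm = AP))
}

#' Swept volume of one triangle between two frames
#'
#' Signed volume of the closed polyhedron joining a triangle's vertices at
#' consecutive frames (two caps and three side quads, each quad split
#' along the diagonal anchored at its lower vertex index so that side
#' contributions cancel exactly between edge-sharing triangles). Sign
#' convention: positive when the triangle moves against its outward
#' normal (inward motion; positive during exhalation), so that summing
#' over a closed surface yields `V(t) - V(t+1)` exactly.
#'
#' @param p0,p1 N x 3 vertex matrices at frames `t` and `t+1`.
#' @param triangles M x 3 triangle matrix (subset allowed).
#' @return numeric vector of signed swept volumes (mm^3) per triangle.
#' @export
swept_volumes <- function(p0, p1, triangles) {
  tr <- triangles
  m <- nrow(tr)
  tot <- numeric(m)
  det6 <- function(a, b, c) rowSums(a * cross3(b, c))
  # caps: frame t with reversed winding, frame t+1 with original winding
  a0 <- p0[tr[, 1L], , drop = FALSE]
  b0 <- p0[tr[, 2L], , drop = FALSE]
  c0 <- p0[tr[, 3L], , drop = FALSE]
  a1 <- p1[tr[, 1L], , drop = FALSE]
  b1 <- p1[tr[, 2L], , drop = FALSE]
  c1 <- p1[tr[, 3L], , drop = FALSE]
  tot <- det6(a0, c0, b0) + det6(a1, b1, c1)
  # sides: for edge (u, v) quad (u0, v0, v1, u1), diagonal from min(u,v)
  for (e in 1:3) {
    u <- tr[, e]; v <- tr[, e %% 3L + 1L]
    u0 <- p0[u, , drop = FALSE]; v0 <- p0[v, , drop = FALSE]
    u1 <- p1[u, , drop = FALSE]; v1 <- p1[v, , drop = FALSE]
    lo <- u < v
    # quad as seen by this triangle: u0 -> v0 -> v1 -> u1; the diagonal is
    # anchored at the lower vertex index, independent of traversal
    # direction, so contributions cancel exactly across shared edges
    # if u < v: diagonal (u0, v1): triangles (u0, v0, v1), (u0, v1, u1)
    # else:     diagonal (v0, u1): triangles (v0, v1, u1), (v0, u1, u0)
    s1 <- numeric(m); s2 <- numeric(m)
    if (any(lo)) {
      s1[lo] <- det6(u0[lo, , drop = FALSE], v0[lo, , drop = FALSE],
                     v1[lo, , drop = FALSE])
      s2[lo] <- det6(u0[lo, , drop = FALSE], v1[lo, , drop = FALSE],
                     u1[lo, , drop = FALSE])
    }
    if (any(!lo)) {
      s1[!lo] <- det6(v0[!lo, , drop = FALSE], v1[!lo, , drop = FALSE],
                      u1[!lo, , drop = FALSE])
      s2[!lo] <- det6(v0[!lo, , drop = FALSE], u1[!lo, , drop = FALSE],
                      u0[!lo, , drop = FALSE])
    }
    tot <- tot + s1 + s2
  }
  # det6/6 gives the outward-oriented polyhedron volume whose sign is
  # positive for motion along +normal; flip for exhalation-positive
  -tot / 6
}

#' Region-wise swept-volume features A1-A3
#'
#' Erodes the diaphragmatic (`D`) and costal (`C`) regions by two triangle
#' strips (to avoid unreliable boundary measurements), then accumulates
#' per-step swept volumes: `dV_D(t)` and `dV_C(t)` for each step
#' `t -> t+1`, A1 = total diaphragm-displaced volume, A2 = total
#' costal-displaced volume, A3 = A1 / (A1 + A2). RV-normalised variants
#' (divided by B1) are also returned.
#'
#' @param tracked a [tracked_mesh()].
#' @param partition `surface_partition` (elements `D`, `C`).
#' @param erode_strips boundary strips to remove before accumulation.
#' @return list with `A1_L`, `A2_L`, `A3`, `A1_over_RV`, `A2_over_RV`,
#'   and per-step `dV_D_L`, `dV_C_L`.
#' @export
swept_volume_features <- function(tracked, partition, erode_strips = 2L) {
  adj <- partition$adjacency
  if (is.null(adj)) adj <- triangle_adjacency(tracked$mesh)
  D <- erode_region(partition$D, adj, erode_strips)
  C <- erode_region(partition$C, adj, erode_strips)
  tr <- tracked$mesh$triangles
  Tn <- tracked$T
  dV_D <- numeric(Tn - 1L); dV_C <- numeric(Tn - 1L)
  for (t in seq_len(Tn - 1L)) {
    p0 <- tracked$positions[[t]]; p1 <- tracked$positions[[t + 1L]]
    if (length(D) > 0L)
      dV_D[t] <- sum(swept_volumes(p0, p1, tr[D, , drop = FALSE]))
    if (length(C) > 0L)
      dV_C[t] <- sum(swept_volumes(p0, p1, tr[C, , drop = FALSE]))
  }
  A1 <- sum(dV_D); A2 <- sum(dV_C)
  RV <- mesh_volume(tracked$mesh, tracked$positions[[Tn]])
  list(A1_L = A1 / 1e6, A2_L = A2 / 1e6, A3 = A1 / (A1 + A2),
       A1_over_RV = A1 / RV, A2_over_RV = A2 / RV,
       dV_D_L = dV_D / 1e6, dV_C_L = dV_C / 1e6,
       D_eroded = D, C_eroded = C)
}

#' Diaphragm excursion features A4-A5
#'
#' Per diaphragmatic triangle, the cranio-caudal displacement of its
#' centroid relative to full inspiration (`z(t) - z(1)`, cranial
#' positive) is maximised over the frames after full inspiration, so
#' purely caudal (paradoxical) motion yields a negative excursion. A4 is the area-weighted mean over
#' the diaphragmatic surface (weights: reference-frame triangle areas).
#' For A5 the diaphragm is split into anterior and posterior halves by
#' the mid-coronal plane of the lung's reference (full-expiration)
#' bounding box; A5 is the posterior minus the anterior area-weighted
#' mean excursion in mm (computed for the right lung; the left
#' hemidiaphragm is largely obscured by the heart). Both half means are
#' also returned so a ratio can be formed.
#'
#' @param tracked a [tracked_mesh()].
#' @param partition `surface_partition` (element `D`).
#' @param lung `"right"` or `"left"`; A5 is `NA` for the left lung.
#' @return list with `A4_mm`, `A5_mm`, `anterior_mean_mm`,
#'   `posterior_mean_mm`, and the per-triangle `max_cc_mm` map (named by
#'   triangle index).
#' @export
diaphragm_excursion <- function(tracked, partition, lung = c("right", "left")) {
  lung <- match.arg(lung)
  D <- partition$D
  if (length(D) == 0L) stop("empty diaphragmatic region")
  tr <- tracked$mesh$triangles[D, , drop = FALSE]
  cent_z <- function(p) (p[tr[, 1L], 3L] + p[tr[, 2L], 3L] + p[tr[, 3L], 3L]) / 3
  z1 <- cent_z(tracked$positions[[1L]])
  disp <- sapply(tracked$positions[-1L], function(p) cent_z(p) - z1)
  max_cc <- apply(disp, 1L, max)
  areas <- triangle_areas(tracked$mesh)[D]
  A4 <- sum(max_cc * areas) / sum(areas)
  # anterior/posterior split at the mid-coronal plane of the reference box
  y_mid <- mean(range(tracked$mesh$vertices[, 2L]))
  cy <- triangle_centroids(tracked$mesh)[D, 2L]
  ant <- cy >= y_mid
  amean <- if (any(ant)) sum(max_cc[ant] * areas[ant]) / sum(areas[ant]) else NA_real_
  pmean <- if (any(!ant)) sum(max_cc[!ant] * areas[!ant]) / sum(areas[!ant]) else NA_real_
  A5 <- if (lung == "right") pmean - amean else NA_real_
  out <- list(A4_mm = A4, A5_mm = A5, anterior_mean_mm = amean,
              posterior_mean_mm = pmean,
              max_cc_mm = stats::setNames(max_cc, D))
  out
}

#' Diaphragm dome orientation features A6-A7
#'
#' Per frame, each diaphragmatic triangle normal is projected onto the
#' sagittal (y-z) plane and the signed angle to the caudal axis (-z) is
#' computed, positive when the normal tilts posteriorly (a dome tilted
#' backwards at full inspiration gives a positive angle). The
#' area-weighted mean over the dome gives the orientation curve. A6 is
#' the orientation at full inspiration (t = 1); A7 the signed extremum of
#' `orientation(t) - orientation(t_start)` for t in the motion window,
#' where start/end of motion are the first times 10% and 90% of the total
#' volume change are reached.
#'
#' @param tracked a [tracked_mesh()].
#' @param partition `surface_partition` (element `D`, right lung).
#' @return list with `A6_deg`, `A7_deg`, `t_start`, `t_end`, and the
#'   `orientation_deg` curve.
#' @export
diaphragm_orientation <- function(tracked, partition) {
  D <- partition$D
  if (length(D) == 0L) stop("empty diaphragmatic region")
  tr <- tracked$mesh$triangles
  areas <- triangle_areas(tracked$mesh)[D]
  orient <- vapply(tracked$positions, function(p) {
    n <- triangle_normals(surface_mesh(p, tr[D, , drop = FALSE],
                                       validate = FALSE))
    ang <- atan2(-n[, 2L], -n[, 3L]) * 180 / pi
    sum(ang * areas) / sum(areas)
  }, numeric(1))
  V <- vapply(tracked$positions, function(p) mesh_volume(tracked$mesh, p),
              numeric(1))
  dV <- abs(V - V[1L])
  total <- dV[length(dV)]
  if (total <= 0) {
    return(list(A6_deg = orient[1L], A7_deg = 0, t_start = 1L,
                t_end = tracked$T, orientation_deg = orient))
  }
  cum <- dV / max(dV)
  if (any(diff(dV) < -1e-9 * max(dV)))
    cum <- cummax(dV) / max(dV)       # non-monotone V(t): first crossings
  t_start <- which(cum >= 0.1)[1L]
  t_end <- which(cum >= 0.9)[1L]
  win <- t_start:t_end
  diffs <- orient[win] - orient[t_start]
  A7 <- diffs[which.max(abs(diffs))]
  list(A6_deg = orient[1L], A7_deg = A7, t_start = t_start, t_end = t_end,
       orientation_deg = orient)
}

#' Full per-lung feature table
#'
#' Convenience wrapper computing B1-B6 and A1-A7 plus the time curves for
#' one tracked, partitioned lung.
#'
#' @inheritParams basic_features
#' @param lung `"right"` or `"left"` (A5-A7 are right-lung features; A6/A7
#'   are still computed for the left lung but flagged).
#' @return list with `features` (named numeric vector), `curves`
#'   (data.frame with t, V_L, CC_mm, AP_mm, orientation_deg),
#'   `excursion_map`.
#' @export
extract_features <- function(tracked, partition, lung = c("right", "left")) {
  lung <- match.arg(lung)
  bf <- basic_features(tracked, partition)
  sv <- swept_volume_features(tracked, partition)
  ex <- diaphragm_excursion(tracked, partition, lung)
  dor <- diaphragm_orientation(tracked, partition)
  feats <- c(unlist(bf$features),
             A1_L = sv$A1_L, A2_L = sv$A2_L, A3 = sv$A3,
             A1_over_RV = sv$A1_over_RV, A2_over_RV = sv$A2_over_RV,
             A4_mm = ex$A4_mm, A5_mm = ex$A5_mm,
             anterior_mean_mm = ex$anterior_mean_mm,
             posterior_mean_mm = ex$posterior_mean_mm,
             A6_deg = dor$A6_deg, A7_deg = dor$A7_deg)
  curves <- bf$curves
  curves$orientation_deg <- dor$orientation_deg
  list(features = feats, curves = curves, excursion_map = ex$max_cc_mm,
       lung = lung, swept = sv)
}

#' Write a feature table to CSV / JSON
#'
#' One row per subject and lung, mirroring the layout used for
#' supplementary spreadsheets (id, group, then features).
#'
#' @param rows data.frame with columns `subject`, `lung`, `group` and
#'   feature columns.
#' @param path output path; `.csv` or `.json` by extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
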