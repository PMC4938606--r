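#' Unfold a partitioned lung surface into a 2D box map
#'
#' Associates the diaphragmatic surface with the bottom of the lung's
#' reference bounding box and the anterior, posterior and lateral costal
#' surfaces with its front, back and side faces; each side is mapped by
#' orthographic projection onto its box face and rotated about the shared
#' bottom edge into the bottom plane. Superior costal and medial
#' triangles are not part of the map.
#'
#' @param mesh a [surface_mesh()] (reference frame).
#' @param partition a `surface_partition` (or list with `label`).
#' @return data.frame with one row per mapped triangle: `triangle`,
#'   `segment` (`bottom`, `front`, `back`, `left`, `right`), `u`, `v`
#'   (mm, plane coordinates).
#' @export
unfold_surface <- function(mesh, partition) {
  lab <- partition$label
  cent <- triangle_centroids(mesh)
  lo <- apply(mesh$vertices, 2L, min)
  hi <- apply(mesh$vertices, 2L, max)
  xm <- (lo[1L] + hi[1L]) / 2
  seg <- rep(NA_character_, nrow(cent))
  seg[lab == "diaphragmatic"] <- "bottom"
  seg[lab == "costal_anterior"] <- "front"
  seg[lab == "costal_posterior"] <- "back"
  lat <- lab == "costal_lateral"
  seg[lat & cent[, 1L] >= xm] <- "right"
  seg[lat & cent[, 1L] < xm] <- "left"
  keep <- !is.na(seg)
  u <- numeric(nrow(cent)); v <- numeric(nrow(cent))
  b <- seg == "bottom" & keep
  u[b] <- cent[b, 1L];                 v[b] <- cent[b, 2L]
  f <- seg == "front" & keep           # anterior: fold about y = hi[2]
  u[f] <- cent[f, 1L];                 v[f] <- hi[2L] + (cent[f, 3L] - lo[3L])
  bk <- seg == "back" & keep           # posterior: fold about y = lo[2]
  u[bk] <- cent[bk, 1L];               v[bk] <- lo[2L] - (cent[bk, 3L] - lo[3L])
  r <- seg == "right" & keep
  u[r] <- hi[1L] + (cent[r, 3L] - lo[3L]); v[r] <- cent[r, 2L]
  l <- seg == "left" & keep
  u[l] <- lo[1L] - (cent[l, 3L] - lo[3L]); v[l] <- cent[l, 2L]
  data.frame(triangle = which(keep), segment = seg[keep], u = u[keep],
             v = v[keep])
}

#' Per-triangle signed excursion along each segment's axis
#'
#' For every mapped triangle, the maximum over time of the centroid
#' displacement relative to frame 1 along the segment's axis, signed so
#' that motion toward the lung's interior reference planes is positive:
#' lateral segments measure LR excursion toward the mid-sagittal plane,
#' anterior/posterior segments AP excursion toward the mid-coronal plane,
#' and diaphragm (bottom) segments CC excursion in the cranial direction.
#'
#' @param tracked a [tracked_mesh()].
#' @param partition a `surface_partition` on the same connectivity.
#' @return the [unfold_surface()] data.frame with an `excursion_mm`
#'   column.
#' @export
excursion_map <- function(tracked, partition) {
  um <- unfold_surface(tracked$mesh, partition)
  lo <- apply(tracked$mesh$vertices, 2L, min)
  hi <- apply(tracked$mesh$vertices, 2L, max)
  mid <- (lo + hi) / 2
  tr <- tracked$mesh$triangles[um$triangle, , drop = FALSE]
  cent_t <- function(p, axis)
    (p[tr[, 1L], axis] + p[tr[, 2L], axis] + p[tr[, 3L], axis]) / 3
  axis <- ifelse(um$segment == "bottom", 3L,
                 ifelse(um$segment %in% c("front", "back"), 2L, 1L))
  c1 <- sapply(1:3, function(a) cent_t(tracked$positions[[1L]], a))
  ref <- c1[cbind(seq_along(axis), axis)]
  # sign: cranial for bottom; toward the mid plane for the sides
  sgn <- ifelse(um$segment == "bottom", 1,
                ifelse(ref >= mid[axis], -1, 1))
  exc <- matrix(NA_real_, nrow(um), tracked$T - 1L)
  for (t in seq.int(2L, tracked$T)) {
    ct <- sapply(1:3, function(a) cent_t(tracked$positions[[t]], a))
    exc[, t - 1L] <- sgn * (ct[cbind(seq_along(axis), axis)] - ref)
  }
  um$excursion_mm <- apply(exc, 1L, max)
  um
}

#' Write an excursion map as CSV
#'
#' @param map data.frame from [excursion_map()].
#' @param path output CSV path.
#' @param lung optional lung label column value.
#' @return `path`, invisibly.
#' @export
write_excursion_map <- function(map, path, lung = NA_character_) {
  out <- cbind(lung = lung, map)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
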