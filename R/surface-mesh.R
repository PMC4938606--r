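#' Watertight triangle surface mesh
#'
#' The central geometric object: vertex positions in physical mm
#' coordinates and triangles with consistent outward winding. Validity
#' (watertightness, orientation) is checked on construction unless
#' `validate = FALSE`.
#'
#' @param vertices numeric N x 3 matrix (mm).
#' @param triangles integer M x 3 matrix of 1-based vertex indices.
#' @param validate check watertightness and consistent orientation.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must be N x 3")
  if (ncol(triangles) != 3L) stop("'triangles' must be M x 3")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  m <- structure(list(vertices = vertices, triangles = triangles),
                 class = "surface_mesh")
  if (validate) assert_watertight(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# Directed edges of all triangles, one row per half-edge.
half_edges <- function(mesh) {
  tr <- mesh$triangles
  cbind(from = c(tr[, 1L], tr[, 2L], tr[, 3L]),
        to   = c(tr[, 2L], tr[, 3L], tr[, 1L]))
}

#' Check watertightness and consistent orientation
#'
#' Every undirected edge must be shared by exactly two triangles which
#' traverse it in opposite directions.
#'
#' @param mesh a [surface_mesh()].
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_watertight <- function(mesh) {
  he <- half_edges(mesh)
  nv <- nrow(mesh$vertices)
  key_dir <- (as.numeric(he[, 1L]) - 1) * nv + he[, 2L]
  if (anyDuplicated(key_dir))
    stop("mesh is not consistently oriented (repeated directed edge)")
  a <- pmin(he[, 1L], he[, 2L]); b <- pmax(he[, 1L], he[, 2L])
  key_und <- (as.numeric(a) - 1) * nv + b
  cnt <- table(key_und)
  if (any(cnt != 2L))
    stop("mesh is not watertight (", sum(cnt != 2L),
         " edges not shared by exactly 2 triangles)")
  invisible(TRUE)
}

#' Per-triangle geometry
#'
#' @param mesh a [surface_mesh()].
#' @return `triangle_normals()`: M x 3 outward unit normals;
#'   `triangle_areas()`: M areas (mm^2); `triangle_centroids()`: M x 3
#'   centroids (mm).
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  n <- cross3(e1, e2)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname triangle_normals
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  sqrt(rowSums(cross3(e1, e2)^2)) / 2
}

#' @rdname triangle_normals
#' @export
triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1L], , drop = FALSE] + v[tr[, 2L], , drop = FALSE] +
     v[tr[, 3L], , drop = FALSE]) / 3
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes
#' `det(v1, v2, v3) / 6`; positive for outward-oriented meshes.
#'
#' @param mesh a [surface_mesh()], or a vertex matrix via `vertices` to
#'   evaluate the same connectivity at other time points.
#' @param vertices optional replacement N x 3 vertex matrix.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, vertices = NULL) {
  v <- if (is.null(vertices)) mesh$vertices else vertices
  tr <- mesh$triangles
  v1 <- v[tr[, 1L], , drop = FALSE]
  v2 <- v[tr[, 2L], , drop = FALSE]
  v3 <- v[tr[, 3L], , drop = FALSE]
  sum(rowSums(v1 * cross3(v2, v3))) / 6
}

#' Edge-sharing triangle adjacency
#'
#' @param mesh a watertight [surface_mesh()].
#' @return M x 3 integer matrix: row `i` holds the three triangles sharing
#'   an edge with triangle `i`.
#' @export
triangle_adjacency <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  nv <- nrow(mesh$vertices)
  tri_id <- rep(seq_len(m), 3L)
  he <- half_edges(mesh)
  a <- pmin(he[, 1L], he[, 2L]); b <- pmax(he[, 1L], he[, 2L])
  key <- (as.numeric(a) - 1) * nv + b
  ord <- order(key)
  k <- key[ord]; t_of <- tri_id[ord]
  if (length(k) %% 2L != 0L || any(k[c(TRUE, FALSE)] != k[c(FALSE, TRUE)]))
    stop("boundary edges found: mesh is not watertight")
  t1 <- t_of[c(TRUE, FALSE)]; t2 <- t_of[c(FALSE, TRUE)]
  pairs <- rbind(cbind(t1, t2), cbind(t2, t1))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  adj <- matrix(NA_integer_, m, 3L)
  col <- sequence(rle(pairs[, 1L])$lengths)
  if (any(col > 3L)) stop("triangle with more than 3 edge-neighbours")
  adj[cbind(pairs[, 1L], col)] <- pairs[, 2L]
  adj
}

#' Erode a triangle region by boundary strips
#'
#' Removes `strips` BFS layers of boundary triangles (triangles adjacent to
#' a triangle outside the region) from the region, in the edge-sharing
#' adjacency graph. `strips = 0` is the identity.
#'
#' @param region integer vector of triangle indices (or logical mask).
#' @param adjacency result of [triangle_adjacency()].
#' @param strips number of boundary layers to remove.
#' @return integer vector of remaining triangle indices (possibly empty,
#'   with a warning).
#' @export
erode_region <- function(region, adjacency, strips = 2L) {
  m <- nrow(adjacency)
  inreg <- logical(m)
  if (is.logical(region)) inreg <- region else inreg[region] <- TRUE
  if (!any(inreg)) stop("empty region")
  strips <- as.integer(strips)
  for (s in seq_len(strips)) {
    if (!any(inreg)) break
    nb_out <- matrix(!inreg[adjacency], ncol = 3L)
    boundary <- inreg & rowSums(nb_out) > 0L
    inreg <- inreg & !boundary
  }
  if (!any(inreg)) warning("region eroded to the empty set")
  which(inreg)
}

#' Taubin mesh smoothing
#'
#' Two-step lambda/mu umbrella smoothing (volume-preserving low-pass
#' filter); used after [extract_mesh()] to remove voxelisation staircase.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda+mu passes.
#' @param lambda,mu smoothing factors (`0 < lambda`, `mu < -lambda`).
#' @return Smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, iterations = 60L, lambda = 0.6, mu = -0.61) {
  v <- mesh$vertices
  he <- half_edges(mesh)
  A <- Matrix::sparseMatrix(i = he[, 1L], j = he[, 2L], x = 1,
                            dims = c(nrow(v), nrow(v)))
  A <- (A + Matrix::t(A))
  A@x <- rep(1, length(A@x))          # undirected 0/1 adjacency
  deg <- Matrix::rowSums(A)
  W <- A / deg
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  surface_mesh(v, mesh$triangles, validate = FALSE)
}

#' Connected components of triangles; keep the largest surface
#' @keywords internal
largest_mesh_component <- function(vertices, triangles) {
  nv <- nrow(vertices)
  he <- cbind(c(triangles[, 1L], triangles[, 2L], triangles[, 3L]),
              c(triangles[, 2L], triangles[, 3L], triangles[, 1L]))
  g <- igraph::graph_from_edgelist(he, directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  comp <- igraph::components(g)
  keep_comp <- which.max(tabulate(comp$membership[triangles[, 1L]], comp$no))
  tri_keep <- comp$membership[triangles[, 1L]] == keep_comp
  triangles <- triangles[tri_keep, , drop = FALSE]
  used <- sort(unique(as.vector(triangles)))
  remap <- integer(nv); remap[used] <- seq_along(used)
  list(vertices = vertices[used, , drop = FALSE],
       triangles = matrix(remap[triangles], ncol = 3L))
}
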