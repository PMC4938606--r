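#' Curvature watershed on a triangle mesh
#'
#' Floods the per-vertex maximal principal curvature field from its local
#' minima so that each basin (patch) has relatively homogeneous curvature
#' and high-curvature ridges fall on patch boundaries. Vertices are
#' processed in increasing curvature order (ties by index, making the
#' result deterministic and invariant to constant fields); each vertex
#' joins the basin of its lowest already-flooded neighbour, or founds a
#' new basin if none exists. Triangles take the majority basin of their
#' three vertices; ties go to the basin with the lowest mean curvature.
#'
#' @param mesh a [surface_mesh()].
#' @param curvature per-vertex curvature (1/mm), e.g.
#'   [principal_curvature_max()].
#' @return A `patch_map`: list with `patch` (integer per triangle),
#'   `n_patches`, `vertex_basin`, and per-patch `centroid`, `mean_normal`,
#'   `mean_curvature`, `triangles`.
#' @export
mesh_watershed <- function(mesh, curvature) {
  nv <- nrow(mesh$vertices)
  if (length(curvature) != nv) stop("curvature must be defined at all vertices")
  one <- vertex_rings(mesh, 1L)
  # minimum plateaus: connected equal-value components none of whose
  # members has a strictly lower neighbour
  has_lower <- vapply(seq_len(nv), function(i)
    any(curvature[one[[i]]] < curvature[i]), logical(1))
  he <- half_edges(mesh)
  eq <- curvature[he[, 1L]] == curvature[he[, 2L]]
  g_eq <- igraph::graph_from_edgelist(he[eq, , drop = FALSE],
                                      directed = FALSE)
  if (igraph::vcount(g_eq) < nv)
    g_eq <- igraph::add_vertices(g_eq, nv - igraph::vcount(g_eq))
  plat <- igraph::components(g_eq)$membership
  plat_has_lower <- rowsum(as.numeric(has_lower), plat)[, 1L] > 0
  min_plateaus <- which(!plat_has_lower)
  basin <- integer(nv)
  nb_count <- length(min_plateaus)
  basin_of_plateau <- integer(max(plat))
  basin_of_plateau[min_plateaus] <- seq_len(nb_count)
  seeds_v <- which(basin_of_plateau[plat] > 0L)
  basin[seeds_v] <- basin_of_plateau[plat[seeds_v]]
  # priority flood: grow basins in increasing curvature, FIFO on ties
  h <- heap_new(nv * 4L)
  for (v in seeds_v) heap_push(h, curvature[v], v)
  while (h$n > 0L) {
    v <- heap_pop(h)
    for (u in one[[v]]) {
      if (basin[u] == 0L) {
        basin[u] <- basin[v]
        heap_push(h, curvature[u], u)
      }
    }
  }
  tr <- mesh$triangles
  b3 <- matrix(basin[tr], ncol = 3L)
  # per-basin mean curvature for tie-breaking
  agg <- rowsum(curvature, basin)
  bmean <- numeric(nb_count)
  ids <- as.integer(rownames(agg))
  bmean[ids] <- agg[, 1L] / tabulate(basin, nb_count)[ids]
  patch <- apply_majority(b3, bmean)
  # compact patch ids to those actually used by triangles
  used <- sort(unique(patch))
  patch <- match(patch, used)
  np <- length(used)
  cent <- triangle_centroids(mesh)
  tn <- triangle_normals(mesh)
  ta <- triangle_areas(mesh)
  patches <- lapply(seq_len(np), function(p) which(patch == p))
  centroid <- do.call(rbind, lapply(patches, function(ix)
    colSums(cent[ix, , drop = FALSE] * ta[ix]) / sum(ta[ix])))
  mean_normal <- do.call(rbind, lapply(patches, function(ix) {
    n <- colSums(tn[ix, , drop = FALSE] * ta[ix])
    n / max(sqrt(sum(n^2)), 1e-12)
  }))
  mean_curv <- vapply(patches, function(ix)
    mean(curvature[unique(as.vector(tr[ix, , drop = FALSE]))]), numeric(1))
  structure(list(patch = patch, n_patches = np, vertex_basin = basin,
                 triangles = patches, centroid = centroid,
                 mean_normal = mean_normal, mean_curvature = mean_curv),
            class = "patch_map")
}

# majority basin of each triangle row; ties -> basin with lowest mean value
apply_majority <- function(b3, basin_mean) {
  n <- nrow(b3)
  out <- integer(n)
  same12 <- b3[, 1L] == b3[, 2L]
  same13 <- b3[, 1L] == b3[, 3L]
  same23 <- b3[, 2L] == b3[, 3L]
  out[same12 | same13] <- b3[same12 | same13, 1L]
  out[!same12 & !same13 & same23] <- b3[!same12 & !same13 & same23, 2L]
  alldiff <- !same12 & !same13 & !same23
  if (any(alldiff)) {
    sub <- b3[alldiff, , drop = FALSE]
    pick <- max.col(-matrix(basin_mean[sub], ncol = 3L), ties.method = "first")
    out[alldiff] <- sub[cbind(seq_len(nrow(sub)), pick)]
  }
  out
}

# minimal binary min-heap keyed by (value, insertion counter)
heap_new <- function(capacity = 1024L) {
  env <- new.env()
  env$key <- numeric(capacity)
  env$seq <- numeric(capacity)
  env$id <- integer(capacity)
  env$n <- 0L
  env$counter <- 0
  env
}

heap_less <- function(h, a, b) {
  h$key[a] < h$key[b] || (h$key[a] == h$key[b] && h$seq[a] < h$seq[b])
}

heap_push <- function(h, key, id) {
  h$n <- h$n + 1L
  h$counter <- h$counter + 1
  if (h$n > length(h$key)) {
    h$key <- c(h$key, numeric(length(h$key)))
    h$seq <- c(h$seq, numeric(length(h$seq)))
    h$id <- c(h$id, integer(length(h$id)))
  }
  i <- h$n
  h$key[i] <- key; h$seq[i] <- h$counter; h$id[i] <- id
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(h, i, p)) {
      swap_heap(h, i, p); i <- p
    } else break
  }
}

heap_pop <- function(h) {
  out <- h$id[1L]
  swap_heap(h, 1L, h$n)
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    s <- i
    if (l <= h$n && heap_less(h, l, s)) s <- l
    if (r <= h$n && heap_less(h, r, s)) s <- r
    if (s == i) break
    swap_heap(h, i, s); i <- s
  }
  out
}

swap_heap <- function(h, a, b) {
  tmp <- h$key[a]; h$key[a] <- h$key[b]; h$key[b] <- tmp
  tmp <- h$seq[a]; h$seq[a] <- h$seq[b]; h$seq[b] <- tmp
  tmpi <- h$id[a]; h$id[a] <- h$id[b]; h$id[b] <- tmpi
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d patches over %d triangles\n", x$n_patches,
              length(x$patch)))
  invisible(x)
}
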