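#' Per-vertex normals
#'
#' Area-weighted average of incident triangle normals, normalised.
#'
#' @param mesh a [surface_mesh()].
#' @return N x 3 matrix of outward unit normals.
#' @export
vertex_normals <- function(mesh) {
  tn <- triangle_normals(mesh)
  ta <- triangle_areas(mesh)
  nv <- nrow(mesh$vertices)
  out <- matrix(0, nv, 3L)
  for (c in 1:3) {
    idx <- mesh$triangles[, c]
    for (d in 1:3)
      out[, d] <- out[, d] + tabulate_w(idx, tn[, d] * ta, nv)
  }
  len <- sqrt(rowSums(out^2)); len[len == 0] <- 1
  out / len
}

# sum of weights w by integer bin
tabulate_w <- function(bin, w, nbins) {
  rs <- rowsum(w, bin)
  out <- numeric(nbins)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Maximal principal curvature per vertex
#'
#' Fits a quadric height field over each vertex's k-ring neighbourhood in
#' the tangent frame of the vertex normal and takes the largest eigenvalue
#' of the resulting shape operator. Sign convention: convex-outward
#' regions have positive curvature (sphere of radius r gives +1/r).
#'
#' @param mesh a [surface_mesh()].
#' @param ring neighbourhood ring order (2 recommended for voxel-derived
#'   meshes).
#' @return numeric vector of kappa_max (1/mm) per vertex.
#' @export
principal_curvature_max <- function(mesh, ring = 2L) {
  v <- mesh$vertices
  nv <- nrow(v)
  vn <- vertex_normals(mesh)
  nbr <- vertex_rings(mesh, ring)
  kmax <- numeric(nv)
  for (i in seq_len(nv)) {
    nb <- nbr[[i]]
    if (length(nb) < 5L) { kmax[i] <- NA_real_; next }
    n0 <- vn[i, ]
    # tangent basis
    t1 <- if (abs(n0[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * n0) * n0
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n0[2L] * t1[3L] - n0[3L] * t1[2L],
            n0[3L] * t1[1L] - n0[1L] * t1[3L],
            n0[1L] * t1[2L] - n0[2L] * t1[1L])
    d <- v[nb, , drop = FALSE] - matrix(v[i, ], length(nb), 3L, byrow = TRUE)
    u <- d %*% t1; w <- d %*% t2; h <- d %*% n0
    X <- cbind(u^2 / 2, u * w, w^2 / 2, u, w)
    fit <- tryCatch(qr.solve(qr(X), h), error = function(e) NULL)
    if (is.null(fit)) { kmax[i] <- NA_real_; next }
    a <- fit[1L]; b <- fit[2L]; c_ <- fit[3L]
    # shape operator of the height field (first-order slope correction)
    g <- 1 + fit[4L]^2 + fit[5L]^2
    II <- matrix(c(a, b, b, c_), 2L) / sqrt(g)
    ev <- eigen(II, symmetric = TRUE, only.values = TRUE)$values
    # height along outward normal: convex surfaces curve away (negative h)
    kmax[i] <- max(-ev)
  }
  if (anyNA(kmax)) {
    # isolated/degenerate vertices: stop if any ring was truly empty
    bad <- which(is.na(kmax))
    deg <- lengths(nbr)[bad]
    if (any(deg == 0L)) stop("isolated vertex without neighbourhood ring")
    kmax[bad] <- 0
  }
  kmax
}

# list of k-ring vertex neighbourhoods (excluding the vertex itself)
vertex_rings <- function(mesh, ring = 2L) {
  nv <- nrow(mesh$vertices)
  he <- half_edges(mesh)
  adj1 <- split(he[, 2L], he[, 1L])
  nbr <- vector("list", nv)
  keys <- as.integer(names(adj1))
  one <- vector("list", nv)
  one[keys] <- lapply(adj1, unique)
  for (i in seq_len(nv)) {
    cur <- one[[i]]
    if (ring >= 2L) {
      acc <- cur
      for (r in seq_len(ring - 1L)) {
        nxt <- unique(unlist(one[cur], use.names = FALSE))
        acc <- unique(c(acc, nxt))
        cur <- nxt
      }
      acc <- setdiff(acc, i)
      nbr[[i]] <- acc
    } else {
      nbr[[i]] <- setdiff(cur, i)
    }
  }
  nbr
}

#' Signed normal curvature across each adjacency edge
#'
#' Dihedral estimate between adjacent triangle centroids:
#' `kappa = sign * ||n_i - n_j|| / ||p_i - p_j||`, positive across convex
#' hinges (normals diverging away from the interior) and negative across
#' concave ones.
#'
#' @param mesh a [surface_mesh()].
#' @param adjacency from [triangle_adjacency()].
#' @return list with integer matrix `edges` (i < j triangle pairs) and
#'   numeric `kappa` (1/mm).
#' @export
edge_normal_curvature <- function(mesh, adjacency = triangle_adjacency(mesh)) {
  cent <- triangle_centroids(mesh)
  tn <- triangle_normals(mesh)
  m <- nrow(adjacency)
  i <- rep(seq_len(m), 3L)
  j <- as.vector(adjacency)
  keep <- !is.na(j) & i < j
  i <- i[keep]; j <- j[keep]
  dp <- cent[j, , drop = FALSE] - cent[i, , drop = FALSE]
  dn <- tn[j, , drop = FALSE] - tn[i, , drop = FALSE]
  L <- sqrt(rowSums(dp^2))
  kappa <- sign(rowSums(dp * dn)) * sqrt(rowSums(dn^2)) / pmax(L, 1e-12)
  list(edges = cbind(i = i, j = j), kappa = kappa)
}
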