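#' Analytic mesh primitives
#'
#' Closed, consistently oriented meshes used as geometric test substrates
#' and phantom building blocks.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions icosahedron subdivision level (faces = 20 * 4^n).
#' @param center length-3 centre (mm).
#' @return A [surface_mesh()].
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ea <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    eb <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    key <- (as.numeric(ea) - 1) * nv + eb
    ukey <- unique(as.vector(key))
    mid_of <- match(as.vector(key), ukey)            # per (face, edge slot)
    ua <- ((ukey - 1) %% nv) + 1
    ub <- floor((ukey - 1) / nv) + 1
    mids <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- matrix(mid_of + nv, ncol = 3L)              # midpoint ids per face
    f <- rbind(cbind(f[, 1L], m[, 1L], m[, 3L]),
               cbind(f[, 2L], m[, 2L], m[, 1L]),
               cbind(f[, 3L], m[, 3L], m[, 2L]),
               m)
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f, validate = FALSE)
}

#' @rdname icosphere
#' @param half_axes length-3 ellipsoid half axes (mm).
#' @export
ellipsoid_mesh <- function(half_axes, subdivisions = 3L, center = c(0, 0, 0)) {
  m <- icosphere(1, subdivisions)
  surface_mesh(sweep(sweep(m$vertices, 2, half_axes, "*"), 2, center, "+"),
               m$triangles, validate = FALSE)
}

#' @rdname icosphere
#' @param height cylinder height (mm), axis along z.
#' @param n_theta,n_z angular / axial resolution.
#' @export
cylinder_mesh <- function(radius = 1, height = 2, n_theta = 48L, n_z = 24L,
                          center = c(0, 0, 0)) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  z <- seq(-height / 2, height / 2, length.out = n_z + 1L)
  side <- cbind(rep(radius * cos(theta), n_z + 1L),
                rep(radius * sin(theta), n_z + 1L),
                rep(z, each = n_theta))
  vid <- function(it, iz) (iz - 1L) * n_theta + (it - 1L) %% n_theta + 1L
  it <- rep(seq_len(n_theta), n_z)
  iz <- rep(seq_len(n_z), each = n_theta)
  # outward winding: counter-clockwise seen from outside
  f1 <- cbind(vid(it, iz), vid(it + 1L, iz), vid(it + 1L, iz + 1L))
  f2 <- cbind(vid(it, iz), vid(it + 1L, iz + 1L), vid(it, iz + 1L))
  nv <- n_theta * (n_z + 1L)
  v <- rbind(side, c(0, 0, -height / 2), c(0, 0, height / 2))
  bot <- nv + 1L; top <- nv + 2L
  fb <- cbind(bot, vid(seq_len(n_theta) + 1L, 1L), vid(seq_len(n_theta), 1L))
  ftp <- cbind(top, vid(seq_len(n_theta), n_z + 1L),
               vid(seq_len(n_theta) + 1L, n_z + 1L))
  surface_mesh(sweep(v, 2, center, "+"), rbind(f1, f2, fb, ftp),
               validate = FALSE)
}

#' @rdname icosphere
#' @param sides length-3 box edge lengths (mm).
#' @export
box_mesh <- function(sides = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- sides / 2
  v <- as.matrix(expand.grid(x = c(-h[1L], h[1L]), y = c(-h[2L], h[2L]),
                             z = c(-h[3L], h[3L])))
  # corners: 1(---) 2(+--) 3(-+-) 4(++-) 5(--+) 6(+-+) 7(-++) 8(+++)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),       # bottom (-z)
             c(5, 6, 8), c(5, 8, 7),       # top (+z)
             c(1, 2, 6), c(1, 6, 5),       # -y
             c(3, 7, 8), c(3, 8, 4),       # +y
             c(1, 5, 7), c(1, 7, 3),       # -x
             c(2, 4, 8), c(2, 8, 6))       # +x
  surface_mesh(sweep(v, 2, center, "+"), f)
}
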