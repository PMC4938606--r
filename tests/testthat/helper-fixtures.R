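# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# voxelised ball, radius 25 mm, 1 mm spacing
ball_mask <- function(r = 25, n = 61L, spacing = 1) {
  cc <- (seq_len(n) - (n + 1) / 2) * spacing
  d2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  binary_mask(array(as.integer(d2 <= r^2), c(n, n, n)),
              spacing = rep(spacing, 3),
              origin = rep(cc[1L], 3))
}

# voxelised axis-aligned box of the given physical side lengths
box_mask <- function(sides = c(40, 30, 20), spacing = 1) {
  n <- as.integer(sides / spacing) + 10L
  dat <- array(0L, n)
  for (a in 1:3) stopifnot(sides[a] / spacing == round(sides[a] / spacing))
  i <- lapply(1:3, function(a) 5L + seq_len(as.integer(sides[a] / spacing)))
  dat[i[[1L]], i[[2L]], i[[3L]]] <- 1L
  binary_mask(dat, spacing = rep(spacing, 3))
}

# a sphere with a spherical dimple pressed into its +x side
dimpled_mask <- function(r = 40, dimple_r = 24, depth = 26, spacing = 1.5) {
  n <- as.integer(ceiling(2 * r / spacing)) + 6L
  cc <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = cc, y = cc, z = cc)
  inside <- g$x^2 + g$y^2 + g$z^2 <= r^2
  dc <- c(r + dimple_r - depth, 0, 0)
  inside <- inside &
    ((g$x - dc[1L])^2 + g$y^2 + g$z^2) > dimple_r^2
  binary_mask(array(as.integer(inside), c(n, n, n)),
              spacing = rep(spacing, 3), origin = rep(cc[1L], 3))
}

# smooth trigonometric deformation field for conservation tests
random_smooth_deformation <- function(p, amplitude = 3) {
  a <- stats::runif(9, -1, 1) * amplitude
  w <- stats::runif(3, 1 / 40, 1 / 12)
  p + cbind(a[1L] * sin(w[1L] * p[, 2L]) + a[2L] * cos(w[2L] * p[, 3L]),
            a[3L] * sin(w[2L] * p[, 1L]) + a[4L] * cos(w[3L] * p[, 3L]),
            a[5L] * sin(w[3L] * p[, 1L]) + a[6L] * cos(w[1L] * p[, 2L]))
}

# control-like phantom pipeline products shared between test files
phantom_case <- function(type = "control", seed = 1L) {
  fixture(paste0("phantom_", type, "_", seed), function() {
    spec <- stock_phantom(type, rng_seed = seed)
    ph <- generate_phantom(spec, mask_frames = spec$T, truth = TRUE)
    mesh <- extract_mesh(ph$reference_mask, target_edge_mm = 3.5,
                         smooth_iterations = 40)
    tl <- truth_labels(spec, triangle_centroids(mesh))
    list(spec = spec, ph = ph, mesh = mesh, labels = tl)
  })
}

# feature extraction against analytic truth labels (boundary band dropped)
phantom_features <- function(case, lung = "right") {
  lab <- ifelse(case$labels$boundary, NA, case$labels$label)
  part <- list(D = which(lab == "diaphragmatic"),
               C = which(lab == "costal"),
               adjacency = triangle_adjacency(case$mesh))
  tracked <- propagate_mesh(case$mesh, case$ph$field, case$spec$T)
  extract_features(tracked, part, lung)
}
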