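test_that("curvature emphasis weights convex edges five-fold", {
  expect_equal(curvature_emphasis(2), 10)
  expect_equal(curvature_emphasis(-2), 2)
  expect_equal(curvature_emphasis(0), 0)
})

test_that("edge weights penalise convex hinges more than concave ones", {
  # dimpled sphere: edges crossing the dimple rim are convex hinges
  dm <- fixture("dimpled", function() dimpled_mask())
  mesh <- fixture("dimpled_mesh", function()
    extract_mesh(fixture("dimpled", dimpled_mask), target_edge_mm = 4))
  adj <- triangle_adjacency(mesh)
  w <- edge_weights(mesh, adj, seq_len(nrow(mesh$triangles)))
  expect_true(all(w$w > 0 & w$w <= 1))
  expect_error(edge_weights(mesh, adj, 1:10, w1 = 0), "positive")
  # strongest convex hinge gets a lower weight than an equally sharp
  # concave hinge
  k <- w$kappa
  top_convex <- order(k, decreasing = TRUE)[1:20]
  match_concave <- sapply(k[top_convex], function(kk)
    which.min(abs(-k - kk)))
  expect_lt(mean(w$w[top_convex]), mean(w$w[match_concave]))
})

test_that("random walker solves the Dirichlet problem exactly", {
  w <- list(edges = cbind(1:4, 2:5), w = rep(1, 4))
  P <- random_walker(w, seeds = c(1, 5), seed_labels = c("A", "B"),
                     n_nodes = 5)
  expect_equal(unname(P[, "A"]), c(1, 0.75, 0.5, 0.25, 0),
               tolerance = 1e-12)
  # all nodes seeded: probabilities are the seed indicators
  P2 <- random_walker(w, seeds = 1:5,
                      seed_labels = c("A", "A", "B", "B", "A"), n_nodes = 5)
  expect_equal(unname(P2[, "A"]), c(1, 1, 0, 0, 1))
  # random graph vs dense direct solve
  set.seed(7)
  n <- 60
  ed <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(ed)) < 0.08
  ed <- ed[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  keep_v <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep_v)
  ed <- igraph::as_edgelist(g)
  n <- igraph::vcount(g)
  wt <- stats::runif(nrow(ed), 0.05, 1)
  seeds <- c(3, min(40, n)); labs <- c("A", "B")
  P3 <- random_walker(list(edges = ed, w = wt), seeds, labs, n)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1L]; j <- ed[k, 2L]
    L[i, j] <- L[i, j] - wt[k]; L[j, i] <- L[j, i] - wt[k]
  }
  diag(L) <- -rowSums(L)
  U <- setdiff(seq_len(n), seeds)
  dense <- solve(L[U, U], -L[U, seeds] %*% diag(2))
  expect_lt(max(abs(P3[U, ] - dense)), 1e-8)
  # probability axioms
  expect_lt(max(abs(rowSums(P3) - 1)), 1e-10)
  expect_true(all(P3 >= -1e-12 & P3 <= 1 + 1e-12))
})

test_that("random walker flags unseeded components", {
  w <- list(edges = rbind(c(1, 2), c(3, 4)), w = c(1, 1))
  expect_warning(P <- random_walker(w, seeds = 1L, seed_labels = "A",
                                    n_nodes = 4), "unseeded")
  expect_equal(unname(P[, 1L]), c(1, 1, 1, 1))  # single label everywhere
})

test_that("hull distance matches the analytic ellipsoid oracle", {
  m <- ellipsoid_mesh(c(50, 40, 30), 3)
  # scaled-down interior copies of the surface sit at a known depth
  for (f in c(0.98, 0.9)) {
    pts <- m$vertices[seq(1, nrow(m$vertices), by = 40), ] * f
    d <- convex_hull_distance(pts, m$vertices)
    # analytic distance to the ellipsoid along the surface normal is
    # bounded by (1-f) * min/max axis
    expect_true(all(d > 0.8 * (1 - f) * 30 - 0.2))
    expect_true(all(d < (1 - f) * 50 + 0.5))
  }
})

test_that("costal extraction keeps convex surfaces and drops the dimple", {
  m <- ellipsoid_mesh(c(50, 40, 60), 3)
  pm <- mesh_watershed(m, principal_curvature_max(m))
  expect_identical(sort(extract_costal(m, pm)), seq_len(nrow(m$triangles)))
  # concave indentation: the deep interior of the phantom's cardiac
  # pocket must not be merged into the costal surface
  case <- phantom_case("control", 1L)
  pm2 <- mesh_watershed(case$mesh, principal_curvature_max(case$mesh))
  co <- extract_costal(case$mesh, pm2)
  d <- convex_hull_distance(triangle_centroids(case$mesh),
                            case$mesh$vertices)
  deep_medial <- which(case$labels$label == "medial" &
                         !case$labels$boundary & d > 20)
  expect_gt(length(deep_medial), 20)
  expect_lt(length(intersect(deep_medial, co)) / length(deep_medial), 0.02)
  # frac = 1 selects a subset of the frac = 0.25 result
  co_strict <- extract_costal(case$mesh, pm2, frac = 1)
  expect_true(all(co_strict %in% co))
})

test_that("costal subdivision follows the outward normal ray", {
  m <- icosphere(40, 3)
  all_t <- seq_len(nrow(m$triangles))
  lab <- subdivide_costal(m, all_t)
  nrm <- triangle_normals(m)
  cent <- triangle_centroids(m)
  expect_length(lab, length(all_t))
  # brute-force first-hit ray/box-face oracle on a random subset
  lo <- apply(m$vertices, 2, min); hi <- apply(m$vertices, 2, max)
  set.seed(5)
  idx <- sample(all_t, 60)
  lab_idx <- subdivide_costal(m, idx)
  for (k in seq_along(idx)) {
    i <- idx[k]
    tt <- Inf; axis <- NA; side <- NA
    for (a in 1:3) for (s in c(-1, 1)) {
      bound <- if (s > 0) hi[a] else lo[a]
      if (sign(nrm[i, a]) != s) next
      th <- (bound - cent[i, a]) / nrm[i, a]
      if (th > 0 && th < tt) { tt <- th; axis <- a; side <- s }
    }
    expected <- if (axis == 2 && side > 0) "anterior" else
      if (axis == 2) "posterior" else
      if (axis == 3 && side > 0) "superior" else
      if (axis == 3) "posterior" else "lateral"
    expect_identical(lab_idx[k], expected)
  }
  # axis-aligned sanity: +y normal triangles are anterior, +z superior
  py <- which.max(nrm[, 2L]); pz <- which.max(nrm[, 3L])
  expect_identical(subdivide_costal(m, py), "anterior")
  expect_identical(subdivide_costal(m, pz), "superior")
})

test_that("anatomical seeds land on the dome and the indentation", {
  case <- phantom_case("control", 1L)
  mesh <- case$mesh
  pm <- mesh_watershed(mesh, principal_curvature_max(mesh))
  co <- extract_costal(mesh, pm)
  region <- setdiff(seq_len(nrow(mesh$triangles)), co)
  adj <- triangle_adjacency(mesh)
  w <- edge_weights(mesh, adj, region)
  seeds <- select_seeds(mesh, pm, w, region)
  truth <- case$labels$label
  expect_gt(length(seeds$seed_nodes), 1)
  sd_tri <- w$nodes[seeds$seed_nodes]
  dia_seeds <- sd_tri[seeds$seed_labels == "diaphragmatic"]
  med_seeds <- sd_tri[seeds$seed_labels == "medial"]
  expect_true(mean(truth[dia_seeds] == "diaphragmatic") > 0.9)
  expect_true(mean(truth[med_seeds] == "medial") > 0.9)
})

test_that("iterative partition is deterministic for a fixed seed", {
  case <- phantom_case("control", 1L)
  p1 <- suppressWarnings(partition_lung_surface(case$mesh, rng_seed = 11))
  p2 <- suppressWarnings(partition_lung_surface(case$mesh, rng_seed = 11))
  expect_identical(p1$label, p2$label)
  # partition is exhaustive and exclusive
  expect_true(all(p1$label %in% c("costal_anterior", "costal_posterior",
                                  "costal_superior", "costal_lateral",
                                  "medial", "diaphragmatic")))
  expect_identical(intersect(p1$D, p1$C), integer(0))
  expect_identical(length(p1$label), nrow(case$mesh$triangles))
})
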