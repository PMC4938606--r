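test_that("surface mesh construction enforces watertightness", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tet <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  expect_silent(surface_mesh(v, tet))
  # open fan: boundary edges
  expect_error(surface_mesh(v, tet[1:3, ]), "watertight")
  # one flipped triangle: repeated directed edge
  bad <- tet; bad[1L, ] <- rev(bad[1L, ])
  expect_error(surface_mesh(v, bad), "oriented")
})

test_that("mesh volume matches closed forms and flips with winding", {
  expect_equal(mesh_volume(box_mesh(c(1, 1, 1))), 1)
  ico <- icosphere(30, 4)
  expect_lt(abs(mesh_volume(ico) - 4 / 3 * pi * 30^3) / (4 / 3 * pi * 30^3),
            0.005)
  rev_ico <- surface_mesh(ico$vertices, ico$triangles[, c(1, 3, 2)],
                          validate = FALSE)
  expect_equal(mesh_volume(rev_ico), -mesh_volume(ico))
  # volume error decreases under refinement
  errs <- sapply(2:4, function(s)
    abs(mesh_volume(icosphere(30, s)) - 4 / 3 * pi * 30^3))
  expect_true(all(diff(errs) < 0))
})

test_that("mesh extraction from masks is watertight and volume-accurate", {
  ball <- fixture("ball", function() ball_mask())
  m <- extract_mesh(ball, target_edge_mm = 3)
  expect_silent(assert_watertight(m))
  va <- 4 / 3 * pi * 25^3
  expect_lt(abs(mesh_volume(m) - va) / va, 0.02)
  el <- sqrt(rowSums((m$vertices[m$triangles[, 1L], ] -
                        m$vertices[m$triangles[, 2L], ])^2))
  expect_gt(mean(el), 0.7 * 3); expect_lt(mean(el), 1.3 * 3)
  # Euler characteristic 2 for a genus-0 surface, and 2E = 3F
  nE <- nrow(m$triangles) * 3 / 2
  expect_equal(nrow(m$vertices) - nE + nrow(m$triangles), 2)
  # raw (unsmoothed) surface encloses exactly the voxel volume
  raw <- extract_mesh(ball, target_edge_mm = 3, smooth_iterations = 0)
  vox <- resample_mask(ball, 3 / 1.138)
  expect_equal(mesh_volume(raw),
               sum(lungkin:::make_well_composed(vox$data)) * (3 / 1.138)^3)
  expect_error(extract_mesh(binary_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("box mask volume is recovered within 2%", {
  # a sharp box is meshed at the native voxel resolution (coarse
  # resampling would quantise the faces by up to half a voxel per side)
  bm <- box_mask(c(40, 30, 20))
  m <- extract_mesh(bm, target_edge_mm = 1.2)
  expect_lt(abs(mesh_volume(m) - 24000) / 24000, 0.02)
  raw <- extract_mesh(bm, target_edge_mm = 1.2, smooth_iterations = 0)
  expect_equal(mesh_volume(raw), 24000)
})

test_that("triangle adjacency is symmetric and 3-regular", {
  tet <- box_mesh(c(1, 1, 1))
  adj <- triangle_adjacency(tet)
  expect_true(all(rowSums(!is.na(adj)) == 3L))
  ico <- icosphere(1, 2)
  a2 <- triangle_adjacency(ico)
  # symmetry via brute-force shared-edge scan
  for (i in sample(nrow(a2), 20)) {
    for (j in a2[i, ]) expect_true(i %in% a2[j, ])
  }
  shared_edges <- function(i, j, tr)
    length(intersect(tr[i, ], tr[j, ])) == 2L
  for (i in sample(nrow(a2), 10)) {
    for (j in a2[i, ]) expect_true(shared_edges(i, j, ico$triangles))
  }
})

test_that("region erosion removes BFS boundary layers", {
  ico <- icosphere(10, 3)
  adj <- triangle_adjacency(ico)
  cent <- triangle_centroids(ico)
  disk <- which(cent[, 3L] > 3)
  expect_identical(erode_region(disk, adj, 0), sort(disk))
  expect_warning(out <- erode_region(disk[1L], adj, 2), "empty")
  expect_length(out, 0)
  # oracle: remove BFS-depth<2 triangles from the boundary
  e2 <- erode_region(disk, adj, 2)
  inreg <- logical(nrow(adj)); inreg[disk] <- TRUE
  depth <- rep(Inf, nrow(adj))
  boundary <- disk[apply(matrix(!inreg[adj[disk, ]], ncol = 3), 1, any)]
  depth[boundary] <- 0
  frontier <- boundary
  d <- 0
  while (length(frontier) > 0 && d < 2) {
    nxt <- setdiff(intersect(unique(as.vector(adj[frontier, ])), disk),
                   which(is.finite(depth)))
    d <- d + 1
    depth[nxt] <- d
    frontier <- nxt
  }
  oracle <- sort(setdiff(disk, which(depth < 2)))
  expect_identical(e2, oracle)
  # composition: erode(erode(R,1),1) == erode(R,2)
  expect_identical(erode_region(erode_region(disk, adj, 1), adj, 1), e2)
  expect_true(all(e2 %in% disk))
})

test_that("principal curvature recovers sphere, plane and cylinder", {
  sph <- icosphere(50, 3)
  k <- principal_curvature_max(sph)
  expect_lt(abs(stats::median(k) - 1 / 50) / (1 / 50), 0.15)
  expect_true(all(k > 0))
  cyl <- cylinder_mesh(20, 100, 64, 32)
  k2 <- principal_curvature_max(cyl)
  interior <- abs(cyl$vertices[, 3L]) < 30
  expect_lt(abs(stats::median(k2[interior]) - 1 / 20) / (1 / 20), 0.15)
  # flat interior of the cylinder caps: |kappa| ~ 0 over the planar
  # 1-ring (the 2-ring reaches onto the curved side wall)
  k1 <- principal_curvature_max(cyl, ring = 1)
  lid <- cyl$vertices[, 3L] > 49 &
    sqrt(rowSums(cyl$vertices[, 1:2]^2)) < 1e-6
  expect_true(all(abs(k1[lid]) < 1e-3))
})

test_that("STL and PLY round-trip meshes and labels", {
  m <- icosphere(10, 1)
  labs <- sample(0:5, nrow(m$triangles), replace = TRUE)
  stl <- file.path(tempdir(), "m.stl")
  write_stl(m, stl, labels = labs)
  back <- read_stl(stl)
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-5)
  expect_identical(attr(back, "labels"), labs)
  write_stl(m, stl, ascii = TRUE)
  back2 <- read_stl(stl)
  expect_equal(mesh_volume(back2), mesh_volume(m), tolerance = 1e-4)
  ply <- file.path(tempdir(), "m.ply")
  write_ply(m, ply, labels = labs)
  back3 <- read_ply(ply)
  expect_identical(attr(back3, "labels"), as.integer(labs))
  expect_equal(mesh_volume(back3), mesh_volume(m), tolerance = 1e-4)
})
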