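test_that("mesh propagation applies the field and checks the reference", {
  m <- icosphere(20, 2)
  ident <- function(p, t) p
  tr <- propagate_mesh(m, ident, 4)
  for (t in 1:4) expect_equal(tr$positions[[t]], m$vertices)
  # rigid translation preserves volume, shifts the centroid
  shift <- function(p, t) if (t == 1) sweep(p, 2, c(0, 0, 10), "+") else p
  tr2 <- propagate_mesh(m, shift, 2)
  expect_equal(mesh_volume(m, tr2$positions[[1L]]), mesh_volume(m))
  expect_equal(mean(tr2$positions[[1L]][, 3L]) - mean(m$vertices[, 3L]), 10)
  expect_warning(
    tracked_mesh(m, list(m$vertices, m$vertices[, c(1, 3, 2)])),
    "volume")
})

test_that("basic features respond to scaling and rest", {
  m <- icosphere(30, 3)
  cent <- triangle_centroids(m)
  part <- list(D = which(cent[, 3L] < -25), C = which(cent[, 3L] > 25))
  # static maneuver
  still <- propagate_mesh(m, function(p, t) p, 3)
  bf <- basic_features(still, part)
  expect_equal(bf$features$B2, 0)
  expect_equal(bf$features$B3, 1)
  expect_equal(bf$features$B4, 1)
  expect_equal(bf$features$B5, 1)
  expect_equal(bf$features$B6, 1)
  # isotropic scaling x1.2 at inspiration
  sc <- function(p, t) if (t == 1) p * 1.2 else p
  bf2 <- basic_features(propagate_mesh(m, sc, 2), part)
  expect_equal(bf2$features$B4, 1.2, tolerance = 1e-10)
  expect_equal(bf2$features$B5, 1.2, tolerance = 1e-10)
  expect_equal(bf2$features$B6, 1, tolerance = 1e-10)
  expect_equal(bf2$features$B3, 1.2^3, tolerance = 1e-10)
})

test_that("swept volumes telescope exactly over a closed surface", {
  # unit-area triangle moved 3 mm against its normal sweeps +3 mm^3
  p0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  p1 <- p0; p1[, 3L] <- -3
  expect_equal(swept_volumes(p0, p1, rbind(1:3)), 3)
  # conservation: sum of swept volumes equals V(t) - V(t+1) to 1e-9
  set.seed(11)
  m <- icosphere(40, 3)
  for (rep in 1:5) {
    q0 <- random_smooth_deformation(m$vertices)
    q1 <- random_smooth_deformation(q0) +
      matrix(stats::rnorm(length(q0), 0, 0.2), ncol = 3L)
    sw <- sum(swept_volumes(q0, q1, m$triangles))
    dv <- mesh_volume(m, q0) - mesh_volume(m, q1)
    expect_lt(abs(sw - dv) / max(abs(dv), 1), 1e-9)
  }
  # translation invariance of per-triangle swept volumes
  sw0 <- swept_volumes(m$vertices, m$vertices * 0.98, m$triangles)
  off <- matrix(c(10, -20, 5), nrow(m$vertices), 3L, byrow = TRUE)
  sw1 <- swept_volumes(m$vertices + off, m$vertices * 0.98 + off,
                       m$triangles)
  expect_equal(sw0, sw1, tolerance = 1e-10)
})

test_that("region swept volumes attribute the change and normalise by RV", {
  m <- icosphere(30, 3)
  cent <- triangle_centroids(m)
  part <- list(D = which(cent[, 3L] < -15), C = which(cent[, 3L] > 15),
               adjacency = triangle_adjacency(m))
  sc <- function(p, t) if (t == 1) p * 1.1 else p
  tr <- propagate_mesh(m, sc, 2)
  sv <- swept_volume_features(tr, part)
  expect_gt(sv$A1_L, 0)           # both regions move inward when deflating
  expect_gt(sv$A2_L, 0)
  expect_equal(sv$A3, sv$A1_L / (sv$A1_L + sv$A2_L))
  expect_equal(sv$A1_over_RV, sv$A1_L * 1e6 / mesh_volume(m))
  # symmetric cap regions sweep equal volumes
  expect_equal(sv$A3, 0.5, tolerance = 0.05)
})

test_that("diaphragm excursion follows the sign convention", {
  m <- icosphere(30, 3)
  cent <- triangle_centroids(m)
  part <- list(D = which(cent[, 3L] < -15))
  # whole lung sits 15 mm lower at inspiration, rises to the reference
  lift <- function(p, t) if (t == 1) sweep(p, 2, c(0, 0, -15), "+") else p
  ex <- diaphragm_excursion(propagate_mesh(m, lift, 3), part, "right")
  expect_equal(ex$A4_mm, 15, tolerance = 1e-10)
  expect_equal(ex$A5_mm, 0, tolerance = 1e-10)
  # caudal (paradoxical) motion gives a negative mean excursion
  sink <- function(p, t) if (t == 1) sweep(p, 2, c(0, 0, 5), "+") else p
  ex2 <- diaphragm_excursion(propagate_mesh(m, sink, 3), part, "right")
  expect_equal(ex2$A4_mm, -5, tolerance = 1e-10)
  expect_true(is.na(
    diaphragm_excursion(propagate_mesh(m, lift, 3), part, "left")$A5_mm))
})

test_that("diaphragm orientation measures the dome tilt", {
  # closed box whose bottom face is tilted 20 deg backwards about x
  th <- -20 * pi / 180            # backward tilt: posterior side higher
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  b <- box_mesh(c(40, 40, 40))
  vb <- b$vertices %*% t(R)
  mb <- surface_mesh(vb, b$triangles, validate = FALSE)
  nrm <- triangle_normals(mb)
  D <- which(nrm[, 3L] < -0.7)          # rotated bottom face
  tr <- propagate_mesh(mb, function(p, t) p, 3)
  dor <- diaphragm_orientation(tr, list(D = D))
  expect_equal(dor$A6_deg, 20, tolerance = 1e-6)
  expect_equal(dor$A7_deg, 0)
  # horizontal dome: normal parallel to -z gives 0 deg
  D0 <- which(triangle_normals(b)[, 3L] < -0.9)
  dor0 <- diaphragm_orientation(propagate_mesh(b, function(p, t) p, 2),
                                list(D = D0))
  expect_equal(dor0$A6_deg, 0, tolerance = 1e-10)
})

test_that("feature table export round-trips", {
  rows <- data.frame(subject = c("a", "b"), lung = "right",
                     group = c("patient", "control"),
                     B3 = c(1.5, 2.4), A4_mm = c(10, 60))
  csv <- file.path(tempdir(), "features.csv")
  write_feature_table(rows, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$A4_mm, rows$A4_mm)
  js <- file.path(tempdir(), "features.json")
  write_feature_table(rows, js)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$B3, rows$B3)
})
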