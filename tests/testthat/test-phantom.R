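test_that("phantom specs validate their geometry", {
  expect_error(phantom_spec(T = 1), "frames")
  expect_error(phantom_spec(cut_z = -200), "cap plane")
  expect_error(phantom_spec(dome_height = 90), "equator|ramp|calibration")
  expect_error(phantom_spec(ap_contraction = 0.1,
                            motion_support = "dome_column"), "contraction")
  s <- stock_phantom("control", rng_seed = 3)
  expect_s3_class(s, "phantom_spec")
})

test_that("phantom generation is deterministic for a fixed seed", {
  s1 <- stock_phantom("control", rng_seed = 5)
  s2 <- stock_phantom("control", rng_seed = 5)
  expect_identical(s1[names(s1) != "rng_seed"], s2[names(s2) != "rng_seed"])
  m1 <- generate_phantom(s1, mask_frames = s1$T, truth = FALSE)
  m2 <- generate_phantom(s2, mask_frames = s2$T, truth = FALSE)
  expect_identical(m1$reference_mask$data, m2$reference_mask$data)
  # different seeds give different jittered geometry
  s3 <- stock_phantom("control", rng_seed = 6)
  expect_false(identical(s1$half_axes, s3$half_axes))
})

test_that("a static phantom produces no motion", {
  s <- phantom_spec(d_max = 0, grad_posterior = 0, ap_contraction = 0,
                    theta_start = 5, theta_end = 5, T = 3, jitter = 0)
  fld <- phantom_displacement(s)
  p <- matrix(stats::rnorm(60, 0, 25), ncol = 3L)
  for (t in 1:3) expect_equal(fld(p, t), p)
  tr <- phantom_truth(s)
  expect_lt(abs(tr$V_t_mm3[1L] / tr$V_t_mm3[3L] - 1), 1e-9)
  expect_equal(tr$A4_mm, 0)
})

test_that("displacement provider is the identity at the reference frame", {
  s <- stock_phantom("control", rng_seed = 2)
  fld <- phantom_displacement(s)
  p <- matrix(stats::runif(90, -0.8, 0.8), ncol = 3L) %*%
    diag(s$half_axes)
  expect_equal(fld(p, s$T), p)
  # per-frame steps stay below the amplitude bound
  v <- fld(p, 1)
  for (t in 2:s$T) {
    vn <- fld(p, t)
    expect_lt(max(abs(vn - v)), s$amp_max + s$d_max)
    v <- vn
  }
})

test_that("rasterised masks track the analytic volumes", {
  s <- stock_phantom("control", rng_seed = 1, spacing = 1.6)
  frames <- c(1L, 6L, s$T)
  ph <- generate_phantom(s, mask_frames = frames, truth = TRUE)
  for (f in as.character(frames)) {
    m <- ph$masks[[f]]
    vol <- sum(m$data) * prod(m$spacing)
    expect_lt(abs(vol - ph$truth$V_t_mm3[as.integer(f)]) /
                ph$truth$V_t_mm3[as.integer(f)], 0.02)
  }
  # expiration-like: analytic volume strictly decreasing
  expect_true(all(diff(ph$truth$V_t_mm3) < 0))
  expect_gt(ph$truth$V_t_mm3[1L] / ph$truth$V_t_mm3[s$T], 1)
})

test_that("truth labels classify the analytic primitives", {
  s <- stock_phantom("control", rng_seed = 1, jitter = 0)
  # dome apex point
  apex <- c(0, 0, lungkin:::phantom_dome_z(s, 0, 0))
  expect_identical(truth_labels(s, rbind(apex))$label, "diaphragmatic")
  # deepest indentation point: on the sphere, facing the lung centre
  dirc <- -s$indent_center / sqrt(sum(s$indent_center^2))
  deep <- s$indent_center + dirc * s$indent_radius
  expect_identical(truth_labels(s, rbind(deep))$label, "medial")
  # shell point
  shell <- c(0, 0, s$half_axes[3L])
  tl <- truth_labels(s, rbind(shell))
  expect_identical(tl$label, "costal")
  expect_false(tl$boundary)
  expect_error(truth_labels(s, rbind(c(500, 0, 0)), tol_mm = 5), "tol")
  # random surface sample labels match the signed-distance oracle
  case <- phantom_case("control", 1L)
  d <- lungkin:::truth_distances(case$spec,
                                 triangle_centroids(case$mesh))
  oracle <- c("costal", "diaphragmatic", "medial")[apply(abs(d), 1,
                                                         which.min)]
  expect_identical(case$labels$label, oracle)
})
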