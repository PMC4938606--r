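test_that("box surfaces unfold to their own rectangles", {
  b <- box_mesh(c(40, 30, 20))
  nrm <- triangle_normals(b)
  lab <- rep("costal_superior", nrow(b$triangles))
  lab[nrm[, 3L] < -0.9] <- "diaphragmatic"
  lab[nrm[, 2L] > 0.9] <- "costal_anterior"
  lab[nrm[, 2L] < -0.9] <- "costal_posterior"
  lab[abs(nrm[, 1L]) > 0.9] <- "costal_lateral"
  part <- list(label = lab)
  um <- unfold_surface(b, part)
  # bottom face maps to itself
  bot <- um[um$segment == "bottom", ]
  cb <- triangle_centroids(b)[bot$triangle, ]
  expect_equal(bot$u, cb[, 1L]); expect_equal(bot$v, cb[, 2L])
  # segments occupy disjoint rectangles around the bottom
  rng <- lapply(split(um, um$segment), function(s)
    c(min(s$u), max(s$u), min(s$v), max(s$v)))
  expect_gt(min(rng$front[3L]), max(rng$bottom[4L]) - 1e-9)
  expect_lt(max(rng$back[4L]), min(rng$bottom[3L]) + 1e-9)
  expect_gt(min(rng$right[1L]), max(rng$bottom[2L]) - 1e-9)
  expect_lt(max(rng$left[2L]), min(rng$bottom[1L]) + 1e-9)
  # coverage: everything except superior appears exactly once
  expect_identical(sort(um$triangle),
                   sort(which(lab != "costal_superior")))
  expect_false(any(duplicated(um$triangle)))
})

test_that("uniform inward contraction gives uniform positive excursion", {
  b <- box_mesh(c(40, 40, 40))
  nrm <- triangle_normals(b)
  lab <- rep("costal_superior", nrow(b$triangles))
  lab[nrm[, 3L] < -0.9] <- "diaphragmatic"
  lab[nrm[, 2L] > 0.9] <- "costal_anterior"
  lab[nrm[, 2L] < -0.9] <- "costal_posterior"
  lab[abs(nrm[, 1L]) > 0.9] <- "costal_lateral"
  part <- list(label = lab)
  # every face sits 8 mm further out at inspiration (frame 1)
  sc <- function(p, t) if (t == 1) p * (28 / 20) else p
  tr <- propagate_mesh(b, sc, 2)
  em <- excursion_map(tr, part)
  expect_true(all(abs(em$excursion_mm - 8) < 1e-9))
  # caudal dome motion renders negative on the diaphragm segment
  sink <- function(p, t) if (t == 1) sweep(p, 2, c(0, 0, 6), "+") else p
  em2 <- excursion_map(propagate_mesh(b, sink, 2), part)
  expect_true(all(em2$excursion_mm[em2$segment == "bottom"] == -6))
})

test_that("diaphragm-segment mean excursion matches A4 on the phantom", {
  case <- phantom_case("control", 1L)
  lab <- ifelse(case$labels$boundary, NA, case$labels$label)
  part <- list(label = ifelse(is.na(lab), "medial",
                              ifelse(lab == "costal", "costal_superior", lab)),
               D = which(lab == "diaphragmatic"))
  tracked <- propagate_mesh(case$mesh, case$ph$field, case$spec$T)
  em <- excursion_map(tracked, part)
  bot <- em[em$segment == "bottom", ]
  areas <- triangle_areas(case$mesh)[bot$triangle]
  mean_exc <- sum(bot$excursion_mm * areas) / sum(areas)
  ex <- diaphragm_excursion(tracked, part, "right")
  expect_equal(mean_exc, ex$A4_mm, tolerance = 1e-10)
})
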