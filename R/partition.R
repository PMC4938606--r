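#' Distance from interior points to the convex hull boundary
#'
#' For a point inside the hull, the distance to the hull boundary equals
#' `min_u (h(u) - p . u)` over unit directions `u`, where
#' `h(u) = max_v v . u` is the support function of the vertex set. The
#' minimum is taken over a dense icosphere direction set; this
#' over-estimates the true distance by at most about `R * theta^2 / 2`
#' (object radius R, angular sampling step theta), a fraction of a
#' millimetre at lung scale.
#'
#' @param points n x 3 query points (mm), assumed inside the hull.
#' @param vertices m x 3 hull-defining point set (mm).
#' @param n_subdiv icosphere subdivision for the direction set.
#' @return numeric distances (mm, >= 0 up to sampling error).
#' @export
convex_hull_distance <- function(points, vertices, n_subdiv = 3L) {
  dirs <- icosphere(1, n_subdiv)$vertices
  sup <- dirs %*% t(vertices)
  h <- vapply(seq_len(nrow(dirs)), function(k) max(sup[k, ]), numeric(1))
  out <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(dirs)))
    out <- pmin(out, h[k] - points %*% dirs[k, ])
  as.vector(out)
}

#' Extract the costal surface
#'
#' The costal (chest-wall adjacent) surface is the only large convex lung
#' surface region, so it hugs the convex hull: watershed patches in which
#' at least a fraction `frac` of triangles have centroids closer than
#' `hull_dist_mm` to the hull of the mesh vertices are merged into the
#' costal surface.
#'
#' @param mesh a [surface_mesh()].
#' @param patches a `patch_map` from [mesh_watershed()].
#' @param hull_dist_mm proximity threshold (mm).
#' @param frac minimum fraction of close triangles per patch.
#' @return integer vector of costal triangle indices.
#' @export
extract_costal <- function(mesh, patches, hull_dist_mm = 10, frac = 0.25) {
  cent <- triangle_centroids(mesh)
  rng <- apply(mesh$vertices, 2L, function(x) diff(range(x)))
  if (min(rng) < 1e-9) stop("degenerate (coplanar) vertex set: no 3D hull")
  d <- convex_hull_distance(cent, mesh$vertices)
  close_tri <- d < hull_dist_mm
  sel <- vapply(patches$triangles, function(ix) mean(close_tri[ix]) >= frac,
                logical(1))
  sort(unlist(patches$triangles[sel], use.names = FALSE))
}

#' Subdivide the costal surface by bounding-box face
#'
#' Visualization-oriented labelling: each costal triangle is labelled by
#' the face of the lung's axis-aligned bounding box first intersected by
#' the outward normal ray from its centroid. Hits on the medial or
#' inferior face (rare for genuinely costal triangles) fall back to
#' lateral and posterior respectively.
#'
#' @param mesh a [surface_mesh()].
#' @param costal integer vector of costal triangle indices.
#' @param medial_side which x-side of the box faces the mediastinum
#'   (`"low"` = medial at small x, as for a right lung with +x to the
#'   subject's left... choose per lung).
#' @return character vector (same length as `costal`) with values
#'   `"anterior"`, `"posterior"`, `"superior"`, `"lateral"`.
#' @export
subdivide_costal <- function(mesh, costal, medial_side = c("low", "high")) {
  medial_side <- match.arg(medial_side)
  cent <- triangle_centroids(mesh)[costal, , drop = FALSE]
  nrm <- triangle_normals(mesh)[costal, , drop = FALSE]
  lo <- apply(mesh$vertices, 2L, min)
  hi <- apply(mesh$vertices, 2L, max)
  # first positive-t axis-plane crossing: t = (bound - c) / n per axis
  t_hit <- matrix(Inf, length(costal), 3L)
  bound_hi <- matrix(NA, length(costal), 3L)
  for (a in 1:3) {
    pos <- nrm[, a] > 1e-12
    neg <- nrm[, a] < -1e-12
    t_hit[pos, a] <- (hi[a] - cent[pos, a]) / nrm[pos, a]
    t_hit[neg, a] <- (lo[a] - cent[neg, a]) / nrm[neg, a]
    bound_hi[, a] <- pos
  }
  if (any(!is.finite(apply(t_hit, 1L, min))))
    stop("normal ray misses bounding box (centroid outside box?)")
  axis <- max.col(-t_hit, ties.method = "first")
  hi_side <- bound_hi[cbind(seq_along(costal), axis)]
  lab <- character(length(costal))
  lab[axis == 2L & hi_side] <- "anterior"
  lab[axis == 2L & !hi_side] <- "posterior"
  lab[axis == 3L & hi_side] <- "superior"
  lab[axis == 3L & !hi_side] <- "posterior"     # inferior hit fallback
  lat_hi <- if (medial_side == "low") TRUE else FALSE
  lab[axis == 1L & hi_side == lat_hi] <- "lateral"
  lab[axis == 1L & hi_side != lat_hi] <- "lateral"  # medial hit fallback
  lab
}

#' Random-walker edge weights on the non-costal triangle graph
#'
#' Implements the boundary-emphasising distance
#' `d_ij = w1 ||p_i - p_j|| + w2 ||n_i - n_j|| + w3 f(kappa_ij)` with
#' `f(kappa) = 5 kappa` for convex (`kappa >= 0`) and `|kappa|` for
#' concave edges, and weight `w_ij = exp(-d_ij^2)`. Centroid distances are
#' normalised by their mean over the region so the weights are scale-free;
#' the edge normal curvature is normalised likewise (multiplied by the
#' mean centroid distance).
#'
#' @param mesh a [surface_mesh()].
#' @param adjacency from [triangle_adjacency()].
#' @param region integer vector of triangle indices forming the graph
#'   nodes (typically the non-costal surface).
#' @param w1,w2,w3 positive coefficients of the three distance terms.
#' @return list with `nodes` (triangle index per node), `edges`
#'   (node-index pairs, i < j), `w` (weights in (0, 1]), `d` and `kappa`.
#' @export
edge_weights <- function(mesh, adjacency, region, w1 = 1, w2 = 1, w3 = 1) {
  if (any(c(w1, w2, w3) <= 0)) stop("weight coefficients must be positive")
  region <- sort(region)
  node_of <- integer(nrow(adjacency))
  node_of[region] <- seq_along(region)
  cent <- triangle_centroids(mesh)
  tn <- triangle_normals(mesh)
  i <- rep(region, 3L)
  j <- as.vector(adjacency[region, , drop = FALSE])
  keep <- !is.na(j) & node_of[j] > 0L & i < j
  i <- i[keep]; j <- j[keep]
  dp <- cent[j, , drop = FALSE] - cent[i, , drop = FALSE]
  dn <- tn[j, , drop = FALSE] - tn[i, , drop = FALSE]
  L <- sqrt(rowSums(dp^2))
  Lbar <- mean(L)
  kappa <- sign(rowSums(dp * dn)) * sqrt(rowSums(dn^2)) / pmax(L, 1e-12)
  kap_n <- kappa * Lbar
  fk <- ifelse(kap_n >= 0, 5 * kap_n, abs(kap_n))
  d <- w1 * L / Lbar + w2 * sqrt(rowSums(dn^2)) + w3 * fk
  # floor keeps strongly separated parts numerically connected so the
  # Dirichlet system stays nonsingular; ratios across ridges are intact
  list(nodes = region, edges = cbind(i = node_of[i], j = node_of[j]),
       w = pmax(exp(-d^2), 1e-9), d = d, kappa = kappa)
}

#' Piecewise-linear curvature emphasis of the random-walker distance
#'
#' @param kappa signed normal curvature (convex positive).
#' @return `5 * kappa` for `kappa >= 0`, `|kappa|` otherwise.
#' @export
curvature_emphasis <- function(kappa) ifelse(kappa >= 0, 5 * kappa, abs(kappa))

#' Anatomical seed selection for the medial/diaphragm split
#'
#' Applies the seeding rules on the non-costal watershed patches:
#' the most posterior patch is diaphragmatic; the most superior patch and
#' every patch partially occluded from a viewpoint centrally below the
#' lung are medial; labels then propagate to adjacent unlabeled patches
#' whose mean normals diverge less than `max_normal_deg` and whose mean
#' inter-patch edge weight exceeds `ridge_threshold`, until a fixpoint.
#' One seed node (the patch's central triangle) is emitted per labelled
#' patch.
#'
#' @param mesh a [surface_mesh()].
#' @param patches `patch_map` restricted implicitly via `region`: only
#'   patches whose triangles all lie in `region` are considered.
#' @param weights from [edge_weights()] on the same region.
#' @param region integer vector of non-costal triangle indices.
#' @param max_normal_deg normal divergence limit for propagation (deg).
#' @param ridge_threshold minimum mean inter-patch weight for propagation.
#' @return list with `seed_nodes` (node ids into `weights$nodes`),
#'   `seed_labels` (`"diaphragmatic"`/`"medial"`), `patch_label` (per
#'   patch), `fully_labeled` flag, `viewpoint`.
#' @export
select_seeds <- function(mesh, patches, weights, region,
                         max_normal_deg = 30, ridge_threshold = exp(-2.25)) {
  inreg <- logical(length(patches$patch))
  inreg[region] <- TRUE
  pat_ids <- which(vapply(patches$triangles, function(ix) all(inreg[ix]),
                          logical(1)))
  if (length(pat_ids) == 0L) stop("no watershed patch lies in the region")
  cent_p <- patches$centroid[pat_ids, , drop = FALSE]
  lab <- rep(NA_character_, length(pat_ids))
  post <- which.min(cent_p[, 2L])           # most posterior (min y)
  sup <- which.max(cent_p[, 3L])            # most superior (max z)
  if (post == sup)
    stop("ambiguous seeds: one patch is both most posterior and most superior")
  lab[post] <- "diaphragmatic"
  lab[sup] <- "medial"
  # occlusion from a viewpoint centrally below the lung
  vlo <- apply(mesh$vertices, 2L, min)
  vhi <- apply(mesh$vertices, 2L, max)
  viewpoint <- c(mean(c(vlo[1L], vhi[1L])), mean(c(vlo[2L], vhi[2L])),
                 vlo[3L] - 0.25 * (vhi[3L] - vlo[3L]))
  test <- occlusion_tester(mesh, viewpoint)
  for (k in seq_along(pat_ids)) {
    if (k == post) next                     # posterior rule wins for its patch
    if (!is.na(lab[k])) next
    for (f in patches$triangles[[pat_ids[k]]]) {
      if (test(f)) { lab[k] <- "medial"; break }
    }
  }
  # propagation over patch adjacency
  padj <- patch_adjacency_weights(patches, weights, pat_ids)
  cosmax <- cos(max_normal_deg * pi / 180)
  nrm_p <- patches$mean_normal[pat_ids, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (k in which(is.na(lab))) {
      nbrs <- padj$nbr[[k]]
      if (length(nbrs) == 0L) next
      ok <- !is.na(lab[nbrs]) &
        (nrm_p[nbrs, , drop = FALSE] %*% nrm_p[k, ]) > cosmax &
        padj$wbar[[k]] > ridge_threshold
      if (any(ok)) {
        cand <- nbrs[ok]
        best <- cand[which.max(padj$wbar[[k]][ok])]
        lab[k] <- lab[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  node_of <- integer(nrow(mesh$triangles))
  node_of[weights$nodes] <- seq_along(weights$nodes)
  seeded <- which(!is.na(lab))
  seed_tri <- vapply(pat_ids[seeded], function(p)
    central_triangle(patches, p, mesh), integer(1))
  list(seed_nodes = node_of[seed_tri], seed_labels = lab[seeded],
       patch_ids = pat_ids, patch_label = lab,
       fully_labeled = !anyNA(lab), viewpoint = viewpoint)
}

# central triangle: nearest to the patch's area-weighted centroid
central_triangle <- function(patches, p, mesh) {
  ix <- patches$triangles[[p]]
  cent <- triangle_centroids(mesh)[ix, , drop = FALSE]
  target <- patches$centroid[p, ]
  d2 <- rowSums(sweep(cent, 2, target)^2)
  ix[which.min(d2)]           # which.min takes the lowest index on ties
}

# mean inter-patch edge weight and patch neighbour lists
patch_adjacency_weights <- function(patches, weights, pat_ids) {
  patch_of_tri <- patches$patch
  tri_of_node <- weights$nodes
  pi_ <- patch_of_tri[tri_of_node[weights$edges[, 1L]]]
  pj <- patch_of_tri[tri_of_node[weights$edges[, 2L]]]
  cross <- pi_ != pj
  a <- pmin(pi_[cross], pj[cross]); b <- pmax(pi_[cross], pj[cross])
  key <- paste(a, b)
  wk <- rowsum(weights$w[cross], key)
  ck <- rowsum(rep(1, sum(cross)), key)
  wbar <- wk[, 1L] / ck[, 1L]
  names(wbar) <- rownames(wk)
  idx_of <- match(seq_along(patches$triangles), pat_ids)
  nbr <- vector("list", length(pat_ids))
  wb <- vector("list", length(pat_ids))
  for (nm in names(wbar)) {
    ab <- as.integer(strsplit(nm, " ")[[1L]])
    ka <- idx_of[ab[1L]]; kb <- idx_of[ab[2L]]
    if (is.na(ka) || is.na(kb)) next
    nbr[[ka]] <- c(nbr[[ka]], kb); wb[[ka]] <- c(wb[[ka]], wbar[[nm]])
    nbr[[kb]] <- c(nbr[[kb]], ka); wb[[kb]] <- c(wb[[kb]], wbar[[nm]])
  }
  list(nbr = nbr, wbar = wb)
}

# Ray-occlusion test helper: precomputes the ray-independent parts of the
# Moller-Trumbore intersection so each ray costs a few vector operations.
occlusion_tester <- function(mesh, viewpoint) {
  cent <- triangle_centroids(mesh)
  tn <- triangle_normals(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  v1 <- v[tr[, 1L], , drop = FALSE]
  e1 <- v[tr[, 2L], , drop = FALSE] - v1
  e2 <- v[tr[, 3L], , drop = FALSE] - v1
  tv <- matrix(viewpoint, nrow(v1), 3L, byrow = TRUE) - v1
  qv <- cross3(tv, e1)
  t_num <- rowSums(qv * e2)
  u_e2 <- tv                                  # for pv = dir x e2 terms
  function(f) {
    dir <- cent[f, ] - viewpoint
    if (sum(dir * tn[f, ]) >= 0) return(FALSE)   # back-facing: skip
    pv <- cbind(dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L],
                dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L],
                dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L])
    det <- rowSums(e1 * pv)
    u <- rowSums(tv * pv) / det
    w <- (qv %*% dir) / det
    t_ <- t_num / det
    hit <- abs(det) > 1e-12 & u >= 0 & w >= 0 & (u + w) <= 1 &
      t_ > 1e-9 & t_ < 1 - 1e-6
    hit[f] <- FALSE
    any(hit)
  }
}

# logical named vector: is each candidate triangle occluded from viewpoint?
# Only triangles facing the viewpoint count: a back-facing triangle hides
# behind its own surface patch by construction and carries no information
# about concave pockets.
occluded_triangles <- function(mesh, candidates, viewpoint) {
  test <- occlusion_tester(mesh, viewpoint)
  out <- vapply(candidates, test, logical(1))
  names(out) <- as.character(candidates)
  out
}

#' Seeded random walker on a weighted graph
#'
#' Solves the combinatorial Dirichlet problem: non-seed probabilities are
#' harmonic with respect to the weighted graph Laplacian with seed nodes
#' clamped to their label indicators, equivalently the probability that a
#' weight-biased random walk starting at the node first reaches a seed of
#' each label.
#'
#' @param weights list with `edges` (n x 2 node pairs) and `w` (positive
#'   weights), as from [edge_weights()]; `n_nodes` inferred from the seed
#'   and edge ids unless given.
#' @param seeds integer node ids.
#' @param seed_labels labels (character or factor), one per seed.
#' @param n_nodes number of graph nodes.
#' @return matrix (n_nodes x n_labels) of probabilities, columns named by
#'   label; rows sum to 1.
#' @export
random_walker <- function(weights, seeds, seed_labels,
                          n_nodes = max(weights$edges, seeds)) {
  if (length(seeds) == 0L) stop("need at least one seed")
  if (length(seeds) != length(seed_labels)) stop("one label per seed")
  labs <- unique(as.character(seed_labels))
  ed <- weights$edges
  w <- weights$w
  L <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                            j = c(ed[, 2L], ed[, 1L]),
                            x = rep(-w, 2L), dims = c(n_nodes, n_nodes))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  is_seed <- logical(n_nodes)
  is_seed[seeds] <- TRUE
  U <- which(!is_seed)
  P <- matrix(0, n_nodes, length(labs), dimnames = list(NULL, labs))
  P[cbind(seeds, match(as.character(seed_labels), labs))] <- 1
  if (length(U) == 0L) return(P)
  LU <- L[U, U, drop = FALSE]
  B <- L[U, seeds, drop = FALSE]
  S <- P[seeds, , drop = FALSE]
  # isolated unseeded components make LU singular: detect and fall back
  sol <- tryCatch(as.matrix(Matrix::solve(LU, -B %*% S)),
                  error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular system (unseeded component): assigning uniform ",
            "probabilities there")
    g <- igraph::graph_from_edgelist(ed, directed = FALSE)
    if (igraph::vcount(g) < n_nodes)
      g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    seeded_comps <- unique(comp[seeds])
    ok <- U[comp[U] %in% seeded_comps]
    bad <- setdiff(U, ok)
    if (length(ok) > 0L) {
      LU2 <- L[ok, ok, drop = FALSE]
      B2 <- L[ok, seeds, drop = FALSE]
      P[ok, ] <- as.matrix(Matrix::solve(LU2, -B2 %*% S))
    }
    P[bad, ] <- 1 / length(labs)
    return(P)
  }
  P[U, ] <- sol
  P
}

#' Iterative random-walker surface partitioning
#'
#' Alternates random-walker solves with confidence thresholding: nodes
#' with `p_diaphragm > p_d` form the diaphragmatic partition and
#' `p_medial > p_m` the medial partition; new seeds are sampled uniformly
#' inside each partition (one per `reseed_per` member triangles, fixed
#' RNG) and added to the seed set. Iteration stops when fewer than
#' `change_tol` of the triangles change partition, or at `max_iter`.
#' Final labels: `p_diaphragm > p_d` is diaphragmatic, everything else
#' medial. When the seed-selection stage already labelled every patch the
#' walker is skipped and patch labels are used directly.
#'
#' @param mesh a [surface_mesh()].
#' @param patches `patch_map` from [mesh_watershed()].
#' @param weights from [edge_weights()].
#' @param seeds from [select_seeds()].
#' @param region non-costal triangle indices (the walker graph).
#' @param p_d,p_m probability thresholds for diaphragm / medial.
#' @param change_tol stop when the changed fraction falls below this.
#' @param max_iter iteration cap.
#' @param reseed_per one new random seed per this many partition triangles.
#' @param rng_seed integer seed for reproducible re-seeding.
#' @return list with `label` (per mesh triangle: `"diaphragmatic"`,
#'   `"medial"`, or `NA` outside the region), `p_diaphragm` per node,
#'   `iterations`, `converged`, `walker_used`.
#' @export
iterative_partition <- function(mesh, patches, weights, seeds, region,
                                p_d = 0.8, p_m = 0.6, change_tol = 0.03,
                                max_iter = 10L, reseed_per = 50L,
                                rng_seed = 1L) {
  n_nodes <- length(weights$nodes)
  lab <- rep(NA_character_, nrow(mesh$triangles))
  if (seeds$fully_labeled) {
    for (k in seq_along(seeds$patch_ids))
      lab[patches$triangles[[seeds$patch_ids[k]]]] <- seeds$patch_label[k]
    return(list(label = lab, p_diaphragm = NULL, iterations = 0L,
                converged = TRUE, walker_used = FALSE))
  }
  seed_nodes <- seeds$seed_nodes
  seed_labels <- seeds$seed_labels
  prev_part <- rep(NA_character_, n_nodes)
  P <- NULL
  iterations <- 0L
  converged <- FALSE
  rng <- local_rng(rng_seed)
  for (it in seq_len(max_iter)) {
    iterations <- it
    P <- random_walker(weights, seed_nodes, seed_labels, n_nodes)
    pd <- if ("diaphragmatic" %in% colnames(P)) P[, "diaphragmatic"] else
      rep(0, n_nodes)
    pm <- if ("medial" %in% colnames(P)) P[, "medial"] else rep(0, n_nodes)
    part <- ifelse(pd > p_d, "diaphragmatic",
                   ifelse(pm > p_m, "medial", NA_character_))
    changed <- mean(xor(is.na(part), is.na(prev_part)) |
                      (!is.na(part) & !is.na(prev_part) & part != prev_part))
    if (it > 1L && changed < change_tol) { converged <- TRUE; break }
    prev_part <- part
    # add random seeds inside each thresholded partition
    for (lb in c("diaphragmatic", "medial")) {
      inside <- setdiff(which(!is.na(part) & part == lb), seed_nodes)
      n_new <- min(length(inside), max(0L, length(inside) %/% reseed_per))
      if (n_new > 0L) {
        new_nodes <- rng$sample(inside, n_new)
        seed_nodes <- c(seed_nodes, new_nodes)
        seed_labels <- c(seed_labels, rep(lb, n_new))
      }
    }
  }
  pd <- P[, "diaphragmatic"]
  node_lab <- ifelse(pd > p_d, "diaphragmatic", "medial")
  lab[weights$nodes] <- node_lab
  list(label = lab, p_diaphragm = pd, iterations = iterations,
       converged = converged, walker_used = TRUE)
}

# self-contained RNG stream that leaves the global seed untouched
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    st
  }
  env$sample <- function(x, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- sample(x, n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  env
}

#' Full anatomical partition of a lung surface mesh
#'
#' Runs the whole partitioning cascade: per-vertex curvature, watershed,
#' costal extraction by hull proximity, costal subdivision, edge weights
#' on the residual surface, anatomical seed selection and (when needed)
#' the iterative random walker separating the diaphragmatic from the
#' medial surface.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param hull_dist_mm,frac see [extract_costal()].
#' @param p_d,p_m,change_tol,max_iter,rng_seed see [iterative_partition()].
#' @param w1,w2,w3 see [edge_weights()].
#' @param ring curvature neighbourhood ring, see
#'   [principal_curvature_max()].
#' @param medial_side see [subdivide_costal()].
#' @return A `surface_partition`: list with `label` (per triangle, one of
#'   `costal_anterior`, `costal_posterior`, `costal_superior`,
#'   `costal_lateral`, `medial`, `diaphragmatic`), index sets `D`
#'   (diaphragmatic), `C` (all costal), plus diagnostics (`patches`,
#'   `iterations`, `converged`, `walker_used`).
#' @export
partition_lung_surface <- function(mesh, hull_dist_mm = 10, frac = 0.25,
                                   p_d = 0.8, p_m = 0.6, change_tol = 0.03,
                                   max_iter = 10L, rng_seed = 1L,
                                   w1 = 1, w2 = 1, w3 = 1, ring = 2L,
                                   medial_side = "low") {
  kappa <- principal_curvature_max(mesh, ring = ring)
  patches <- mesh_watershed(mesh, kappa)
  costal <- extract_costal(mesh, patches, hull_dist_mm, frac)
  m <- nrow(mesh$triangles)
  region <- setdiff(seq_len(m), costal)
  if (length(region) == 0L)
    stop("entire surface is costal: nothing to partition")
  adjacency <- triangle_adjacency(mesh)
  weights <- edge_weights(mesh, adjacency, region, w1, w2, w3)
  seeds <- select_seeds(mesh, patches, weights, region)
  part <- iterative_partition(mesh, patches, weights, seeds, region,
                              p_d = p_d, p_m = p_m, change_tol = change_tol,
                              max_iter = max_iter, rng_seed = rng_seed)
  label <- character(m)
  costal_sub <- subdivide_costal(mesh, costal, medial_side)
  label[costal] <- paste0("costal_", costal_sub)
  label[region] <- part$label[region]
  # watershed patches can straddle the region border; any region triangle
  # that the walker did not see inherits its patch label, else medial
  label[label == "" | is.na(label)] <- "medial"
  structure(list(label = label, D = which(label == "diaphragmatic"),
                 C = grep("^costal_", label), patches = patches,
                 seeds = seeds, iterations = part$iterations,
                 converged = part$converged, walker_used = part$walker_used,
                 adjacency = adjacency),
            class = "surface_partition")
}

#' @export
print.surface_partition <- function(x, ...) {
  cat("<surface_partition>\n")
  print(table(x$label))
  cat(sprintf("walker used: %s, iterations: %d, converged: %s\n",
              x$walker_used, x$iterations, x$converged))
  invisible(x)
}
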