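#' Otsu threshold of an intensity volume
#'
#' Computes the threshold maximising the between-class variance over a
#' 256-bin histogram spanning the intensity range; ties are broken toward
#' the lower threshold. Foreground are voxels strictly above the cut.
#'
#' @param volume a [voxel_grid()] with at least two distinct values.
#' @param n_bins number of histogram bins.
#' @return A [binary_mask()] with attribute `"threshold"`.
#' @export
otsu_threshold <- function(volume, n_bins = 256L) {
  stopifnot(is_voxel_grid(volume))
  v <- as.vector(volume$data)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("constant volume: no Otsu threshold exists")
  cut <- otsu_cut(v, n_bins)
  mask <- binary_mask(array(as.integer(volume$data > cut), dim(volume$data)),
                      volume$spacing, volume$origin)
  attr(mask, "threshold") <- cut
  mask
}

# threshold value (bin upper edge) maximising between-class variance
otsu_cut <- function(v, n_bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                       # class 0 = bins 1..k
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[n_bins]
  # between-class variance for cut after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  w0k <- w0[k]; m0k <- mu0[k]
  valid <- w0k > 0 & w0k < 1
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mu_tot * w0k[valid] - m0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  kbest <- which.max(sb)                # which.max takes the first (lowest) tie
  breaks[kbest + 1L]
}

#' Body mask for bias-field estimation
#'
#' Otsu-thresholds an intensity volume to separate the (bright) body from
#' air, optionally removing an exclusion mask (e.g. a manual lung
#' segmentation so that the air-filled lungs are not part of the body mask).
#'
#' @param volume intensity [voxel_grid()].
#' @param exclude optional [binary_mask()] on the same grid.
#' @return A [binary_mask()].
#' @export
build_body_mask <- function(volume, exclude = NULL) {
  m <- otsu_threshold(volume)
  if (!is.null(exclude)) {
    stop_if_grid_mismatch(volume, exclude)
    m$data <- array(as.integer(m$data == 1L & exclude$data == 0L), dim(m$data))
    if (sum(m$data) == 0L)
      warning("body mask is empty after exclusion")
  }
  m
}

#' Iterative bias-correction masking driver
#'
#' Alternates mask construction and bias correction: at each iteration a
#' body mask is computed from the current corrected volume via
#' [build_body_mask()], and the corrector is applied to the *original*
#' volume using that newest mask. Three iterations are the default; more
#' typically give no further improvement.
#'
#' @param volume intensity [voxel_grid()].
#' @param corrector function `(volume, mask) -> voxel_grid` implementing a
#'   single bias-field correction (e.g. [poly_bias_corrector()]); an
#'   external N4 implementation can be plugged in through the same contract.
#' @param n_iter number of iterations (>= 1).
#' @param exclude optional exclusion mask passed to [build_body_mask()].
#' @return The corrected [voxel_grid()], with the final body mask attached
#'   as attribute `"mask"`.
#' @export
iterative_bias_correction <- function(volume, corrector, n_iter = 3L,
                                      exclude = NULL) {
  stopifnot(is_voxel_grid(volume), is.function(corrector))
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("'n_iter' must be >= 1")
  current <- volume
  mask <- NULL
  for (i in seq_len(n_iter)) {
    mask <- build_body_mask(current, exclude)
    if (sum(mask$data) == 0L)
      stop("empty body mask at iteration ", i)
    current <- tryCatch(corrector(volume, mask), error = function(e)
      stop("bias corrector failed at iteration ", i, ": ",
           conditionMessage(e)))
    if (!is_voxel_grid(current)) stop("corrector must return a voxel_grid")
  }
  attr(current, "mask") <- mask
  current
}

#' Polynomial bias corrector
#'
#' Returns a corrector for [iterative_bias_correction()] that fits a
#' multiplicative low-order polynomial bias field to the log-intensities
#' inside the mask by least squares and divides it out. This is a simple
#' smooth-field corrector; dedicated B-spline correctors (N4) can be used
#' through the same contract when available.
#'
#' @param order polynomial order (1 or 2) in the physical coordinates.
#' @param eps intensities below `eps` are left untouched in the log fit.
#' @return function `(volume, mask) -> voxel_grid`.
#' @export
poly_bias_corrector <- function(order = 2L, eps = 1e-6) {
  force(order); force(eps)
  function(volume, mask) {
    stop_if_grid_mismatch(volume, mask)
    d <- dim(volume$data)
    idx <- which(mask$data == 1L & volume$data > eps, arr.ind = TRUE)
    if (nrow(idx) < 20L) stop("too few voxels in mask for polynomial fit")
    P <- voxel_centers(volume, idx)
    sc <- apply(abs(P), 2, max); sc[sc == 0] <- 1
    Ps <- sweep(P, 2, sc, "/")
    X <- poly_design(Ps, order)
    y <- log(volume$data[mask$data == 1L & volume$data > eps])
    beta <- qr.solve(qr(X), y)
    allidx <- which(array(TRUE, d), arr.ind = TRUE)
    Pa <- sweep(voxel_centers(volume, allidx), 2, sc, "/")
    logfield <- poly_design(Pa, order) %*% beta
    field <- array(exp(logfield - mean(logfield[mask$data == 1L])), d)
    voxel_grid(volume$data / field, volume$spacing, volume$origin)
  }
}

poly_design <- function(P, order) {
  x <- P[, 1L]; y <- P[, 2L]; z <- P[, 3L]
  X <- cbind(1, x, y, z)
  if (order >= 2L) X <- cbind(X, x^2, y^2, z^2, x * y, x * z, y * z)
  X
}

#' Dilate a mask by a physical-space ball
#'
#' Morphological dilation with a ball of the given radius in mm; the
#' structuring element is derived from the voxel spacing, so anisotropic
#' grids dilate by the same physical distance along every axis.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm ball radius in mm (>= 0).
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.finite(radius_mm) || radius_mm < 0) stop("'radius' must be >= 0")
  if (radius_mm == 0 || sum(mask$data) == 0L) return(mask)
  r <- ceiling(radius_mm / mask$spacing)
  offs <- as.matrix(expand.grid(dx = -r[1L]:r[1L], dy = -r[2L]:r[2L],
                                dz = -r[3L]:r[3L]))
  dist <- sqrt((offs[, 1L] * mask$spacing[1L])^2 +
               (offs[, 2L] * mask$spacing[2L])^2 +
               (offs[, 3L] * mask$spacing[3L])^2)
  offs <- offs[dist <= radius_mm + 1e-9, , drop = FALSE]
  d <- dim(mask$data)
  fg <- which(mask$data == 1L, arr.ind = TRUE)
  out <- array(0L, d)
  for (k in seq_len(nrow(offs))) {
    i <- fg[, 1L] + offs[k, 1L]
    j <- fg[, 2L] + offs[k, 2L]
    l <- fg[, 3L] + offs[k, 3L]
    ok <- i >= 1L & i <= d[1L] & j >= 1L & j <= d[2L] & l >= 1L & l <= d[3L]
    out[cbind(i[ok], j[ok], l[ok])] <- 1L
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Dice overlap between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`. When both masks are empty the Dice score
#' is defined as 1 (total-function convention).
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1)
  2 * sum(a$data == 1L & b$data == 1L) / (na + nb)
}

#' Connected components of a mask (6-connectivity)
#'
#' @param mask a [binary_mask()].
#' @return integer array of component labels (0 = background), with
#'   attribute `"sizes"` giving voxel counts per label, largest first
#'   relabelled to 1.
#' @export
mask_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  fg <- which(mask$data == 1L)
  lab <- array(0L, d)
  if (length(fg) == 0L) { attr(lab, "sizes") <- integer(0); return(lab) }
  pos <- array(0L, d); pos[fg] <- seq_along(fg)
  ai <- arrayInd(fg, d)
  edges <- list()
  for (axis in 1:3) {
    nb <- ai
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= d[axis]
    nbl <- pos[nb[ok, , drop = FALSE]]
    has <- nbl > 0L
    edges[[axis]] <- cbind(which(ok)[has], nbl[has])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  lab[fg] <- relabel[comp$membership]
  attr(lab, "sizes") <- as.integer(comp$csize[ord])
  lab
}

#' Keep the largest connected component of a mask
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] containing only the largest 6-connected
#'   foreground component.
#' @export
largest_component <- function(mask) {
  lab <- mask_components(mask)
  binary_mask(array(as.integer(lab == 1L), dim(lab)), mask$spacing,
              mask$origin)
}
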