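#' Voxel grid containers
#'
#' A `voxel_grid` holds a 3D scalar array together with its physical
#' geometry: voxel spacing in mm and the physical position of the first
#' voxel centre. The axis convention is fixed throughout the package and
#' assumes a supine subject:
#' * axis 1 (x): left-right (LR),
#' * axis 2 (y): anterior-posterior (AP), +y anterior,
#' * axis 3 (z): cranial-caudal (CC), +z cranial.
#'
#' A `binary_mask` is a `voxel_grid` whose data are restricted to 0/1.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `voxel_grid` (and `binary_mask` for
#'   [binary_mask()]).
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  g <- voxel_grid(data, spacing, origin)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask data must contain only 0 and 1")
  storage.mode(g$data) <- "integer"
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "binary_mask"))
    cat(sprintf("  foreground: %d voxels\n", sum(x$data)))
  invisible(x)
}

#' @rdname voxel_grid
#' @param x object to test.
#' @export
is_voxel_grid <- function(x) inherits(x, "voxel_grid")

# Same shape, spacing and origin (to tolerance)?
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("voxel grids do not share shape/spacing/origin")
  invisible(TRUE)
}

#' Physical coordinates of voxel centres
#'
#' @param grid a [voxel_grid()].
#' @param which integer matrix of voxel indices (n x 3); defaults to all
#'   foreground voxels for masks.
#' @return n x 3 matrix of physical mm coordinates.
#' @keywords internal
voxel_centers <- function(grid, which = NULL) {
  if (is.null(which)) {
    if (!inherits(grid, "binary_mask"))
      stop("'which' required for non-mask grids")
    which <- base::which(grid$data == 1L, arr.ind = TRUE)
  }
  sweep(sweep(which - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Ordered dynamic sequence of voxel grids
#'
#' Frames share a common grid; frame 1 is full inspiration and frame `T`
#' full expiration for the expiratory maneuver analysed here.
#'
#' @param frames list of [voxel_grid()] objects on a common grid (length >= 2).
#' @param frame_rate optional frames per second.
#' @return A `dynamic_sequence` object.
#' @export
dynamic_sequence <- function(frames, frame_rate = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames")
  lapply(frames, function(f) if (!is_voxel_grid(f)) stop("frames must be voxel grids"))
  for (i in seq_along(frames)[-1L]) stop_if_grid_mismatch(frames[[1L]], frames[[i]])
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "dynamic_sequence")
}

#' @export
length.dynamic_sequence <- function(x) length(x$frames)

#' Read a binary mask from NIfTI or MetaImage
#'
#' Non-binary data are thresholded at 0.5 with a warning. Spacing and origin
#' are taken from the file header.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.mhd`/`.mha`).
#' @param format `"auto"` (by extension), `"nifti"` or `"metaimage"`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  g <- read_volume(path, format)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1))) {
    warning("non-binary image data; thresholding at 0.5")
    g$data <- array(as.integer(g$data > 0.5), dim(g$data))
  }
  binary_mask(g$data, g$spacing, g$origin)
}

#' Read a scalar volume from NIfTI or MetaImage
#'
#' @inheritParams read_mask
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
      "metaimage" else "nifti"
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4L] == 1L) {
      img2 <- array(as.numeric(img), d[1:3])
      d <- d[1:3]
    } else if (length(d) != 3L) {
      stop("expected a 3D image, got ", length(d), " dimensions")
    } else {
      img2 <- array(as.numeric(img), d)
    }
    spacing <- RNifti::pixdim(img)[1:3]
    xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
    origin <- if (!is.null(xf) && all(dim(xf) == c(4L, 4L)))
      xf[1:3, 4L] else c(0, 0, 0)
    if (any(spacing <= 0) || any(!is.finite(spacing)))
      stop("file declares zero/negative voxel spacing")
    voxel_grid(img2, spacing, origin)
  } else {
    read_metaimage(path)
  }
}

#' Write a mask or volume
#'
#' Masks are stored as unsigned 8-bit, scalar volumes as 32-bit float.
#'
#' @param grid a [voxel_grid()] or [binary_mask()].
#' @param path output path (`.nii`, `.nii.gz`, `.mhd`).
#' @param format see [read_mask()].
#' @return `path`, invisibly.
#' @export
write_mask <- function(grid, path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
      "metaimage" else "nifti"
  }
  if (format == "nifti") {
    dat <- grid$data
    datatype <- if (inherits(grid, "binary_mask")) "uint8" else "float"
    img <- RNifti::asNifti(array(as.numeric(dat), dim(dat)))
    attr(img, "pixdim") <- grid$spacing
    xf <- diag(4)
    diag(xf)[1:3] <- grid$spacing
    xf[1:3, 4L] <- grid$origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path, datatype = datatype)
  } else {
    write_metaimage(grid, path)
  }
  invisible(path)
}

# --- MetaImage (.mhd + .raw / .mha) -----------------------------------------
# Minimal MetaImage support: 3D MET_UCHAR / MET_SHORT / MET_FLOAT / MET_DOUBLE,
# uncompressed, local byte order.

read_metaimage <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- trimws(m[3L])
  }
  ndims <- as.integer(kv[["NDims"]] %||% "3")
  if (ndims != 3L) stop("expected a 3D image, got NDims=", ndims)
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1L]])
  spacing <- as.numeric(strsplit(kv[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1L]])
  origin <- as.numeric(strsplit(kv[["Offset"]] %||% "0 0 0", "\\s+")[[1L]])
  if (any(spacing <= 0)) stop("file declares zero/negative voxel spacing")
  etype <- kv[["ElementType"]] %||% "MET_FLOAT"
  dfile <- kv[["ElementDataFile"]] %||% "LOCAL"
  n <- prod(dims)
  if (identical(dfile, "LOCAL")) stop("embedded .mha data not supported; use .mhd + .raw")
  rawpath <- file.path(dirname(path), dfile)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  dat <- switch(etype,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE)),
    MET_FLOAT = readBin(con, "double", n, size = 4L),
    MET_DOUBLE = readBin(con, "double", n, size = 8L),
    stop("unsupported ElementType: ", etype))
  voxel_grid(array(dat, dims), spacing, origin)
}

write_metaimage <- function(grid, path) {
  if (!grepl("\\.mhd$", path, ignore.case = TRUE))
    stop("MetaImage output requires a .mhd path")
  rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  is_mask <- inherits(grid, "binary_mask")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(grid$data), collapse = " ")),
           paste("ElementSpacing =", paste(grid$spacing, collapse = " ")),
           paste("Offset =", paste(grid$origin, collapse = " ")),
           paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_FLOAT"),
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (is_mask) {
    writeBin(as.raw(as.vector(grid$data)), con)
  } else {
    writeBin(as.vector(as.numeric(grid$data)), con, size = 4L)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a binary mask to a new isotropic spacing
#'
#' Nearest-neighbour resampling onto a grid with the given spacing covering
#' the same physical extent. Used by [extract_mesh()] to reach a target
#' triangle edge length.
#'
#' @param mask a [binary_mask()].
#' @param new_spacing target spacing in mm (scalar, isotropic).
#' @return A [binary_mask()].
#' @export
resample_mask <- function(mask, new_spacing) {
  stopifnot(inherits(mask, "binary_mask"), new_spacing > 0)
  d <- dim(mask$data)
  extent <- d * mask$spacing
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  # new voxel centres in old (fractional, 1-based) index space
  idx <- lapply(1:3, function(a) {
    cent <- (seq_len(nd[a]) - 0.5) * new_spacing        # mm from grid corner
    i <- round(cent / mask$spacing[a] + 0.5)
    pmin(pmax(i, 1L), d[a])
  })
  newdat <- mask$data[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  binary_mask(array(newdat, nd),
              spacing = rep(new_spacing, 3),
              origin = mask$origin - mask$spacing / 2 + new_spacing / 2)
}
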