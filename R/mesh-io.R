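#' Read and write STL surface meshes
#'
#' Binary and ASCII STL are supported. For binary STL the 2-byte
#' per-triangle attribute is returned; files following the
#' VisCAM/SolidView convention store a 15-bit colour there (bit 15 set,
#' 5 bits per channel), which can be used as a per-triangle label.
#' STL stores no connectivity, so identical vertex coordinates are merged
#' on read to recover a shared-vertex mesh.
#'
#' @param path file path.
#' @return [read_stl()]: a [surface_mesh()] with attribute `"attr_bytes"`
#'   (integer per triangle, binary STL only) and `"labels"` (decoded
#'   VisCAM colour labels, if colour bits are present).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  close(con)
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", 50L * ntri)
  dim(rec) <- c(50L, ntri)
  fl <- readBin(as.vector(rec[1:48, ]), "double", size = 4L,
                n = 12L * ntri, endian = "little")
  fl <- matrix(fl, nrow = 12L)
  tris_xyz <- t(fl[4:12, , drop = FALSE])            # skip facet normal
  att <- readBin(as.vector(rec[49:50, ]), "integer", size = 2L, n = ntri,
                 signed = FALSE, endian = "little")
  mesh <- weld_triangle_soup(tris_xyz)
  attr(mesh, "attr_bytes") <- att
  if (any(bitwAnd(att, 32768L) > 0L)) {
    # VisCAM colour: bits 0-14 = 5-bit B,G,R from LSB
    attr(mesh, "labels") <- bitwAnd(att, 32767L)
  }
  mesh
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(xyz) %% 3L != 0L) stop("malformed ASCII STL")
  tris_xyz <- matrix(t(xyz), ncol = 9L, byrow = TRUE)
  weld_triangle_soup(tris_xyz)
}

# m x 9 matrix (v1 v2 v3 coords per triangle) -> welded surface_mesh
weld_triangle_soup <- function(tris_xyz) {
  pts <- rbind(tris_xyz[, 1:3, drop = FALSE], tris_xyz[, 4:6, drop = FALSE],
               tris_xyz[, 7:9, drop = FALSE])
  key <- apply(pts, 1L, paste, collapse = "_")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  m <- nrow(tris_xyz)
  surface_mesh(verts, cbind(uid[1:m], uid[m + 1:m], uid[2 * m + 1:m]),
               validate = FALSE)
}

#' @rdname read_stl
#' @param mesh a [surface_mesh()].
#' @param labels optional integer per-triangle labels (0..32767), stored in
#'   the binary attribute word with the VisCAM colour bit set.
#' @param ascii write ASCII STL instead of binary.
#' @export
write_stl <- function(mesh, path, labels = NULL, ascii = FALSE) {
  tn <- triangle_normals(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid lungkin", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("  facet normal %g %g %g", tn[i, 1L], tn[i, 2L],
                         tn[i, 3L]), con)
      writeLines("    outer loop", con)
      for (c in 1:3)
        writeLines(sprintf("      vertex %g %g %g", v[tr[i, c], 1L],
                           v[tr[i, c], 2L], v[tr[i, c], 3L]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid lungkin", con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "lungkin binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
  att <- if (is.null(labels)) integer(nrow(tr)) else
    bitwOr(as.integer(labels), 32768L)
  for (i in seq_len(nrow(tr))) {
    writeBin(c(tn[i, ], v[tr[i, 1L], ], v[tr[i, 2L], ], v[tr[i, 3L], ]),
             con, size = 4L, endian = "little")
    writeBin(att[i], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read and write PLY meshes with per-face labels
#'
#' ASCII PLY with vertex `x y z` properties and face vertex lists; an
#' optional integer `label` face property carries partition labels.
#'
#' @param path file path.
#' @param mesh a [surface_mesh()].
#' @param labels optional integer per-triangle labels.
#' @return `read_ply()`: a [surface_mesh()] with attribute `"labels"` when
#'   present.
#' @export
write_ply <- function(mesh, path, labels = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", "comment lungkin surface partition",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(tr)),
           "property list uchar int vertex_indices")
  if (!is.null(labels)) hdr <- c(hdr, "property int label")
  writeLines(c(hdr, "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1L], v[, 2L], v[, 3L]), con)
  if (is.null(labels)) {
    writeLines(sprintf("3 %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L,
                       tr[, 3L] - 1L), con)
  } else {
    writeLines(sprintf("3 %d %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L,
                       tr[, 3L] - 1L, as.integer(labels)), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  end <- match("end_header", txt)
  if (is.na(end)) stop("not an ASCII PLY file")
  hdr <- txt[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  has_label <- any(grepl("^property int label", hdr))
  vrows <- txt[end + seq_len(nv)]
  frows <- txt[end + nv + seq_len(nf)]
  v <- do.call(rbind, lapply(strsplit(vrows, "\\s+"), function(p)
    as.numeric(p[1:3])))
  fparse <- do.call(rbind, lapply(strsplit(frows, "\\s+"), as.numeric))
  if (any(fparse[, 1L] != 3)) stop("only triangle faces supported")
  mesh <- surface_mesh(v, fparse[, 2:4, drop = FALSE] + 1L, validate = FALSE)
  if (has_label) attr(mesh, "labels") <- as.integer(fparse[, 5L])
  mesh
}
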