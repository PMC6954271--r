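#' Triangulated surface mesh
#'
#' Minimal triangle-mesh container used for reference surface areas
#' (stand-in for a structured-light 3D scan exported to a mesh tool).
#' Coordinates are millimetres.
#'
#' @param vertices Numeric matrix, n x 3.
#' @param faces Integer matrix, m x 3 of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f cm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_surface_area(x)))
  invisible(x)
}

#' Total mesh surface area
#'
#' Sum of triangle areas by the half-cross-product rule; degenerate
#' (zero-area) triangles contribute nothing. Vertex units are mm, the
#' result cm^2.
#'
#' @param mesh A [surface_mesh()].
#' @return Area in cm^2.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1, 2, 3)))
#' mesh_surface_area(m)  # 0.005 cm^2
#' @export
mesh_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2)) / 100
}

#' Read a triangulated mesh (ascii PLY / OBJ / STL)
#'
#' Minimal readers for the common ascii mesh interchange formats;
#' polygonal faces are fan-triangulated. Binary variants are not
#' supported.
#'
#' @param path Mesh file (`.ply`, `.obj` or `.stl`, ascii).
#' @return A [surface_mesh()].
#' @export
read_surface_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  switch(ext,
         ply = read_ply_ascii(lines),
         obj = read_obj_ascii(lines),
         stl = read_stl_ascii(lines),
         stop("unsupported mesh format: .", ext))
}

read_ply_ascii <- function(lines) {
  if (!grepl("^ply", lines[1L])) stop("not a PLY file")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  if (!any(grepl("format\\s+ascii", header)))
    stop("only ascii PLY is supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", header, value = TRUE)[1L]))
  body <- lines[(end + 1L):length(lines)]
  vt <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:3])))
  faces <- list()
  for (l in body[nv + seq_len(nf)]) {
    tok <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    idx <- tok[2:(1 + tok[1L])] + 1L       # PLY indices are 0-based
    for (j in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j + 1L], idx[j + 2L])
  }
  surface_mesh(vt, do.call(rbind, faces))
}

read_obj_ascii <- function(lines) {
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  vt <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4])))
  faces <- list()
  for (l in fl) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]][-1L]
    idx <- as.integer(sub("/.*", "", tok))
    for (j in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j + 1L], idx[j + 2L])
  }
  surface_mesh(vt, do.call(rbind, faces))
}

read_stl_ascii <- function(lines) {
  if (!grepl("^\\s*solid", lines[1L]))
    stop("only ascii STL is supported")
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  vt <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4])))
  if (nrow(vt) %% 3L != 0L) stop("malformed STL vertex list")
  surface_mesh(vt, matrix(seq_len(nrow(vt)), ncol = 3L, byrow = TRUE))
}

#' Write a mesh as ascii PLY
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
  invisible(path)
}

#' Icosphere mesh
#'
#' Regular icosahedron with vertices on the sphere, each face recursively
#' subdivided with new vertices re-projected to the sphere. Used as an
#' analytic-area reference mesh (area converges to `4 pi r^2` from
#' below).
#'
#' @param radius_mm Sphere radius (mm).
#' @param subdivisions Number of 4-way subdivision passes.
#' @return A [surface_mesh()].
#' @export
icosphere <- function(radius_mm = 20, subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # triangle soup subdivision; vertices re-projected each pass
  tri <- lapply(seq_len(nrow(f)), function(i) v[f[i, ], , drop = FALSE])
  for (s in seq_len(subdivisions)) {
    tri <- do.call(c, lapply(tri, function(t) {
      m12 <- (t[1L, ] + t[2L, ]) / 2
      m23 <- (t[2L, ] + t[3L, ]) / 2
      m13 <- (t[1L, ] + t[3L, ]) / 2
      list(rbind(t[1L, ], m12, m13), rbind(m12, t[2L, ], m23),
           rbind(m13, m23, t[3L, ]), rbind(m12, m23, m13))
    }))
  }
  vt <- do.call(rbind, tri)
  vt <- vt * radius_mm / sqrt(rowSums(vt^2))
  surface_mesh(vt, matrix(seq_len(nrow(vt)), ncol = 3L, byrow = TRUE))
}
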