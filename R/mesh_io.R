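#' Read a triangular mesh from PLY, OBJ or STL
#'
#' Format is chosen by extension. ASCII variants of all three formats are
#' supported; coordinates are taken to be in mm. STL carries no topology, so
#' its vertices are merged at a 1e-6 mm tolerance and the watertight flag is
#' recomputed. OBJ 1-based indices map directly onto the package's 1-based
#' faces.
#'
#' @param path mesh file path (`.ply`, `.obj`, `.stl`).
#' @return a [trimesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         stop("unknown mesh extension '.", ext, "' for ", path))
}

#' Write a triangular mesh to PLY, OBJ or STL
#'
#' ASCII output with 9 significant digits. An optional per-face scalar is
#' written to PLY as the face property `quality` (ignored by the other
#' formats).
#'
#' @param mesh a [trimesh].
#' @param path output path; extension picks the format.
#' @param per_face_scalars optional numeric vector, one value per face.
#' @export
write_mesh <- function(mesh, path, per_face_scalars = NULL) {
  if (!is.null(per_face_scalars) && length(per_face_scalars) != nrow(mesh$faces))
    stop("per_face_scalars must have one value per face")
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         ply = write_ply(mesh, path, per_face_scalars),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path),
         stop("unknown mesh extension '.", ext, "' for ", path))
  invisible(path)
}

num9 <- function(x) formatC(x, digits = 9, format = "g")

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file (missing 'ply' magic): ", path)
  if (!any(grepl("^format\\s+ascii", lines)))
    stop("only ASCII PLY is supported: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY, no end_header: ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[(hdr_end + 1):length(lines)]
  vtx <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(f) as.numeric(f[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(seq_along(fl), function(i) {
    f <- as.numeric(fl[[i]])
    if (f[1] != 3) stop("PLY face ", i, " is not a triangle (", f[1], " vertices)")
    f[2:4] + 1  # PLY is 0-based
  }))
  trimesh(vtx, faces)
}

write_ply <- function(mesh, path, per_face_scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           if (!is.null(per_face_scalars)) "property float quality",
           "end_header")
  writeLines(hdr, con)
  writeLines(paste(num9(mesh$vertices[, 1]), num9(mesh$vertices[, 2]),
                   num9(mesh$vertices[, 3])), con)
  fl <- paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  if (!is.null(per_face_scalars)) fl <- paste(fl, num9(per_face_scalars))
  writeLines(fl, con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- grep("^v\\s", lines, value = TRUE)
  ft <- grep("^f\\s", lines, value = TRUE)
  if (!length(vt) || !length(ft)) stop("malformed OBJ (no v/f records): ", path)
  vtx <- do.call(rbind, lapply(strsplit(trimws(vt), "\\s+"),
                               function(f) as.numeric(f[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(ft), "\\s+"), function(f) {
    idx <- as.integer(sub("/.*", "", f[-1]))
    if (length(idx) != 3L) stop("non-triangular OBJ face: ", paste(f, collapse = " "))
    idx
  }))
  trimesh(vtx, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", num9(mesh$vertices[, 1]), num9(mesh$vertices[, 2]),
                   num9(mesh$vertices[, 3])), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported (no 'solid' header): ", path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("malformed STL (vertex count not a multiple of 3): ", path)
  raw <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(f) as.numeric(f[2:4])))
  # merge duplicate vertices at 1e-6 mm
  key <- apply(round(raw / 1e-6) * 1e-6, 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  vtx <- raw[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  trimesh(vtx, faces)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
  writeLines("solid mesh", con)
  for (f in seq_len(nrow(F))) {
    writeLines(c(paste("facet normal", paste(num9(n[f, ]), collapse = " ")),
                 "  outer loop",
                 paste("    vertex", num9(V[F[f, 1], 1]), num9(V[F[f, 1], 2]), num9(V[F[f, 1], 3])),
                 paste("    vertex", num9(V[F[f, 2], 1]), num9(V[F[f, 2], 2]), num9(V[F[f, 2], 3])),
                 paste("    vertex", num9(V[F[f, 3], 1]), num9(V[F[f, 3], 2]), num9(V[F[f, 3], 3])),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}
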