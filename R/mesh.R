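#' Triangular surface mesh
#'
#' Minimal triangle-mesh container: vertices in mm and a face index matrix
#' (1-based). Degenerate (zero-area) faces are rejected at construction.
#'
#' @param vertices V x 3 numeric matrix, mm.
#' @param faces F x 3 integer matrix of vertex indices (1-based).
#' @return object of class `trimesh` with a `watertight` flag (every edge
#'   shared by exactly two faces).
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  a2 <- face_areas_impl(vertices, faces)
  if (any(a2 <= 0))
    stop(sum(a2 <= 0), " degenerate (zero-area) face(s); clean the mesh first")
  structure(list(vertices = vertices, faces = faces,
                 watertight = is_watertight_impl(faces)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces, %swatertight\n",
              nrow(x$vertices), nrow(x$faces), if (x$watertight) "" else "not "))
  invisible(x)
}

mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

is_watertight_impl <- function(faces) {
  e <- mesh_edge_table(faces)
  all(table(paste(e[, 1], e[, 2])) == 2L)
}

face_areas_impl <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-face triangle areas
#' @param mesh a [trimesh].
#' @return numeric vector of face areas, mm^2.
#' @export
face_areas <- function(mesh) face_areas_impl(mesh$vertices, mesh$faces)

# Flood-fill the face adjacency graph making windings consistent; returns the
# reoriented face matrix. Assumes a manifold (edge shared by <=2 faces).
orient_faces_consistently <- function(faces) {
  nf <- nrow(faces)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- mesh_edge_table(faces)
  keys <- paste(e[, 1], e[, 2])
  by_edge <- split(rep(seq_len(nf), 3L), keys)
  out <- faces
  seen <- logical(nf)
  for (start in seq_len(nf)) {
    if (seen[start]) next
    seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      f <- queue[[1L]]; queue <- queue[-1L]
      tri <- out[f, ]
      dir_edges <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
      for (k in 1:3) {
        ab <- dir_edges[k, ]
        nb <- setdiff(by_edge[[ekey(ab[1], ab[2])]], f)
        for (g in nb) {
          if (seen[g]) next
          tg <- out[g, ]
          g_edges <- rbind(tg[c(1, 2)], tg[c(2, 3)], tg[c(3, 1)])
          # consistent orientation: neighbour must traverse the shared edge
          # in the opposite direction
          same_dir <- any(g_edges[, 1] == ab[1] & g_edges[, 2] == ab[2])
          if (same_dir) out[g, ] <- tg[c(1, 3, 2)]
          seen[g] <- TRUE
          queue <- c(queue, g)
        }
      }
    }
  }
  out
}

#' Enclosed volume of a watertight mesh
#'
#' Signed divergence-theorem (summed tetrahedron) volume with the face
#' orientation repaired to be globally consistent and outward; returned
#' positive, converted from mm^3 to cubic centimetres.
#'
#' @param mesh a watertight [trimesh].
#' @return volume in cc.
#' @export
mesh_volume <- function(mesh) {
  if (!mesh$watertight) {
    e <- mesh_edge_table(mesh$faces)
    nb <- table(paste(e[, 1], e[, 2]))
    stop("mesh is not watertight (", sum(nb != 2L), " boundary/non-manifold edges)")
  }
  F <- orient_faces_consistently(mesh$faces)
  abs(signed_volume(mesh$vertices, F)) / 1000
}

signed_volume <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Closest point on each triangle (rows of A,B,C) to a single point p.
# Candidate-based: clamped barycentric plane projection plus the three clamped
# edge projections; the nearest candidate per triangle wins. Robust to sliver
# triangles at the cost of a few extra flops.
closest_point_on_triangles <- function(p, A, B, C) {
  seg_closest <- function(P0, P1) {
    d <- P1 - P0
    t <- rowSums(sweep(-P0, 2L, -p) * d) / pmax(rowSums(d^2), .Machine$double.eps)
    P0 + pmin(pmax(t, 0), 1) * d
  }
  ab <- B - A; ac <- C - A
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  nn <- pmax(rowSums(n^2), .Machine$double.eps)
  ap <- sweep(-A, 2L, -p)                       # p - A per triangle
  proj <- ap - (rowSums(ap * n) / nn) * n       # plane projection rel. to A
  d00 <- rowSums(ab^2); d01 <- rowSums(ab * ac); d11 <- rowSums(ac^2)
  d20 <- rowSums(proj * ab); d21 <- rowSums(proj * ac)
  den <- pmax(d00 * d11 - d01^2, .Machine$double.eps)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- v >= 0 & w >= 0 & (v + w) <= 1
  cand <- list(A + v * ab + w * ac, seg_closest(A, B), seg_closest(B, C),
               seg_closest(C, A))
  d2 <- vapply(cand, function(q) rowSums(sweep(q, 2L, p)^2), numeric(nrow(A)))
  d2[!inside, 1L] <- Inf
  pick <- max.col(-d2, ties.method = "first")
  out <- cand[[2L]]
  for (k in c(1L, 3L, 4L)) {
    sel <- pick == k
    if (any(sel)) out[sel, ] <- cand[[k]][sel, , drop = FALSE]
  }
  out
}

#' Project points to the nearest point on a mesh surface
#'
#' @param mesh a [trimesh].
#' @param points M x 3 matrix.
#' @return M x 3 matrix of surface points.
#' @export
project_to_mesh <- function(mesh, points) {
  points <- as.matrix(points)
  if (!nrow(mesh$faces)) stop("empty mesh")
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  out <- matrix(NA_real_, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    q <- closest_point_on_triangles(points[i, ], A, B, C)
    d2 <- rowSums(sweep(q, 2L, points[i, ])^2)
    out[i, ] <- q[which.min(d2), ]
  }
  if (any(!is.finite(out))) stop("non-finite projection result")
  out
}

# Area-weighted vertex normals; for a watertight mesh the orientation is
# repaired and flipped outward (positive signed volume).
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- orient_faces_consistently(mesh$faces)
  if (mesh$watertight && signed_volume(V, F) < 0) F <- F[, c(1, 3, 2)]
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- matrix(0, nrow(V), 3L)
  for (k in 1:3) {
    idx <- F[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(V))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(V))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(V))
  }
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Construct an icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; a standard watertight test
#' surface and the base shell of the synthetic cranium generator.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (default 3).
#' @param center length-3 centre.
#' @return a watertight [trimesh].
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (V[i, ] + V[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      id <- nv + length(newV)
      mid_cache[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c3 <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c3, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  trimesh(sweep(V * radius, 2L, -center), F)
}
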