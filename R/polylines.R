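#' Define the slicing frame for contour polylines
#'
#' The slicing axis is the maximum-cranial-length chord from glabella to
#' opisthocranion; cutting planes are perpendicular to it, spaced evenly and
#' starting at the opisthocranion (offset 0), walking toward the glabella. The
#' final plane is the largest offset not exceeding the chord length.
#' Optionally the specimen is first rigidly registered onto a reference via
#' the midsagittal landmark triple (glabella, bregma, lambda).
#'
#' @param config [landmark_config] containing `glabella` and `opisthocranion`
#'   (and the midline triple if `reference` is given).
#' @param spacing plane spacing in mm (default 2.0).
#' @param reference optional [landmark_config] whose midsagittal triple the
#'   specimen is aligned onto (rotation + translation).
#' @param midline_names landmarks used for the reference alignment.
#' @return list of class `slicing_frame`: `axis` (unit vector
#'   glabella -> opisthocranion), `origin` (opisthocranion), `offsets` (mm
#'   from the opisthocranion toward the glabella), `chord` (mm), `transform`
#'   (the rigid pre-alignment, or `NULL`).
#' @export
define_slicing_frame <- function(config, spacing = 2.0,
                                 reference = NULL,
                                 midline_names = c("glabella", "bregma", "lambda")) {
  stopifnot(spacing > 0)
  transform <- NULL
  if (!is.null(reference)) {
    tri <- subset_config(config, midline_names)
    tri_ref <- subset_config(reference, midline_names)
    transform <- opa_align(tri, tri_ref, allow_scaling = FALSE)$transform
    config <- apply_transform(transform, config)
  }
  g <- unname(config$coords[match("glabella", config$landmark_names), ])
  o <- unname(config$coords[match("opisthocranion", config$landmark_names), ])
  if (anyNA(g) || anyNA(o)) stop("glabella and opisthocranion are required")
  chord <- sqrt(sum((o - g)^2))
  if (chord < 1e-9) stop("glabella and opisthocranion coincide")
  axis <- (o - g) / chord
  offsets <- seq(0, chord, by = spacing)
  structure(list(axis = axis, origin = o, offsets = offsets, chord = chord,
                 spacing = spacing, transform = transform),
            class = "slicing_frame")
}

# Intersect a mesh with the plane { p : (p - point) . normal = 0 }.
# Returns a list of polylines (each an ordered k x 3 matrix) with a `closed`
# attribute. Chains are matched exactly through shared mesh edges.
mesh_plane_section <- function(mesh, point, normal) {
  V <- mesh$vertices; F <- mesh$faces
  d <- as.numeric(sweep(V, 2L, point) %*% normal)
  d[abs(d) < 1e-12] <- 1e-12   # nudge vertices off the plane
  s <- matrix(d[F], ncol = 3L)
  crossing <- which(apply(s, 1L, function(r) min(r) < 0 && max(r) > 0))
  if (!length(crossing)) return(list())
  edge_pts <- new.env(hash = TRUE)
  face_edges <- vector("list", length(crossing))
  for (i in seq_along(crossing)) {
    f <- F[crossing[i], ]
    df <- d[f]
    pairs <- list(c(1, 2), c(2, 3), c(3, 1))
    keys <- character(0)
    for (pr in pairs) {
      a <- f[pr[1]]; b <- f[pr[2]]
      if (sign(d[a]) == sign(d[b])) next
      lo <- min(a, b); hi <- max(a, b)
      key <- paste(lo, hi)
      if (is.null(edge_pts[[key]])) {
        t <- d[lo] / (d[lo] - d[hi])
        edge_pts[[key]] <- V[lo, ] + t * (V[hi, ] - V[lo, ])
      }
      keys <- c(keys, key)
    }
    face_edges[[i]] <- keys
  }
  # adjacency between intersected edges via faces
  adj <- new.env(hash = TRUE)
  push <- function(a, b) {
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (k in face_edges) if (length(k) == 2L) push(k[1], k[2])
  all_keys <- unique(unlist(face_edges))
  visited <- new.env(hash = TRUE)
  polylines <- list()
  deg <- vapply(all_keys, function(k) length(adj[[k]]), integer(1))
  for (start in c(all_keys[deg < 2L], all_keys)) {   # open chains first
    if (!is.null(visited[[start]])) next
    chain <- start; visited[[start]] <- TRUE
    prev <- NA_character_; cur <- start
    repeat {
      nxt <- setdiff(adj[[cur]], c(prev, NA_character_))
      nxt <- nxt[vapply(nxt, function(k) is.null(visited[[k]]), logical(1))]
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[[1L]]
      visited[[cur]] <- TRUE
      chain <- c(chain, cur)
    }
    closed <- length(chain) > 2L && start %in% adj[[cur]]
    pts <- do.call(rbind, lapply(chain, function(k) edge_pts[[k]]))
    if (closed) pts <- rbind(pts, pts[1L, ])
    if (nrow(pts) >= 3L) {
      attr(pts, "closed") <- closed
      polylines[[length(polylines) + 1L]] <- pts
    }
  }
  polylines
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# Area of a closed planar polygon embedded in 3D (first == last row).
polygon_area3d <- function(pts) {
  p0 <- pts[1L, ]
  v <- sweep(pts[-nrow(pts), , drop = FALSE], 2L, p0)
  cr <- c(0, 0, 0)
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    cr <- cr + c(a[2] * b[3] - a[3] * b[2],
                 a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
  }
  sqrt(sum(cr^2)) / 2
}

#' Generate contour polylines on equidistant parallel planes
#'
#' Slices the mesh with the planes of a [define_slicing_frame()] frame and
#' chains the triangle-plane intersections into polygons. On a watertight
#' mesh every polygon is closed; open meshes may yield open chains, which are
#' returned flagged (with a warning).
#'
#' @param mesh a [trimesh].
#' @param frame a `slicing_frame`.
#' @param min_vertices polygons with fewer vertices are discarded (default 3).
#' @return list of class `contour_polylines`; one element per plane with
#'   `offset_mm` and `polygons`, each polygon carrying `vertices` (k x 3),
#'   `perimeter_mm`, `centroid`, `closed` and (for closed polygons)
#'   `area_mm2`.
#' @export
generate_polylines <- function(mesh, frame, min_vertices = 3L) {
  out <- vector("list", length(frame$offsets))
  any_open <- FALSE
  for (i in seq_along(frame$offsets)) {
    pt <- frame$origin - frame$offsets[i] * frame$axis
    polys <- mesh_plane_section(mesh, pt, frame$axis)
    polys <- Filter(function(p) nrow(p) - isTRUE(attr(p, "closed")) >= min_vertices,
                    polys)
    out[[i]] <- list(offset_mm = frame$offsets[i],
                     polygons = lapply(polys, function(p) {
                       closed <- isTRUE(attr(p, "closed"))
                       if (!closed) any_open <<- TRUE
                       list(vertices = unname(p),
                            perimeter_mm = polyline_length(p),
                            centroid = colMeans(p[seq_len(nrow(p) - closed), , drop = FALSE]),
                            closed = closed,
                            area_mm2 = if (closed) polygon_area3d(p) else NA_real_)
                     }))
  }
  if (any_open) warning("open section chains returned (mesh is not watertight)")
  structure(out, class = "contour_polylines")
}

#' @export
print.contour_polylines <- function(x, ...) {
  np <- vapply(x, function(s) length(s$polygons), integer(1))
  cat(sprintf("<contour_polylines> %d planes, %d polygons total\n",
              length(x), sum(np)))
  invisible(x)
}

#' Write contour polylines to JSON
#'
#' @param sections a `contour_polylines` object.
#' @param path output JSON path.
#' @export
write_polylines_json <- function(sections, path) {
  payload <- lapply(unclass(sections), function(s)
    list(offset_mm = s$offset_mm,
         polygons = lapply(s$polygons, function(p)
           list(vertices = apply(p$vertices, 1L, function(r) r, simplify = FALSE),
                perimeter_mm = p$perimeter_mm, closed = p$closed))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 9)
  invisible(path)
}
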