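#' Mean shape of a group of aligned configurations
#'
#' Coordinate-wise mean over the configurations carrying the requested label.
#' The configurations must already be superimposed (e.g. [gpa()] output or a
#' [shape_space()] `$aligned` list).
#'
#' @param aligned_configs list of superimposed [landmark_config]s.
#' @param labels character vector of group labels, one per configuration.
#' @param group the label to average.
#' @return a [landmark_config] named after the group.
#' @export
group_mean_shape <- function(aligned_configs, labels, group) {
  stopifnot(length(aligned_configs) == length(labels))
  idx <- which(labels == group)
  if (!length(idx)) stop("unknown group label: ", group)
  m <- Reduce(`+`, lapply(aligned_configs[idx], function(cf) cf$coords)) / length(idx)
  out <- set_coords(aligned_configs[[idx[1L]]], m)
  out$specimen_id <- paste0("mean_", group)
  out
}

#' Convert a semilandmark configuration to a triangular mesh
#'
#' Builds a mesh whose vertices are the configuration points and whose faces
#' come from a fixed triangulation template, so that meshes built from
#' homologous configurations share their topology exactly.
#'
#' @param config a [landmark_config], [semilandmark_set] (its points are
#'   `rbind(fixed, semis)`), or bare point matrix.
#' @param triangulation_template F x 3 integer matrix of 1-based indices into
#'   the configuration points.
#' @return a [trimesh].
#' @export
config_to_mesh <- function(config, triangulation_template) {
  pts <- if (inherits(config, "landmark_config")) config$coords
    else if (inherits(config, "semilandmark_set")) all_points(config)
    else as.matrix(config)
  tpl <- as.matrix(triangulation_template)
  if (any(tpl < 1L) || any(tpl > nrow(pts)))
    stop("triangulation template indexes points outside the configuration")
  trimesh(pts, tpl)
}

#' Per-facet local expansion/contraction between two topology-matched meshes
#'
#' For each facet, the signed relative area change of `mesh_b` with respect to
#' `mesh_a`: `(area_b - area_a) / area_a`. Positive values mean the region is
#' locally expanded in `b`, negative locally contracted.
#'
#' @param mesh_a,mesh_b [trimesh]es with identical face lists (built from one
#'   triangulation template).
#' @return list with `values` (per-facet) and `summary` (mean, sd, min, max),
#'   plus a `direction` note recording the sign convention.
#' @export
local_mesh_diff <- function(mesh_a, mesh_b) {
  if (!identical(dim(mesh_a$faces), dim(mesh_b$faces)) ||
      !all(mesh_a$faces == mesh_b$faces))
    stop("meshes do not share their triangulation (topology mismatch)")
  aa <- face_areas(mesh_a); ab <- face_areas(mesh_b)
  v <- (ab - aa) / aa
  list(values = v,
       summary = c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v)),
       direction = "(b - a) / a; positive = locally expanded in b")
}

#' Midsagittal profile polyline of a surface
#'
#' Intersects the mesh with the midsagittal plane, keeps the section chain
#' running from the start landmark to the end point, and resamples it to `n`
#' points equally spaced in arc length (first point at the start, last at the
#' end).
#'
#' @param mesh a [trimesh].
#' @param start length-3 start point (e.g. lambda), on or near the section.
#' @param end length-3 end point (e.g. the midpoint of the inferior nuchal
#'   line landmarks).
#' @param plane list with `point` and unit `normal` defining the midsagittal
#'   plane (e.g. from the configuration's midline landmarks).
#' @param n_points number of output points (default 30).
#' @return n x 3 matrix of profile points.
#' @export
midsagittal_profile <- function(mesh, start, end, plane, n_points = 30L) {
  chains <- mesh_plane_section(mesh, plane$point, plane$normal)
  if (!length(chains)) stop("midsagittal plane does not intersect the mesh")
  best <- NULL
  for (ch in chains) {
    a <- polyline_closest(ch, start); b <- polyline_closest(ch, end)
    score <- a$dist + b$dist
    if (is.null(best) || score < best$score)
      best <- list(chain = ch, a = a, b = b, score = score)
  }
  ch <- best$chain
  span <- max(stats::dist(rbind(start, end)), polyline_length(ch) / 4)
  if (best$a$dist > 0.1 * span || best$b$dist > 0.1 * span)
    stop("start/end points do not lie on the midsagittal section")
  seg <- extract_subpolyline(ch, best$a, best$b,
                             closed = isTRUE(attr(ch, "closed")))
  seg[1L, ] <- start
  seg[nrow(seg), ] <- end
  resample_polyline(seg, n_points)
}

# Closest point on a polyline to p: distance, arc-length position, the point,
# and its segment index.
polyline_closest <- function(pts, p) {
  P0 <- pts[-nrow(pts), , drop = FALSE]
  P1 <- pts[-1L, , drop = FALSE]
  d <- P1 - P0
  len2 <- pmax(rowSums(d^2), .Machine$double.eps)
  t <- pmin(pmax(rowSums(sweep(-P0, 2L, -p) * d) / len2, 0), 1)
  q <- P0 + t * d
  d2 <- rowSums(sweep(q, 2L, p)^2)
  i <- which.min(d2)
  s0 <- c(0, cumsum(sqrt(len2)))
  list(dist = sqrt(d2[i]), seg = i, t = t[i], point = q[i, ],
       s = s0[i] + t[i] * sqrt(len2[i]), total = s0[length(s0)])
}

# Sub-polyline between two closest-point records; for a closed chain the
# shorter of the two arcs is taken. Runs from `a` to `b`.
extract_subpolyline <- function(pts, a, b, closed) {
  k <- nrow(pts)
  forward <- function(a, b) {
    mid <- if (a$seg + 1L <= b$seg) pts[(a$seg + 1L):b$seg, , drop = FALSE]
    rbind(a$point, mid, b$point)
  }
  if (!closed) {
    if (a$s <= b$s) return(forward(a, b))
    seg <- forward(b, a)
    return(seg[rev(seq_len(nrow(seg))), , drop = FALSE])
  }
  L <- a$total
  fwd_len <- (b$s - a$s) %% L
  if (fwd_len <= L - fwd_len) {
    if (a$s <= b$s) return(forward(a, b))
    # wrap past the duplicated closing vertex (row k == row 1)
    mid1 <- if (a$seg + 1L <= k - 1L) pts[(a$seg + 1L):(k - 1L), , drop = FALSE]
    mid2 <- if (b$seg >= 1L) pts[seq_len(b$seg), , drop = FALSE]
    return(rbind(a$point, mid1, mid2, b$point))
  }
  seg <- extract_subpolyline(pts, b, a, closed = TRUE)
  seg[rev(seq_len(nrow(seg))), , drop = FALSE]
}

# Arc-length resampling of an ordered polyline to n equidistant points.
resample_polyline <- function(pts, n) {
  stopifnot(n >= 2L, nrow(pts) >= 2L)
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    i <- findInterval(target[k], s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(seglen))
    t <- (target[k] - s[i]) / max(seglen[i], .Machine$double.eps)
    out[k, ] <- pts[i, ] + t * (pts[i + 1L, ] - pts[i, ])
  }
  out
}

#' Angle at lambda between the two lambda-to-asterion chords
#'
#' @param config [landmark_config] with landmarks `lambda`, `asterion_L`,
#'   `asterion_R`.
#' @return angle in degrees, in (0, 180).
#' @export
lambda_asteria_angle <- function(config) {
  get <- function(nm) {
    i <- match(nm, config$landmark_names)
    if (is.na(i) || config$missing[i]) stop("landmark missing: ", nm)
    config$coords[i, ]
  }
  l <- get("lambda")
  v1 <- get("asterion_L") - l; v2 <- get("asterion_R") - l
  ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Maximum cranial breadth relative to the midsagittal plane
#'
#' The maximum extent of the mesh measured along the midsagittal plane
#' normal: the largest difference of signed vertex distances, with the two
#' achieving vertices returned.
#'
#' @param mesh a [trimesh].
#' @param plane list with `point` and unit `normal` (the midsagittal plane).
#' @return list with `breadth_mm`, `point_left`, `point_right`.
#' @export
max_cranial_breadth <- function(mesh, plane) {
  if (!nrow(mesh$vertices)) stop("empty mesh")
  d <- as.numeric(sweep(mesh$vertices, 2L, plane$point) %*% plane$normal)
  i <- which.max(d); j <- which.min(d)
  list(breadth_mm = d[i] - d[j],
       point_left = mesh$vertices[i, ], point_right = mesh$vertices[j, ])
}
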