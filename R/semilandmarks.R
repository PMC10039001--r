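#' Fixed landmarks plus surface semilandmarks
#'
#' A fixed (anatomical) landmark configuration together with a set of surface
#' semilandmarks constrained to lie on a host mesh. Semilandmarks carry no
#' point-wise homology of their own; they are made comparable across
#' specimens by projection and sliding.
#'
#' @param fixed a [landmark_config] of anatomical landmarks.
#' @param semis S x 3 matrix of surface semilandmark coordinates, mm.
#' @param host_mesh optional [trimesh] the semis lie on; when given, each
#'   semilandmark must be within `tol` of the surface.
#' @param provenance `"template"`, `"projected"` or `"slid"`.
#' @param tol surface tolerance, mm (default 1e-6).
#' @return object of class `semilandmark_set`.
#' @export
semilandmark_set <- function(fixed, semis, host_mesh = NULL,
                             provenance = c("template", "projected", "slid"),
                             tol = 1e-6) {
  provenance <- match.arg(provenance)
  semis <- as.matrix(semis)
  stopifnot(inherits(fixed, "landmark_config"), ncol(semis) == 3L)
  if (!is.null(host_mesh)) {
    p <- project_to_mesh(host_mesh, semis)
    off <- sqrt(max(rowSums((p - semis)^2)))
    if (off > tol)
      stop(sprintf("semilandmark off the host surface by %.3g mm (tol %.3g)", off, tol))
  }
  structure(list(fixed = fixed, semis = semis, provenance = provenance),
            class = "semilandmark_set")
}

#' @export
print.semilandmark_set <- function(x, ...) {
  cat(sprintf("<semilandmark_set> %d fixed + %d surface semilandmarks (%s)\n",
              nrow(x$fixed$coords), nrow(x$semis), x$provenance))
  invisible(x)
}

# Stacked fixed + semilandmark coordinates.
all_points <- function(set) unname(rbind(set$fixed$coords, set$semis))

#' Transfer template surface semilandmarks onto a target specimen
#'
#' Maps the template's semilandmarks through the TPS defined by the fixed
#' landmarks (template -> target) and projects each mapped point to the
#' nearest point on the target surface.
#'
#' @param template a [semilandmark_set] on the template specimen.
#' @param template_mesh the template's [trimesh] (unused by the mapping but
#'   accepted for interface symmetry / validation).
#' @param target_mesh the target's [trimesh].
#' @param target_fixed [landmark_config] of the target's fixed landmarks,
#'   homologous to `template$fixed`.
#' @return a [semilandmark_set] on the target, provenance `"projected"`.
#' @export
project_surface_semilandmarks <- function(template, template_mesh, target_mesh,
                                          target_fixed) {
  if (!identical(template$fixed$landmark_names, target_fixed$landmark_names))
    stop("template and target fixed landmarks are not homologous")
  tps <- tps_fit(template$fixed$coords, target_fixed$coords)
  mapped <- tps_warp(tps, template$semis)
  on_surface <- project_to_mesh(target_mesh, mapped)
  semilandmark_set(target_fixed, on_surface, host_mesh = target_mesh,
                   provenance = "projected")
}

# Nearest face index per point (for tangent planes).
nearest_face <- function(mesh, points) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  vapply(seq_len(nrow(points)), function(i) {
    q <- closest_point_on_triangles(points[i, ], A, B, C)
    which.min(rowSums(sweep(q, 2L, points[i, ])^2))
  }, integer(1))
}

face_unit_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

# Bending energy of the TPS mapping the reference set onto points Y,
# computed from the reference's bending-energy matrix B: sum_d y_d' B y_d.
semiland_energy <- function(B, Y) sum(vapply(1:3, function(d)
  as.numeric(t(Y[, d]) %*% B %*% Y[, d]), numeric(1)))

#' Slide surface semilandmarks to minimize bending energy
#'
#' Tangent-plane linearized sliding: each semilandmark may move within the
#' tangent plane of the surface at its current position; the displacements
#' minimizing the thin-plate-spline bending energy towards the reference
#' configuration are solved in closed form, the points are re-projected onto
#' the surface, and the step repeats. Iteration stops early (returning the
#' best configuration, with a warning) if the energy increases twice in a
#' row.
#'
#' @param set [semilandmark_set] to slide (fixed landmarks stay put).
#' @param host_mesh the [trimesh] the semis slide on.
#' @param reference [semilandmark_set] defining the bending-energy metric
#'   (e.g. the template).
#' @param iterations number of slide/re-project cycles (default 3).
#' @return a [semilandmark_set], provenance `"slid"`, with attribute
#'   `energy_trace` (bending energy before and after each iteration).
#' @export
slide_semilandmarks <- function(set, host_mesh, reference, iterations = 3L) {
  if (nrow(set$semis) != nrow(reference$semis) ||
      nrow(set$fixed$coords) != nrow(reference$fixed$coords))
    stop("set and reference sizes differ")
  ref_pts <- all_points(reference)
  B <- bending_energy_matrix(ref_pts)
  nf <- nrow(set$fixed$coords); ns <- nrow(set$semis)
  semi_rows <- nf + seq_len(ns)
  fn <- face_unit_normals(host_mesh)
  Y <- all_points(set)
  energy <- semiland_energy(B, Y)
  trace <- energy
  best <- list(Y = Y, energy = energy)
  increases <- 0L
  for (it in seq_len(iterations)) {
    normals <- fn[nearest_face(host_mesh, Y[semi_rows, , drop = FALSE]), , drop = FALSE]
    # orthonormal tangent basis per semilandmark
    t1 <- cbind(-normals[, 2], normals[, 1], 0)
    small <- rowSums(t1^2) < 1e-12
    t1[small, ] <- cbind(1, 0, 0)[rep(1, sum(small)), , drop = FALSE]
    t1 <- t1 - rowSums(t1 * normals) * normals
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(normals[, 2] * t1[, 3] - normals[, 3] * t1[, 2],
                normals[, 3] * t1[, 1] - normals[, 1] * t1[, 3],
                normals[, 1] * t1[, 2] - normals[, 2] * t1[, 1])
    # design: columns are the effect of each tangent coefficient on the
    # stacked (x,y,z) coordinate vector
    n_all <- nf + ns
    Tm <- matrix(0, 3L * n_all, 2L * ns)
    for (i in seq_len(ns)) {
      r <- semi_rows[i]
      for (d in 1:3) {
        Tm[(d - 1L) * n_all + r, 2L * i - 1L] <- t1[i, d]
        Tm[(d - 1L) * n_all + r, 2L * i] <- t2[i, d]
      }
    }
    B3 <- kronecker(diag(3), B)
    y0 <- as.numeric(Y)           # column-major: x block, y block, z block
    A <- crossprod(Tm, B3 %*% Tm)
    b <- crossprod(Tm, B3 %*% y0)
    tcoef <- tryCatch(solve(A + diag(1e-10 * max(diag(A)), ncol(A)), -b),
                      error = function(e) rep(0, ncol(A)))
    Ynew <- Y
    delta <- matrix(as.numeric(Tm %*% tcoef), ncol = 3L)
    Ynew[semi_rows, ] <- Y[semi_rows, ] + delta[semi_rows, ]
    Ynew[semi_rows, ] <- project_to_mesh(host_mesh, Ynew[semi_rows, , drop = FALSE])
    e_new <- semiland_energy(B, Ynew)
    trace <- c(trace, e_new)
    if (e_new < best$energy) best <- list(Y = Ynew, energy = e_new)
    increased <- e_new > energy + max(1e-12, 1e-9 * abs(energy))
    increases <- if (increased) increases + 1L else 0L
    Y <- Ynew; energy <- e_new
    if (increases >= 2L) {
      warning("bending energy increased twice; returning best configuration")
      Y <- best$Y
      break
    }
  }
  Y <- best$Y
  out <- semilandmark_set(set$fixed, Y[semi_rows, , drop = FALSE],
                          host_mesh = host_mesh, provenance = "slid",
                          tol = 1e-5)
  attr(out, "energy_trace") <- trace
  out
}

#' Estimate cranial capacity by warping a reference endocast
#'
#' Fits the TPS mapping the reference specimen's landmark (and, by default,
#' semilandmark) configuration onto the target's, warps the reference
#' endocast mesh through it, and returns the warped mesh volume.
#'
#' @param reference_endocast watertight [trimesh] of the reference endocast,
#'   in the reference specimen's frame.
#' @param reference_set [semilandmark_set] on the reference specimen.
#' @param target_set [semilandmark_set] on the target, homologous to
#'   `reference_set`.
#' @param use_semis include the semilandmarks in the TPS (default `TRUE`);
#'   `FALSE` uses the fixed landmarks only.
#' @return estimated capacity in cc; the warped endocast is attached as
#'   attribute `warped_endocast`.
#' @export
estimate_capacity <- function(reference_endocast, reference_set, target_set,
                              use_semis = TRUE) {
  if (!identical(reference_set$fixed$landmark_names,
                 target_set$fixed$landmark_names))
    stop("reference and target fixed landmarks are not homologous")
  src <- if (use_semis) all_points(reference_set) else reference_set$fixed$coords
  dst <- if (use_semis) all_points(target_set) else target_set$fixed$coords
  if (nrow(src) != nrow(dst)) stop("semilandmark counts differ")
  tps <- tps_fit(src, dst)
  warped <- reference_endocast
  warped$vertices <- tps_warp(tps, warped$vertices)
  vol <- mesh_volume(warped)
  attr(vol, "warped_endocast") <- warped
  vol
}
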