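#' Fit a 3D thin-plate spline
#'
#' Fits the interpolating 3D spline mapping `source` landmarks exactly onto
#' `target` landmarks, with the radial kernel U(r) = r (the standard 3D
#' spline kernel of geometric-morphometric software). The model splits into an
#' affine part and non-affine weights satisfying the usual side conditions
#' (weights orthogonal to constants and to the source coordinates).
#'
#' @param source,target N x 3 matrices or [landmark_config]s (same landmarks,
#'   none missing); at least 5 non-coplanar points.
#' @param lambda optional smoothing parameter (0 = exact interpolation).
#' @return object of class `tps_model`.
#' @export
tps_fit <- function(source, target, lambda = 0) {
  nm <- NULL
  if (inherits(source, "landmark_config")) { nm <- source$landmark_names; source <- source$coords }
  if (inherits(target, "landmark_config")) target <- target$coords
  X <- as.matrix(source); Y <- as.matrix(target)
  n <- nrow(X)
  if (!identical(dim(X), dim(Y))) stop("source and target dimensions differ")
  if (n < 5L) stop("TPS needs at least 5 landmarks")
  D <- as.matrix(stats::dist(X))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup)) {
    lab <- if (is.null(nm)) apply(dup, 1L, paste, collapse = "/")
           else paste(nm[dup[, 1]], nm[dup[, 2]], sep = "/")
    stop("duplicate source landmarks make the TPS system singular: ",
         paste(lab, collapse = ", "))
  }
  K <- D + diag(lambda, n)
  P <- cbind(1, X)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  sol <- solve(L, rbind(Y, matrix(0, 4L, 3L)))
  structure(list(source = X, weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE],
                 kernel = "U(r)=r", lambda = lambda),
            class = "tps_model")
}

#' Evaluate a thin-plate-spline warp at points
#'
#' @param model a [tps_model] from [tps_fit()].
#' @param points M x 3 matrix (or [landmark_config]) of probe points.
#' @return warped M x 3 matrix (or warped configuration).
#' @export
tps_warp <- function(model, points) {
  if (inherits(points, "landmark_config"))
    return(set_coords(points, tps_warp(model, points$coords)))
  if (inherits(points, "trimesh")) {
    out <- points
    out$vertices <- tps_warp(model, points$vertices)
    return(out)
  }
  P <- as.matrix(points)
  # distances computed difference-first per source landmark: no cancellation
  # near the landmarks, so interpolation holds to ~1e-12 mm
  U <- matrix(0, nrow(P), nrow(model$source))
  for (j in seq_len(nrow(model$source)))
    U[, j] <- sqrt((P[, 1] - model$source[j, 1])^2 +
                   (P[, 2] - model$source[j, 2])^2 +
                   (P[, 3] - model$source[j, 3])^2)
  cbind(1, P) %*% model$affine + U %*% model$weights
}

#' Bending energy of a fitted thin-plate spline
#'
#' The non-affine deformation energy, summed over the three coordinate
#' directions: `sum_dim t(w) K w`. Zero iff the target is an affine image of
#' the source.
#'
#' @param model a [tps_model].
#' @return non-negative scalar.
#' @export
tps_bending_energy <- function(model) {
  # with kernel U(r) = r the form w'Kw is conditionally negative definite on
  # the side-condition subspace; the physical bending energy is its negative
  K <- as.matrix(stats::dist(model$source))
  -sum(diag(t(model$weights) %*% K %*% model$weights))
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("<tps_model> %d landmarks, kernel %s, bending energy %.4g\n",
              nrow(x$source), x$kernel, tps_bending_energy(x)))
  invisible(x)
}

# Bending-energy matrix of a source configuration: the negated upper-left
# n x n block of L^{-1} (positive semidefinite for kernel U(r) = r), so that
# the energy of targets y is t(y) B y per dimension.
bending_energy_matrix <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- as.matrix(stats::dist(X))
  P <- cbind(1, X)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Li <- solve(L)
  B <- -Li[seq_len(n), seq_len(n), drop = FALSE]
  (B + t(B)) / 2
}

#' Estimate missing landmarks from a complete reference
#'
#' Registers the complete reference onto the target over their shared
#' non-missing landmarks (ordinary Procrustes with scaling), fits a TPS from
#' the registered reference to the target on those landmarks, and maps the
#' reference's positions of the target's missing landmarks through the spline.
#' Estimated landmarks are flagged in the returned configuration.
#'
#' @param partial_target [landmark_config] with missing landmarks.
#' @param full_reference complete [landmark_config]; its landmark set must
#'   contain all of the target's names.
#' @return the completed [landmark_config] (missing mask cleared, `estimated`
#'   flags set on filled landmarks).
#' @export
estimate_missing_landmarks <- function(partial_target, full_reference) {
  if (any(full_reference$missing)) stop("reference must be complete")
  if (!all(partial_target$landmark_names %in% full_reference$landmark_names))
    stop("reference lacks landmarks: ",
         paste(setdiff(partial_target$landmark_names,
                       full_reference$landmark_names), collapse = ", "))
  if (!any(partial_target$missing)) return(partial_target)
  ref <- subset_config(full_reference, partial_target$landmark_names)
  shared <- !partial_target$missing
  if (sum(shared) < 5L) stop("need at least 5 shared non-missing landmarks")
  fit <- opa_align(ref, partial_target, allow_scaling = TRUE)
  refA <- fit$aligned$coords
  tps <- tps_fit(refA[shared, , drop = FALSE],
                 partial_target$coords[shared, , drop = FALSE])
  est <- tps_warp(tps, refA[!shared, , drop = FALSE])
  co <- partial_target$coords
  co[!shared, ] <- est
  set_coords(partial_target, co, missing = rep(FALSE, nrow(co)),
             estimated = partial_target$estimated | !shared)
}
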