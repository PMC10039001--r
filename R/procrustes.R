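#' Similarity transform (rotation + translation + scale)
#'
#' @param rotation 3 x 3 proper rotation matrix (det +1).
#' @param translation length-3 numeric vector, mm.
#' @param scale positive scalar.
#' @return object of class `similarity_transform`. Applied to row-vector
#'   coordinates as `scale * X %*% rotation + translation`.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L, scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)), class = "similarity_transform")
}

#' Apply a similarity transform to points
#' @param transform a [similarity_transform].
#' @param points N x 3 matrix or a [landmark_config].
#' @return transformed points (same type as input).
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "landmark_config")) {
    co <- points$coords
    co[!points$missing, ] <- apply_transform(transform, co[!points$missing, , drop = FALSE])
    return(set_coords(points, co))
  }
  sweep(transform$scale * as.matrix(points) %*% transform$rotation, 2L,
        -transform$translation)
}

#' Invert a similarity transform
#' @param transform a [similarity_transform].
#' @return the inverse [similarity_transform].
#' @export
invert_transform <- function(transform) {
  Rin <- t(transform$rotation)
  s <- 1 / transform$scale
  similarity_transform(Rin, -s * as.numeric(transform$translation %*% Rin), s)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, translation (%.3g, %.3g, %.3g) mm\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Kabsch/Procrustes rotation: proper rotation Q minimizing ||Y - X Q||.
opa_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Least-squares superimposition of `source` onto `target` by rotation and
#' translation, optionally with uniform scaling. Reflections are never
#' permitted. Landmarks missing in either configuration are excluded from the
#' fit (the transform is still applied to all source landmarks).
#'
#' @param source,target [landmark_config]s with identical landmark names.
#' @param allow_scaling include a uniform scale factor (default `TRUE`).
#' @return list with `transform` (a [similarity_transform]), `aligned` (the
#'   transformed source configuration) and `residual` (root-mean-square
#'   landmark distance over the common landmarks, mm).
#' @export
opa_align <- function(source, target, allow_scaling = TRUE) {
  if (!identical(source$landmark_names, target$landmark_names))
    stop("source and target must share landmark names and order")
  use <- !source$missing & !target$missing
  if (sum(use) < 3L) stop("need at least 3 common non-missing landmarks")
  X <- source$coords[use, , drop = FALSE]
  Y <- target$coords[use, , drop = FALSE]
  if (any(svd(scale(X, scale = FALSE))$d[2] < 1e-9 * max(1, max(abs(X)))))
    stop("degenerate geometry: common landmarks are collinear")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  Q <- opa_rotation(Xc, Yc)
  s <- if (allow_scaling) sum((Xc %*% Q) * Yc) / sum(Xc^2) else 1
  tr <- cy - s * as.numeric(cx %*% Q)
  transform <- similarity_transform(Q, tr, s)
  aligned <- apply_transform(transform, source)
  residual <- sqrt(mean(rowSums((aligned$coords[use, , drop = FALSE] - Y)^2)))
  list(transform = transform, aligned = aligned, residual = residual)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of two or more complete, homologous landmark
#' configurations to a consensus. With scaling, configurations and consensus
#' are standardized to unit centroid size. Iteration stops when the consensus
#' moves by less than `tol` in Procrustes distance (default 1e-10), starting
#' from the first configuration.
#'
#' @param configs list of [landmark_config]s with identical landmark names and
#'   no missing landmarks.
#' @param with_scaling standardize size (default `TRUE`).
#' @param tol convergence tolerance on consensus change.
#' @param max_iter iteration cap.
#' @return list with `consensus` (a [landmark_config] of unit centroid size
#'   when scaling), `aligned` (list of superimposed configurations) and
#'   `distances` (per-specimen Procrustes distance to the consensus).
#' @export
gpa <- function(configs, with_scaling = TRUE, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("GPA needs at least 2 configurations")
  names0 <- configs[[1L]]$landmark_names
  for (cf in configs) {
    if (!identical(cf$landmark_names, names0))
      stop("configurations are not homologous (landmark name sets differ)")
    if (any(cf$missing))
      stop("GPA requires complete configurations; estimate missing landmarks first")
  }
  norm1 <- function(m) {
    m <- scale(m, scale = FALSE)
    if (with_scaling) m / sqrt(sum(m^2)) else m
  }
  mats <- lapply(configs, function(cf) norm1(cf$coords))
  cons <- mats[[1L]]
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, function(m) m %*% opa_rotation(m, cons))
    new_cons <- norm1(Reduce(`+`, mats) / length(mats))
    new_cons <- new_cons %*% opa_rotation(new_cons, cons)
    delta <- sqrt(sum((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
  }
  aligned <- mapply(function(cf, m) set_coords(cf, m), configs, mats,
                    SIMPLIFY = FALSE)
  consensus <- set_coords(configs[[1L]], cons)
  consensus$specimen_id <- "consensus"
  dists <- vapply(mats, function(m) sqrt(sum((m - cons)^2)), numeric(1))
  list(consensus = consensus, aligned = aligned, distances = dists)
}

#' Procrustes distance between two superimposed configurations
#'
#' Square root of the summed squared coordinate differences after both
#' configurations are centred and scaled to unit centroid size. The caller is
#' responsible for prior superimposition (no rotation is applied here).
#'
#' @param a,b [landmark_config]s with the same landmarks.
#' @return non-negative scalar (dimensionless).
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(identical(a$landmark_names, b$landmark_names))
  u1 <- scale(a$coords, scale = FALSE); u2 <- scale(b$coords, scale = FALSE)
  sqrt(sum((u1 / sqrt(sum(u1^2)) - u2 / sqrt(sum(u2^2)))^2))
}

#' Cumulative Euclidean distance between two configurations
#'
#' Sum over landmarks of the pointwise 3D distances, in mm, with no centring
#' or rescaling; the configurations must already be registered. Set
#' `reduce = "mean"` for the per-landmark average instead of the sum.
#'
#' @param a,b [landmark_config]s with the same landmarks.
#' @param reduce `"sum"` (default) or `"mean"`.
#' @return non-negative scalar, mm.
#' @export
cumulative_euclidean_distance <- function(a, b, reduce = c("sum", "mean")) {
  stopifnot(identical(a$landmark_names, b$landmark_names))
  reduce <- match.arg(reduce)
  if (abs(centroid_size(a) - centroid_size(b)) >
      0.25 * max(centroid_size(a), centroid_size(b)))
    warning("configurations differ substantially in size; did you register them?")
  d <- sqrt(rowSums((a$coords - b$coords)^2))
  if (reduce == "sum") sum(d) else mean(d)
}

# Least-squares midsagittal plane through the midline landmarks:
# passes through their centroid, normal = smallest principal axis.
midsagittal_plane <- function(config) {
  if (is.null(config$pairing)) stop("configuration has no pairing table")
  mid <- config$pairing$midline
  if (length(mid) < 3L) stop("need at least 3 midline landmarks for the midsagittal plane")
  P <- config$coords[match(mid, config$landmark_names), , drop = FALSE]
  ctr <- colMeans(P)
  ev <- eigen(crossprod(sweep(P, 2L, ctr)), symmetric = TRUE)
  n <- ev$vectors[, 3L]
  list(point = ctr, normal = n / sqrt(sum(n^2)))
}

reflect_across_plane <- function(points, plane) {
  d <- as.numeric(sweep(points, 2L, plane$point) %*% plane$normal)
  points - 2 * outer(d, plane$normal)
}

#' Symmetrise a landmark configuration
#'
#' Reflects the configuration across its best-fit midsagittal plane (the
#' least-squares plane through the midline landmarks), relabels left/right
#' pairs, rigidly registers the reflection back onto the original and averages
#' the two. The result is bilaterally symmetric.
#'
#' @param config a [landmark_config] with a pairing table and at least 3
#'   midline landmarks; no missing landmarks.
#' @return the symmetrised [landmark_config].
#' @export
symmetrise <- function(config) {
  if (any(config$missing)) stop("symmetrise requires a complete configuration")
  plane <- midsagittal_plane(config)
  refl <- reflect_across_plane(config$coords, plane)
  # swap left/right rows so the reflection is anatomically relabelled
  swapped <- refl
  for (p in config$pairing$pairs) {
    i <- match(p[1L], config$landmark_names); j <- match(p[2L], config$landmark_names)
    swapped[i, ] <- refl[j, ]; swapped[j, ] <- refl[i, ]
  }
  mirrored <- set_coords(config, swapped)
  fit <- opa_align(mirrored, config, allow_scaling = FALSE)
  set_coords(config, (config$coords + fit$aligned$coords) / 2)
}
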