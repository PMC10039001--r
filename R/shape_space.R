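#' Build a comparative shape space (GPA + PCA)
#'
#' Generalized Procrustes superimposition of the comparative sample followed
#' by principal component analysis via eigen-decomposition of the covariance
#' matrix of the aligned coordinates. Components are ordered by decreasing
#' eigenvalue; each eigenvector's sign is fixed so its largest-magnitude
#' loading is positive. Out-of-sample specimens are projected with
#' [predict.shape_space()] without updating the space.
#'
#' @param configs list of complete homologous [landmark_config]s, n >= 3.
#' @param group_labels optional character vector (one label per specimen) or
#'   named vector keyed by specimen id.
#' @return object of class `shape_space`: `mean_shape` (unit centroid size),
#'   `eigenvectors` ((3N) x K), `eigenvalues`, `variance_fraction`, `scores`
#'   (n x K matrix, specimens in rows), `aligned`, `group_labels`.
#' @export
shape_space <- function(configs, group_labels = NULL) {
  if (length(configs) < 3L) stop("shape space needs at least 3 specimens")
  g <- gpa(configs, with_scaling = TRUE)
  cons <- g$consensus$coords
  # one final rotation pass so every specimen is exactly optimally rotated
  # onto the returned consensus (GPA stops within tol of this)
  mats <- lapply(g$aligned, function(cf) cf$coords %*%
                   opa_rotation(cf$coords, cons))
  X <- t(vapply(mats, function(m) as.numeric(t(m)),
                numeric(3L * nrow(configs[[1L]]$coords))))
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  rownames(X) <- ids
  mu <- colMeans(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-12
  vals <- ev$values[pos]
  vecs <- ev$vectors[, pos, drop = FALSE]
  for (k in seq_len(ncol(vecs)))  # deterministic sign
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  scores <- sweep(X, 2L, mu) %*% vecs
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  if (!is.null(group_labels)) {
    if (!is.null(names(group_labels))) group_labels <- group_labels[ids]
    group_labels <- stats::setNames(as.character(group_labels), ids)
  }
  mean_shape <- set_coords(configs[[1L]], cons)   # GPA consensus, unit size
  mean_shape$specimen_id <- "mean_shape"
  aligned <- mapply(function(cf, m) set_coords(cf, m), configs, mats,
                    SIMPLIFY = FALSE)
  structure(list(mean_shape = mean_shape, center = mu, eigenvectors = vecs,
                 eigenvalues = vals, variance_fraction = vals / sum(vals),
                 scores = scores, aligned = aligned,
                 group_labels = group_labels),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d specimens, %d landmarks, %d components\n",
              nrow(x$scores), nrow(x$mean_shape$coords), length(x$eigenvalues)))
  cat("variance fractions:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 5)),
             collapse = ", "),
      if (length(x$eigenvalues) > 5) "...\n" else "\n")
  invisible(x)
}

#' @export
summary.shape_space <- function(object, ...) {
  tab <- data.frame(eigenvalue = object$eigenvalues,
                    variance_pct = 100 * object$variance_fraction,
                    cumulative_pct = 100 * cumsum(object$variance_fraction))
  rownames(tab) <- colnames(object$scores)
  print(object)
  print(round(utils::head(tab, 10), 3))
  invisible(tab)
}

#' Project a specimen into an existing shape space
#'
#' Registers the query onto the space exactly as the training sample was
#' registered: centred, scaled to unit centroid size, optimally rotated onto
#' the consensus, then mean-centred coordinates are projected onto the
#' eigenvectors. Training specimens re-project exactly onto their stored
#' scores, projection is invariant to similarity transforms of the query, and
#' the space itself is never updated.
#'
#' @param object a [shape_space].
#' @param newdata a [landmark_config] (or list of them) with the space's
#'   landmark names.
#' @param ... unused.
#' @return numeric vector of K scores (or a matrix, one row per query).
#' @export
predict.shape_space <- function(object, newdata, ...) {
  if (inherits(newdata, "landmark_config")) {
    if (!identical(newdata$landmark_names, object$mean_shape$landmark_names))
      stop("query landmarks do not match the shape space")
    q <- scale(newdata$coords, scale = FALSE)
    q <- q / sqrt(sum(q^2))
    q <- q %*% opa_rotation(q, object$mean_shape$coords)
    y <- as.numeric(t(q)) - object$center
    return(stats::setNames(as.numeric(y %*% object$eigenvectors),
                           colnames(object$scores)))
  }
  out <- t(vapply(newdata, function(cf) predict(object, cf),
                  numeric(ncol(object$scores))))
  rownames(out) <- vapply(newdata, function(cf) cf$specimen_id, character(1))
  out
}

#' Scatter plot of shape-space scores
#'
#' @param x a [shape_space].
#' @param pcs length-2 integer vector of components to plot.
#' @param projected optional matrix/vector of projected scores to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_space <- function(x, pcs = c(1, 2), projected = NULL, ...) {
  s <- x$scores[, pcs, drop = FALSE]
  lab <- sprintf("PC%d (%.1f%%)", pcs, 100 * x$variance_fraction[pcs])
  grp <- if (!is.null(x$group_labels)) factor(x$group_labels) else
    factor(rep("specimen", nrow(s)))
  graphics::plot(s, col = as.integer(grp), pch = 19,
                 xlab = lab[1], ylab = lab[2], ...)
  if (nlevels(grp) > 1L)
    graphics::legend("topright", legend = levels(grp),
                     col = seq_len(nlevels(grp)), pch = 19, bty = "n")
  if (!is.null(projected)) {
    pm <- if (is.matrix(projected)) projected[, pcs, drop = FALSE] else
      matrix(projected[pcs], 1L)
    graphics::points(pm, pch = 17, cex = 1.4, col = "darkorange")
  }
  invisible(x)
}

# Configuration at mean + c * eigenvector k, as a landmark_config.
shape_at_score <- function(space, pc_index, score) {
  y <- as.numeric(t(space$mean_shape$coords)) +
    score * space$eigenvectors[, pc_index]
  set_coords(space$mean_shape, matrix(y, ncol = 3L, byrow = TRUE))
}

#' Deformation maps at the extremes of a principal component
#'
#' Warps a template mesh (with its homologous landmark configuration) to the
#' shapes at mean +/- `k_sd` standard deviations along one component and
#' returns both meshes with the per-facet signed relative area change of each
#' extreme against the mean-shape mesh (positive = local expansion).
#'
#' @param space a [shape_space].
#' @param pc_index component index.
#' @param k_sd extent in standard deviations (sqrt eigenvalue units).
#' @param template_mesh a [trimesh] in the template's frame.
#' @param template_config [landmark_config] homologous to the space, in the
#'   template mesh frame.
#' @return list with `mesh_minus`, `mesh_plus`, `mesh_mean`,
#'   `change_minus`, `change_plus` (per-facet values).
#' @export
pc_extreme_maps <- function(space, pc_index, k_sd, template_mesh, template_config) {
  if (pc_index < 1L || pc_index > length(space$eigenvalues))
    stop("pc_index out of range")
  sdk <- sqrt(space$eigenvalues[pc_index])
  warp_to <- function(target) {
    tps <- tps_fit(template_config$coords, target$coords)
    m <- template_mesh
    m$vertices <- tps_warp(tps, m$vertices)
    m
  }
  mesh_mean <- warp_to(space$mean_shape)
  mesh_minus <- warp_to(shape_at_score(space, pc_index, -k_sd * sdk))
  mesh_plus <- warp_to(shape_at_score(space, pc_index, +k_sd * sdk))
  list(mesh_minus = mesh_minus, mesh_plus = mesh_plus, mesh_mean = mesh_mean,
       change_minus = local_mesh_diff(mesh_mean, mesh_minus)$values,
       change_plus = local_mesh_diff(mesh_mean, mesh_plus)$values)
}
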