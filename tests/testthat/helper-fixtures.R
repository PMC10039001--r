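# Shared fixtures, built in code.

# 12-triangle axis-aligned cube mesh with edge `edge` mm, corner at origin.
cube_mesh <- function(edge = 10) {
  trimesh(as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge,
          rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)))
}

# Random non-degenerate landmark configuration.
random_config <- function(n = 8, seed = NULL, id = "spec") {
  if (!is.null(seed)) set.seed(seed)
  landmark_config(matrix(stats::rnorm(n * 3, sd = 10), n),
                  paste0("lm", seq_len(n)), id)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  virtucrania:::rotation_axis_angle(ax, stats::runif(1, 10, 350))
}

random_similarity <- function(scale = TRUE) {
  similarity_transform(random_rotation(), stats::rnorm(3, sd = 20),
                       if (scale) stats::runif(1, 0.5, 2) else 1)
}

# Parametric torus mesh (major radius R, minor r), watertight.
torus_mesh <- function(R = 30, r = 10, n_u = 48, n_v = 24) {
  u <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  v <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  g <- expand.grid(v = v, u = u)
  verts <- cbind((R + r * cos(g$v)) * cos(g$u),
                 (R + r * cos(g$v)) * sin(g$u),
                 r * sin(g$v))
  idx <- function(i, j) ((i - 1) %% n_u) * n_v + ((j - 1) %% n_v) + 1
  faces <- do.call(rbind, lapply(seq_len(n_u), function(i)
    do.call(rbind, lapply(seq_len(n_v), function(j)
      rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  trimesh(verts, faces)
}

# A small template + population cached per test run (landmark-only).
local_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- generate_template(seed = 42)
    tpl
  }
})
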