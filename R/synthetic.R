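# Seeded generators for fully synthetic "cranium-like" specimens: a smoothly
# deformed ellipsoid shell with named craniometric landmarks, an occipital
# semilandmark patch, endocast shells of known volume, populations with group
# structure, disarticulated fragment pairs with ground-truth poses, and binary
# characters evolved on a known tree. Everything is deterministic given the
# seed, and ground truth is returned beside every fixture.

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rotation_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

unitize <- function(m) m / sqrt(rowSums(m^2))

# Named unit directions of the template landmarks (x anterior, y left,
# z superior); bilateral pairs carry _L/_R suffixes.
template_landmark_dirs <- function() {
  mid <- rbind(glabella = c(1, 0, 0.20), nasion = c(1, 0, 0.02),
               metopion = c(0.80, 0, 0.70), bregma = c(0.15, 0, 1),
               vertex = c(-0.10, 0, 1), lambda = c(-0.55, 0, 0.85),
               opisthocranion = c(-1, 0, 0.10), inion = c(-1, 0, -0.25),
               opisthion = c(-0.50, 0, -0.85), basion = c(-0.25, 0, -1))
  pair_base <- rbind(asterion = c(-0.60, 0.55, 0.25),
                     porion = c(-0.05, 0.95, -0.25),
                     mastoidale = c(-0.12, 0.80, -0.55),
                     euryon = c(-0.15, 1, 0.15),
                     frontotemporale = c(0.75, 0.55, 0.35),
                     stephanion = c(0.45, 0.55, 0.80),
                     pterion = c(0.55, 0.75, 0.40),
                     zygion = c(0.40, 0.95, -0.30),
                     inferior_nuchal = c(-0.80, 0.35, -0.40),
                     auriculare = c(-0.05, 0.98, -0.05))
  dirs <- mid
  for (nm in rownames(pair_base)) {
    l <- pair_base[nm, ]; r <- l * c(1, -1, 1)
    dirs <- rbind(dirs, l, r)
    rownames(dirs)[nrow(dirs) - 1:0] <- paste0(nm, c("_L", "_R"))
  }
  unitize(dirs)
}

template_pairing <- function(dirs) {
  nm <- rownames(dirs)
  lefts <- grep("_L$", nm, value = TRUE)
  list(pairs = lapply(lefts, function(l) c(l, sub("_L$", "_R", l))),
       midline = nm[!grepl("_[LR]$", nm)])
}

# Occipital patch: a structured grid of unit directions over the posterior
# squama, between the lambda and the nuchal region.
occipital_semi_dirs <- function(n_u = 15L, n_v = 10L) {
  # interpolate between an upper arc (near lambda) and a lower arc (nuchal)
  up <- unitize(rbind(c(-0.55, 0, 0.85)))
  lo <- unitize(rbind(c(-0.85, 0, -0.45)))
  out <- matrix(NA_real_, n_u * n_v, 3L)
  k <- 0L
  for (i in seq_len(n_u)) {          # vertical (lambda -> nuchal)
    t <- (i - 1) / (n_u - 1)
    c0 <- unitize(rbind((1 - t) * up + t * lo))
    for (j in seq_len(n_v)) {        # horizontal (left -> right)
      s <- (j - 1) / (n_v - 1) - 0.5
      # swing the direction laterally around the z axis
      ang <- s * (0.9 - 0.25 * abs(2 * t - 1))
      Rz <- rotation_axis_angle(c(0, 0, 1), ang * 180 / pi)
      k <- k + 1L
      out[k, ] <- as.numeric(c0 %*% t(Rz))
    }
  }
  attr(out, "grid") <- c(n_u = n_u, n_v = n_v)
  out
}

grid_faces <- function(n_u, n_v, offset = 0L) {
  faces <- matrix(0L, 2L * (n_u - 1L) * (n_v - 1L), 3L)
  k <- 0L
  for (i in seq_len(n_u - 1L)) for (j in seq_len(n_v - 1L)) {
    a <- (i - 1L) * n_v + j; b <- a + 1L; c3 <- a + n_v; d <- c3 + 1L
    faces[k + 1L, ] <- c(a, b, d) + offset
    faces[k + 2L, ] <- c(a, d, c3) + offset
    k <- k + 2L
  }
  faces
}

#' Generate the deterministic synthetic cranium template
#'
#' A smoothly deformed ellipsoid (semi-axes 90 x 70 x 65 mm; x anterior,
#' y left, z superior) with 30 named craniometric landmarks (glabella,
#' bregma, lambda, opisthocranion, asterion/porion/mastoidale pairs, ...), an
#' occipital patch of 5 fixed landmarks plus 150 surface semilandmarks on a
#' 15 x 10 grid, and that grid's triangulation template. The surface
#' deformation ("bumps") is drawn once from the seed, so identical seeds
#' reproduce the template exactly.
#'
#' @param seed integer seed (default 42).
#' @param axes ellipsoid semi-axes, mm.
#' @param bump_amplitude relative amplitude of the smooth surface bumps
#'   (0 gives the exact ellipsoid, whose volume is analytic).
#' @param subdivisions icosphere subdivision level of the mesh (default 3).
#' @return list of class `synthetic_template`: `mesh`, `landmarks`
#'   ([landmark_config] with pairing table), `occipital`
#'   ([semilandmark_set]), `occ_faces` (triangulation template over the 5+150
#'   occipital points), `surface` (the direction -> surface closure),
#'   `axes`, `seed`.
#' @export
generate_template <- function(seed = 42L, axes = c(90, 70, 65),
                              bump_amplitude = 0.05, subdivisions = 3L) {
  params <- with_seed(seed, list(
    dirs = unitize(matrix(stats::rnorm(18L), ncol = 3L)),
    amps = stats::runif(6L, -1, 1.2) * bump_amplitude,
    sigmas = stats::runif(6L, 0.35, 0.7)))
  rho_fun <- function(U) {
    U <- unitize(as.matrix(U))
    rho <- rep(1, nrow(U))
    if (bump_amplitude > 0)
      for (i in 1:6) {
        ang <- acos(pmin(pmax(U %*% params$dirs[i, ], -1), 1))
        rho <- rho + params$amps[i] * exp(-ang^2 / (2 * params$sigmas[i]^2))
      }
    as.numeric(rho)
  }
  surface <- function(U) {
    U <- unitize(as.matrix(U))
    sweep(U, 2L, axes, `*`) * rho_fun(U)
  }
  ico <- icosphere(1, subdivisions)
  mesh <- trimesh(surface(ico$vertices), ico$faces)
  dirs <- template_landmark_dirs()
  lms <- landmark_config(surface(dirs), rownames(dirs), "template",
                         pairing = template_pairing(dirs))
  occ_fixed_names <- c("lambda", "asterion_L", "asterion_R",
                       "inferior_nuchal_L", "inferior_nuchal_R")
  occ_fixed <- subset_config(lms, occ_fixed_names)
  sd_dirs <- occipital_semi_dirs()
  semis <- project_to_mesh(mesh, surface(sd_dirs))
  grid <- attr(sd_dirs, "grid")
  occ <- semilandmark_set(occ_fixed, semis, host_mesh = mesh,
                          provenance = "template")
  structure(list(mesh = mesh, landmarks = lms, occipital = occ,
                 occ_faces = grid_faces(grid[["n_u"]], grid[["n_v"]],
                                        offset = length(occ_fixed_names)),
                 surface = surface, rho_fun = rho_fun, axes = axes,
                 seed = seed, bump_amplitude = bump_amplitude),
            class = "synthetic_template")
}

#' @export
print.synthetic_template <- function(x, ...) {
  cat(sprintf("<synthetic_template> seed %d: %d landmarks, mesh %d verts, %d occipital semis\n",
              x$seed, nrow(x$landmarks$coords), nrow(x$mesh$vertices),
              nrow(x$occipital$semis)))
  invisible(x)
}

default_groups <- function() data.frame(
  group = c("MPH", "ERN", "EWN", "MOD"),
  offset = 8, sd = 2, stringsAsFactors = FALSE)

# Smooth random displacement field: a symmetric linear strain plus a few
# broad Gaussian bumps, rescaled so the rms landmark displacement equals
# `scale` mm. Smoothness matters: a TPS fitted on most landmarks can then
# absorb the group difference at the remaining ones.
smooth_displacement_field <- function(X, scale) {
  if (scale <= 0) return(matrix(0, nrow(X), 3L))
  S <- matrix(stats::rnorm(9L, sd = 1), 3L); S <- (S + t(S)) / 2
  centers <- X[sample(nrow(X), 4L), , drop = FALSE] +
    matrix(stats::rnorm(12L, sd = 20), 4L)
  widths <- stats::runif(4L, 40, 90)
  amps <- matrix(stats::rnorm(12L), 4L)
  disp <- X %*% S
  for (j in 1:4) {
    w <- exp(-rowSums(sweep(X, 2L, centers[j, ])^2) / (2 * widths[j]^2))
    disp <- disp + outer(w, amps[j, ])
  }
  disp <- scale(disp, scale = FALSE)            # drop the translation part
  disp * scale / sqrt(mean(rowSums(disp^2)))
}

#' Generate a synthetic population with group structure
#'
#' Each individual's landmark configuration is the template's plus a smooth
#' group-mean deformation (a random symmetric strain plus broad Gaussian
#' displacement bumps, rescaled to rms `offset` mm and drawn once per group)
#' plus an individual Gaussian perturbation of scale `sd` mm per coordinate.
#' The individual's mesh and occipital semilandmarks, when requested, are
#' carried through the same thin-plate-spline warp so that surface and
#' landmarks stay consistent.
#'
#' @param template a [generate_template()] result.
#' @param n number of individuals (default 20), allocated to groups
#'   round-robin.
#' @param groups data.frame with columns `group`, `offset` (mm), `sd` (mm);
#'   default four groups (MPH/ERN/EWN/MOD) at offset 8, sd 2.
#' @param seed integer seed.
#' @param meshes also warp the template mesh for each individual (slower).
#' @param group_displacements optional named list of explicit N x 3
#'   displacement matrices overriding the random group means.
#' @return list of specimens, each with `id`, `group`, `config`, `warp` (the
#'   ground-truth [tps_model]), optional `mesh` and `occipital`, and `truth`
#'   (the exact displacement fields). Attribute `groups` records the design.
#' @export
generate_population <- function(template, n = 20L, groups = default_groups(),
                                seed = 1L, meshes = FALSE,
                                group_displacements = NULL) {
  if (n < 2L) stop("population needs n >= 2")
  base <- template$landmarks$coords
  nl <- nrow(base)
  with_seed(seed, {
    gd <- lapply(seq_len(nrow(groups)), function(gi) {
      if (!is.null(group_displacements[[groups$group[gi]]]))
        group_displacements[[groups$group[gi]]]
      else smooth_displacement_field(base, groups$offset[gi])
    })
    names(gd) <- groups$group
    specimens <- vector("list", n)
    for (i in seq_len(n)) {
      gi <- ((i - 1L) %% nrow(groups)) + 1L
      indiv <- matrix(stats::rnorm(nl * 3L, sd = groups$sd[gi]), ncol = 3L)
      target <- base + gd[[gi]] + indiv
      warp <- tps_fit(base, target)
      cfg <- set_coords(template$landmarks, target)
      cfg$specimen_id <- sprintf("%s_%02d", groups$group[gi], i)
      sp <- list(id = cfg$specimen_id, group = groups$group[gi],
                 config = cfg, warp = warp,
                 truth = list(group_disp = gd[[gi]], indiv_disp = indiv))
      if (meshes) {
        sp$mesh <- tps_warp(warp, template$mesh)
        occ_fixed <- subset_config(cfg, template$occipital$fixed$landmark_names)
        semis <- project_to_mesh(sp$mesh, tps_warp(warp, template$occipital$semis))
        sp$occipital <- semilandmark_set(occ_fixed, semis, host_mesh = sp$mesh,
                                         provenance = "projected")
      }
      specimens[[i]] <- sp
    }
    attr(specimens, "groups") <- groups
    specimens
  })
}

#' Split a specimen into two rigidly displaced fragments
#'
#' Partitions the landmarks (and mesh, if present) by a cutting plane with a
#' 2 mm exclusion band (no conjoining points survive), then applies an
#' independent rigid motion to each fragment. The exact motions are returned
#' as ground truth; `rigid_jitter_sd` adds seeded Gaussian jitter (mm /
#' degrees) on top of the fixed base motions, so jitter 0 reproduces the base
#' motions exactly.
#'
#' @param specimen a specimen from [generate_population()], or a list with
#'   `config` (and optionally `mesh`).
#' @param cutting_plane list with `point` and unit `normal`; default a
#'   roughly coronal plane through the landmark centroid separating the
#'   fronto-facial from the basal-posterior landmarks.
#' @param rigid_jitter_sd scale of the random jitter on the fragment poses.
#' @param seed integer seed (used only for the jitter).
#' @param exclusion_band width of the discarded band around the cut, mm.
#' @return list with `pair` (a [fragment_pair]), `truth_a`, `truth_b` (the
#'   applied [similarity_transform]s) and `plane`.
#' @export
fragment_specimen <- function(specimen, cutting_plane = NULL,
                              rigid_jitter_sd = 0, seed = 1L,
                              exclusion_band = 2) {
  cfg <- specimen$config
  if (is.null(cutting_plane)) {
    g <- cfg$coords[match("glabella", cfg$landmark_names), ]
    o <- cfg$coords[match("opisthocranion", cfg$landmark_names), ]
    nrm <- (g - o) / sqrt(sum((g - o)^2))
    cutting_plane <- list(point = colMeans(cfg$coords), normal = nrm)
  }
  d <- as.numeric(sweep(cfg$coords, 2L, cutting_plane$point) %*%
                    cutting_plane$normal)
  in_a <- d > exclusion_band / 2
  in_b <- d < -exclusion_band / 2
  if (sum(in_a) < 4L || sum(in_b) < 4L)
    stop("degenerate split: fewer than 4 landmarks on one side")
  jit <- if (rigid_jitter_sd > 0)
    with_seed(seed, stats::rnorm(14L, sd = rigid_jitter_sd)) else numeric(14L)
  t_a <- similarity_transform(
    rotation_axis_angle(c(0, 0, 1) + jit[1:3] * 0.01, 25 + jit[4]),
    c(40, 25, -10) + jit[5:7], 1)
  t_b <- similarity_transform(
    rotation_axis_angle(c(0, 1, 0.2) + jit[8:10] * 0.01, -40 + jit[11]),
    c(-35, 30, 20) + jit[12:14], 1)
  frag <- function(mask, transform, suffix) {
    sub <- subset_config(cfg, cfg$landmark_names[mask])
    sub$specimen_id <- paste0(cfg$specimen_id, suffix)
    apply_transform(transform, sub)
  }
  mesh_part <- function(mask_fun, transform) {
    if (is.null(specimen$mesh)) return(NULL)
    dm <- as.numeric(sweep(specimen$mesh$vertices, 2L, cutting_plane$point) %*%
                       cutting_plane$normal)
    keep_v <- mask_fun(dm)
    keep_f <- matrix(keep_v[specimen$mesh$faces], ncol = 3L)
    fsel <- rowSums(keep_f) == 3L
    if (!any(fsel)) return(NULL)
    old <- sort(unique(as.integer(specimen$mesh$faces[fsel, ])))
    remap <- match(specimen$mesh$faces[fsel, ], old)
    m <- trimesh(specimen$mesh$vertices[old, , drop = FALSE],
                 matrix(remap, ncol = 3L))
    m$vertices <- apply_transform(transform, m$vertices)
    m
  }
  pair <- fragment_pair(frag(in_a, t_a, "_FF"), frag(in_b, t_b, "_BP"),
                        mesh_a = mesh_part(function(x) x > exclusion_band / 2, t_a),
                        mesh_b = mesh_part(function(x) x < -exclusion_band / 2, t_b))
  list(pair = pair, truth_a = t_a, truth_b = t_b, plane = cutting_plane)
}

#' Generate an endocast shell of known volume
#'
#' The endocast is the template surface rebuilt on semi-axes reduced by the
#' shell thickness; with `bump_amplitude = 0` its volume is exactly the
#' ellipsoid volume 4/3 pi (a-t)(b-t)(c-t) (attached as attribute
#' `analytic_volume_cc`). Given a population specimen, the shell is carried
#' through the specimen's ground-truth warp.
#'
#' @param template a [generate_template()] result.
#' @param shell_thickness bone shell thickness t, mm (> 0 and < the smallest
#'   semi-axis).
#' @param specimen optional specimen from [generate_population()]; its `warp`
#'   is applied to the shell.
#' @param subdivisions icosphere subdivision level (default 3).
#' @return a watertight [trimesh]; attribute `analytic_volume_cc` for the
#'   undeformed exact-ellipsoid case.
#' @export
generate_endocast <- function(template, shell_thickness = 10, specimen = NULL,
                              subdivisions = 3L) {
  t <- shell_thickness
  if (t <= 0 || t >= min(template$axes) * (1 - abs(template$bump_amplitude) * 1.5))
    stop("shell thickness must be positive and smaller than the inner radius")
  ico <- icosphere(1, subdivisions)
  U <- ico$vertices
  inner_axes <- template$axes - t
  verts <- sweep(U, 2L, inner_axes, `*`) * template$rho_fun(U)
  mesh <- trimesh(verts, ico$faces)
  if (!mesh$watertight) stop("endocast shell is not watertight")
  if (!is.null(specimen)) mesh <- tps_warp(specimen$warp, mesh)
  if (template$bump_amplitude == 0)
    attr(mesh, "analytic_volume_cc") <- 4 / 3 * pi * prod(inner_axes) / 1000
  mesh
}

#' Simulate binary discrete characters on a known tree
#'
#' Characters evolve independently along the tree: starting from a random
#' root state, each branch flips the state with probability
#' `1 - exp(-rate * length)`. Missing entries (`?`) are injected uniformly at
#' `missing_rate`.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param n_characters number of characters (default 20).
#' @param substitution_rate per-unit-length flip rate.
#' @param missing_rate probability a cell is replaced by `?`.
#' @param seed integer seed.
#' @return a [character_matrix] with derived state "1" for every character;
#'   the generating tree is attached as attribute `true_tree`.
#' @export
simulate_characters <- function(tree, n_characters = 20L, substitution_rate = 0.5,
                                missing_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            substitution_rate >= 0, missing_rate >= 0, missing_rate <= 1)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  with_seed(seed, {
    states <- matrix(NA_integer_, nnode, n_characters)
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
    states[root, ] <- stats::rbinom(n_characters, 1L, 0.5)
    p_flip <- 1 - exp(-substitution_rate * tr$edge.length)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      flips <- stats::rbinom(n_characters, 1L, p_flip[e])
      states[ch, ] <- bitwXor(states[par, ], flips)
    }
    m <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]), ntip,
                dimnames = list(tree$tip.label,
                                paste0("char", seq_len(n_characters))))
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- "?"
    cm <- character_matrix(m, derived_state_map =
                             stats::setNames(rep("1", n_characters), colnames(m)))
    attr(cm, "true_tree") <- tree
    cm
  })
}
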