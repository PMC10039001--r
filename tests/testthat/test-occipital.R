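test_that("group mean shapes match closed forms and recover truth", {
  a <- random_config(6, seed = 70, id = "a")
  b <- set_coords(a, -a$coords); b$specimen_id <- "b"
  # identical group -> the config itself
  same <- group_mean_shape(list(a, a, a), rep("g", 3), "g")
  expect_equal(same$coords, a$coords, tolerance = 1e-12)
  # two configs symmetric about the origin -> the zero configuration
  mid <- group_mean_shape(list(a, b), c("g", "g"), "g")
  expect_lt(max(abs(mid$coords)), 1e-12)
  expect_error(group_mean_shape(list(a, b), c("g", "g"), "h"), "unknown group")
  # synthetic groups: recovered group means within 3 SE of the truth
  tpl <- local_template()
  pop <- generate_population(tpl, n = 40,
                             groups = data.frame(group = c("A", "B"),
                                                 offset = c(0, 10), sd = 2),
                             seed = 71)
  lab <- vapply(pop, `[[`, character(1), "group")
  cfgs <- lapply(pop, `[[`, "config")
  mB <- group_mean_shape(cfgs, lab, "B")   # raw coordinates, no GPA needed
  truthB <- tpl$landmarks$coords + pop[[which(lab == "B")[1]]]$truth$group_disp
  se <- 2 / sqrt(sum(lab == "B"))          # per-coordinate SE at sd 2 mm
  expect_lt(max(abs(mB$coords - truthB)), 3 * se * sqrt(3) + 1e-9)
})

test_that("config_to_mesh keeps the template topology and exact planar area", {
  # planar unit grid with a hand-built triangulation
  g <- as.matrix(expand.grid(x = 0:3, y = 0:3))
  pts <- cbind(g, 0)
  faces <- virtucrania:::grid_faces(4, 4)
  mesh <- config_to_mesh(pts, faces)
  expect_equal(sum(face_areas(mesh)), 9, tolerance = 1e-9)
  # same template on two configurations -> identical face lists
  mesh2 <- config_to_mesh(pts * 2, faces)
  expect_identical(mesh$faces, mesh2$faces)
  expect_error(config_to_mesh(pts, faces + 10L), "outside")
})

test_that("local mesh differences follow the closed forms", {
  tpl <- local_template()
  occ <- config_to_mesh(tpl$occipital, tpl$occ_faces)
  self <- local_mesh_diff(occ, occ)
  expect_true(all(self$values == 0))
  # uniform scale s -> every facet changes by exactly s^2 - 1
  s <- 1.3
  occ_s <- trimesh(occ$vertices * s, occ$faces)
  sc <- local_mesh_diff(occ, occ_s)
  expect_lt(max(abs(sc$values - (s^2 - 1))), 1e-9)
  # reciprocal relation (1 + v_ab)(1 + v_ba) = 1
  set.seed(72)
  occ_w <- trimesh(occ$vertices + matrix(rnorm(length(occ$vertices)), ncol = 3),
                   occ$faces)
  ab <- local_mesh_diff(occ, occ_w)$values
  ba <- local_mesh_diff(occ_w, occ)$values
  expect_lt(max(abs((1 + ab) * (1 + ba) - 1)), 1e-9)
  # a localized bump changes only the touched facets
  vb <- occ$vertices
  vi <- tpl$occ_faces[40, 1]
  vb[vi, ] <- vb[vi, ] + c(2, 2, 2)
  bump <- local_mesh_diff(occ, trimesh(vb, occ$faces))$values
  touched <- apply(occ$faces == vi, 1, any)
  expect_true(all(abs(bump[!touched]) < 1e-12))
  expect_true(any(abs(bump[touched]) > 1e-3))
  expect_error(local_mesh_diff(occ, cube_mesh()), "topology")
})

test_that("midsagittal profiles follow great circles and resample evenly", {
  sph <- icosphere(50, 5)
  plane <- list(point = c(0, 0, 0), normal = c(0, 1, 0))
  prof <- midsagittal_profile(sph, start = c(0, 0, 50), end = c(50, 0, 0),
                              plane = plane, n_points = 30)
  expect_equal(nrow(prof), 30L)
  expect_equal(prof[1, ], c(0, 0, 50), tolerance = 1e-9)
  expect_equal(prof[30, ], c(50, 0, 0), tolerance = 1e-9)
  # points on the analytic great circle, within the facet sagitta
  expect_lt(max(abs(sqrt(rowSums(prof^2)) - 50)), 1e-3 * 50)
  # arc-length resampling is exact along the section polyline: on a straight
  # polyline the chords are exactly equal
  line <- cbind(c(0, 1, 3, 4, 10), 0, 0)
  rs <- virtucrania:::resample_polyline(line, 6)
  expect_lt(diff(range(sqrt(rowSums(diff(rs)^2)))), 1e-9)
  # equivariance under rigid motion
  set.seed(73)
  tf <- random_similarity(scale = FALSE)
  sph2 <- sph; sph2$vertices <- apply_transform(tf, sph2$vertices)
  plane2 <- list(point = apply_transform(tf, matrix(plane$point, 1))[1, ],
                 normal = as.numeric(matrix(plane$normal, 1) %*% tf$rotation))
  prof2 <- midsagittal_profile(sph2, apply_transform(tf, matrix(c(0, 0, 50), 1))[1, ],
                               apply_transform(tf, matrix(c(50, 0, 0), 1))[1, ],
                               plane2, n_points = 30)
  expect_lt(max(abs(prof2 - apply_transform(tf, prof))), 1e-8)
})

test_that("profile shape space separates bunned from rounded occipitals", {
  # two populations whose group field differs by a posterior bump at the
  # occiput; PC1 of the resampled midsagittal profiles must separate them
  tpl <- local_template()
  base <- tpl$landmarks$coords
  occ_dir <- c(-1, 0, 0.2) / sqrt(1.04)
  w <- exp(-rowSums(sweep(virtucrania:::unitize(base), 2, occ_dir)^2) / 0.3)
  bump <- outer(w, occ_dir) * 12              # ~12 mm posterior bun
  pop <- generate_population(tpl, n = 16,
                             groups = data.frame(group = c("round", "bun"),
                                                 offset = c(0, 1), sd = 1.5),
                             seed = 74,
                             group_displacements = list(
                               round = matrix(0, nrow(base), 3),
                               bun = bump))
  profs <- lapply(pop, function(sp) {
    mesh <- tps_warp(sp$warp, tpl$mesh)
    lam <- sp$config$coords[match("lambda", sp$config$landmark_names), ]
    inl <- sp$config$coords[match(c("inferior_nuchal_L", "inferior_nuchal_R"),
                                  sp$config$landmark_names), ]
    pl <- virtucrania:::midsagittal_plane(sp$config)
    pts <- midsagittal_profile(mesh, lam, colMeans(inl), pl, n_points = 30)
    cf <- landmark_config(pts, paste0("p", 1:30), sp$id)
    cf
  })
  sp1 <- shape_space(profs)
  s1 <- sp1$scores[, 1]
  lab <- vapply(pop, `[[`, character(1), "group")
  pooled <- sqrt((stats::var(s1[lab == "round"]) + stats::var(s1[lab == "bun"])) / 2)
  expect_gt(abs(mean(s1[lab == "round"]) - mean(s1[lab == "bun"])), 2 * pooled)
})

test_that("lambda-asteria angle matches constructed geometries", {
  mk <- function(l, al, ar) landmark_config(
    rbind(l, al, ar), c("lambda", "asterion_L", "asterion_R"))
  # equilateral triangle -> 60 degrees
  eq <- mk(c(0, 0, 1), c(0.5, sqrt(3) / 2 * cos(0), 0), c(-0.5, sqrt(3) / 2, 0))
  eq <- mk(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(lambda_asteria_angle(eq), 60, tolerance = 1e-9)
  # asteria at +/-45 degrees from the sagittal axis -> 90 degrees
  right <- mk(c(0, 0, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(lambda_asteria_angle(right), 90, tolerance = 1e-9)
  expect_error(lambda_asteria_angle(mk(c(0, 0, 0), c(1, 0, 0), c(NA, NA, NA))),
               "asterion_R")
})

test_that("maximum cranial breadth matches analytic shapes and finds bumps", {
  plane <- list(point = c(0, 0, 0), normal = c(0, 1, 0))
  sph <- icosphere(40, 3)
  expect_equal(max_cranial_breadth(sph, plane)$breadth_mm, 80, tolerance = 1e-6)
  ell <- trimesh(sweep(icosphere(1, 3)$vertices, 2, c(90, 70, 65), `*`),
                 sph$faces)
  expect_equal(max_cranial_breadth(ell, plane)$breadth_mm, 140, tolerance = 1e-6)
  # a lateral bump moves the achieving point onto the bump
  vb <- sph$vertices
  i <- which.max(vb[, 2])
  vb[i, 2] <- vb[i, 2] + 5
  br <- max_cranial_breadth(trimesh(vb, sph$faces), plane)
  expect_equal(br$breadth_mm, 85, tolerance = 1e-6)
  expect_equal(br$point_left, vb[i, ], tolerance = 1e-9)
})

test_that("scalar occipital measurements are rigid-motion invariant", {
  tpl <- local_template()
  cfg <- tpl$landmarks
  pl <- virtucrania:::midsagittal_plane(cfg)
  base_angle <- lambda_asteria_angle(cfg)
  base_breadth <- max_cranial_breadth(tpl$mesh, pl)$breadth_mm
  set.seed(75)
  for (rep in 1:3) {
    tf <- random_similarity(scale = FALSE)
    cfg2 <- apply_transform(tf, cfg)
    mesh2 <- tpl$mesh; mesh2$vertices <- apply_transform(tf, mesh2$vertices)
    pl2 <- virtucrania:::midsagittal_plane(cfg2)
    expect_equal(lambda_asteria_angle(cfg2), base_angle, tolerance = 1e-8)
    expect_equal(max_cranial_breadth(mesh2, pl2)$breadth_mm, base_breadth,
                 tolerance = 1e-8)
  }
})
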