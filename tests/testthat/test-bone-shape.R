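test_that("iso-surface of a voxelized sphere is watertight with the topology
           and volume of a sphere", {
  mesh <- extract_surface(sphere_mask())
  di <- mesh_diagnostics(mesh)
  expect_true(di$watertight)
  expect_identical(di$euler, 2L)
  expect_lt(abs(di$volume_mm3 - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.05)
  expect_identical(di$n_degenerate_faces, 0L)
})

test_that("generator bone masks yield watertight meshes", {
  bp <- two_mode_population()
  mesh <- extract_surface(bp$masks[[1]], attr(bp$masks[[1]], "spacing"))
  di <- mesh_diagnostics(mesh)
  expect_true(di$watertight)
  expect_identical(di$euler, 2L)
})

test_that("empty masks error; disconnected masks warn and keep the largest
           component", {
  expect_error(extract_surface(array(FALSE, c(8, 8, 8))), "empty")
  m <- array(FALSE, c(20, 20, 20))
  m[3:8, 3:8, 3:8] <- TRUE
  m[14:16, 14:16, 14:16] <- TRUE
  expect_warning(mesh <- extract_surface(m, c(1, 1, 1), smooth_sigma_mm = 0),
                 "largest")
  di <- mesh_diagnostics(mesh)
  expect_lt(abs(di$volume_mm3 - 6^3), 0.3 * 6^3)
})

test_that("correspondence to itself is the identity", {
  bp <- two_mode_population()
  mesh <- decimate_mesh(extract_surface(bp$masks[[1]],
                                        attr(bp$masks[[1]], "spacing")), 600)
  co <- spectral_correspondence(mesh, mesh, k = 5)
  expect_identical(co$index, seq_len(nrow(mesh$vertices)))
})

test_that("correspondence recovers a random vertex relabeling exactly", {
  bp <- two_mode_population()
  mesh <- decimate_mesh(extract_surface(bp$masks[[2]],
                                        attr(bp$masks[[2]], "spacing")), 600)
  set.seed(5)
  perm <- sample(nrow(mesh$vertices))
  inv <- order(perm)
  tgt <- surface_mesh(mesh$vertices[perm, ],
                      matrix(match(mesh$faces, perm), ncol = 3))
  co <- spectral_correspondence(mesh, tgt, k = 5)
  expect_identical(co$index, inv)
})

test_that("spectral matching beats plain spatial nearest neighbour under a
           planted rotation of a perturbed sphere", {
  d <- 48; c0 <- (d - 1) / 2
  co <- expand.grid(x = 0:(d - 1), y = 0:(d - 1), z = 0:(d - 1))
  r <- sqrt((co$x - c0)^2 + (co$y - c0)^2 + (co$z - c0)^2)
  dir <- cbind(co$x - c0, co$y - c0, co$z - c0) / pmax(r, 1e-9)
  pert <- 1 + 0.05 * (sin(3 * dir[, 1]) * cos(2 * dir[, 2]) +
                        0.5 * sin(4 * dir[, 3]))
  mask <- array(r <= 18 * pert, rep(d, 3)); attr(mask, "spacing") <- c(1, 1, 1)
  mesh <- decimate_mesh(extract_surface(mask, c(1, 1, 1)), 800)
  th <- 40 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- colMeans(mesh$vertices)
  rot <- surface_mesh(sweep(sweep(mesh$vertices, 2, ctr) %*% t(Rz), 2, ctr,
                            "+"), mesh$faces)
  cs <- spectral_correspondence(mesh, rot, k = 5)
  # true correspondence is vertex i -> vertex i; errors measured after
  # undoing the planted rotation
  undo <- function(P) sweep(sweep(P, 2, ctr) %*% Rz, 2, ctr, "+")
  err_sp <- sqrt(rowSums((mesh$vertices - undo(rot$vertices[cs$index, ]))^2))
  nn <- nn_index_cpp(mesh$vertices, rot$vertices)
  err_nn <- sqrt(rowSums((mesh$vertices - undo(rot$vertices[nn, ]))^2))
  edge_len <- mean(sqrt(rowSums((mesh$vertices[mesh$faces[, 1], ] -
                                   mesh$vertices[mesh$faces[, 2], ])^2)))
  expect_lt(mean(err_sp), 2 * edge_len)
  expect_lt(mean(err_sp), mean(err_nn))
})

test_that("generalized Procrustes: rigid motions removed, scale preserved,
           idempotent", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing")), 500)
  P <- base$vertices
  rot <- function(a) rotation_matrix(a)
  sets <- list(P,
               sweep(P %*% t(rot(c(0.2, -0.1, 0.3))), 2, c(5, -3, 2), "+"),
               sweep(P %*% t(rot(c(-0.3, 0.2, 0.1))), 2, c(-2, 4, 1), "+"))
  al <- align_pointsets(sets)
  for (s in 2:3)
    expect_lt(sqrt(mean((al[[1]] - al[[s]])^2)), 1e-6)
  # scale differences survive with scaling off
  sets2 <- list(P, P * 1.25)
  al2 <- align_pointsets(sets2)
  ratio <- sqrt(sum(sweep(al2[[2]], 2, colMeans(al2[[2]]))^2) /
                  sum(sweep(al2[[1]], 2, colMeans(al2[[1]]))^2))
  expect_equal(ratio, 1.25, tolerance = 1e-9)
  # idempotence
  al3 <- align_pointsets(al)
  for (s in 1:3)
    expect_lt(max(abs(al3[[s]] - al[[s]])), 1e-9)
})

test_that("shape model: exact reconstruction and mode clipping", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing")), 400)
  pts <- bone_pointsets(bp, base$vertices)[1:6]
  # two planted modes: the data have rank 2, so the model clips there
  expect_warning(model <- build_shape_model(pts, n_modes = 10), "clipped")
  expect_identical(model$n_modes, 2L)
  for (s in c(1, 4)) {
    rec <- reconstruct_shape(model, model$scores[s, ])
    expect_lt(max(abs(rec - pts[[s]])) / max(abs(pts[[s]])), 1e-8)
  }
  expect_true(all(diff(model$variances) <= 1e-9))
  expect_true(all(abs(colMeans(model$scores)) < 1e-8))
  expect_equal(max(abs(crossprod(model$modes) - diag(model$n_modes))), 0,
               tolerance = 1e-8)
  expect_true(all(diff(model$cum_var_fraction) >= -1e-12))
  expect_equal(model$cum_var_fraction[model$n_modes], 1, tolerance = 1e-8)
})

test_that("PCA agrees with a dense covariance eigen-decomposition oracle", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing")), 200)
  pts <- bone_pointsets(bp, base$vertices)
  model <- build_shape_model(pts, n_modes = 2)
  X <- t(vapply(pts, as.numeric, numeric(length(pts[[1]]))))
  Xc <- sweep(X, 2, colMeans(X))
  # dense oracle via the subject-space Gram matrix (3V x 3V is impractical,
  # n x n is exact for the leading modes)
  G <- Xc %*% t(Xc)
  eg <- eigen(G, symmetric = TRUE)
  oracle_vars <- eg$values[1:2] / (nrow(X) - 1)
  expect_equal(model$variances, oracle_vars, tolerance = 1e-8)
  for (m in 1:2) {
    om <- as.numeric(t(Xc) %*% eg$vectors[, m]) / sqrt(eg$values[m])
    expect_lt(min(sum((model$modes[, m] - om)^2),
                  sum((model$modes[, m] + om)^2)), 1e-8)
  }
})

test_that("two planted orthogonal modes are recovered: eigenvalue ratio and
           subspace", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing"),
                                        smooth_sigma_mm = 1.5), 1000)
  pts <- bone_pointsets(bp, base$vertices)
  model <- build_shape_model(align_pointsets(pts), n_modes = 10)
  oracle <- planted_mode_oracle(bp, pts)
  ratio <- model$variances[1] / model$variances[2]
  oracle_ratio <- oracle$eigenvalues[1] / oracle$eigenvalues[2]
  expect_lt(abs(ratio - 4) / 4, 0.25)
  expect_lt(abs(ratio - oracle_ratio) / oracle_ratio, 0.05)
  expect_lt(subspace_angle_deg(model$modes[, 1:2], oracle$basis), 10)
})

test_that("the spectral pipeline recovers a planted dominant mode from
           masks alone", {
  modes <- list(list(centre = c(1, 0.3, 0.3), sigma = 0.5, sd_mm = 2))
  bp <- generate_bone_population(12, modes, seed = 7, dim = 64,
                                 spacing_mm = c(1.25, 1.25, 1.25))
  meshes <- lapply(bp$masks, function(m)
    decimate_mesh(extract_surface(m, attr(m, "spacing"),
                                  smooth_sigma_mm = 1.5), 800))
  tpl <- meshes[[1]]
  pts <- lapply(meshes, function(m)
    spectral_correspondence(tpl, m, k = 6)$points)
  model <- build_shape_model(align_pointsets(pts), n_modes = 8)
  expect_gt(model$variances[1] / model$variances[2], 3)
  expect_gt(abs(cor(model$scores[, 1], bp$true_scores[, 1])), 0.9)
})

test_that("per-mode group tests: planted shift detected, others at null
           rates, exclusions honoured", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing")), 500)
  set.seed(70)
  n <- 40
  meta <- random_meta(n)
  run_once <- function(shift) {
    scores <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1))
    scores[meta$group == "A", 2] <- scores[meta$group == "A", 2] + shift
    pts <- bone_pointsets(bp, base$vertices, scores)
    model <- build_shape_model(align_pointsets(pts), n_modes = 2)
    tests <- mode_group_test(model, meta)
    m2 <- which.max(abs(cor(model$scores, scores[, 2]))[, 1])
    c(shifted = tests$p[tests$mode == m2] < 0.05,
      other = tests$p[tests$mode == setdiff(1:2, m2)] < 0.05)
  }
  with_shift <- vapply(1:40, function(i) run_once(1), c(a = NA, b = NA))
  expect_gte(mean(with_shift[1, ]), 0.8)  # +1 SD shift, n = 20/20: high power
  null_runs <- vapply(1:40, function(i) run_once(0), c(a = NA, b = NA))
  # 80 null tests at alpha .05: rate within a generous binomial envelope
  expect_lte(mean(null_runs), 0.12)
  # excluding every mode yields an empty table, not an error
  model <- build_shape_model(bone_pointsets(bp, base$vertices), n_modes = 4)
  empty <- mode_group_test(model, random_meta(30), exclude_modes = 1:4)
  expect_identical(nrow(empty), 0L)
})

test_that("mode visualization: zero magnitude collapses to the mean and the
           displacement norm has its closed form", {
  bp <- two_mode_population()
  base <- decimate_mesh(extract_surface(bp$base_mask,
                                        attr(bp$base_mask, "spacing")), 300)
  model <- build_shape_model(bone_pointsets(bp, base$vertices), n_modes = 3)
  v0 <- mode_visualization(model, 1, magnitude = 0)
  expect_equal(v0$mesh_plus, model$mean_vertices, tolerance = 1e-12)
  expect_equal(v0$mesh_minus, model$mean_vertices, tolerance = 1e-12)
  v3 <- mode_visualization(model, 2, magnitude = 3)
  V <- nrow(model$mean_vertices)
  expected <- 3 * sqrt(model$variances[2]) *
    sqrt(rowSums(matrix(model$modes[, 2], V, 3)^2))
  expect_equal(v3$displacement_norm, expected, tolerance = 1e-12)
  # planted-mode displacement concentrates on the perturbed region
  W <- bp$mode_fields(model$mean_vertices)
  v1 <- mode_visualization(model, 1, magnitude = 3)
  support <- W[, 1] > 0.05 * max(W[, 1])
  expect_gt(sum(v1$displacement_norm[support]^2) /
              sum(v1$displacement_norm^2), 0.7)
})

test_that("OFF meshes round-trip", {
  mesh <- decimate_mesh(extract_surface(sphere_mask(24, 9)), 200)
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(mesh, path)
  back <- read_mesh_off(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
})
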