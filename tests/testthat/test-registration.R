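test_that("identity transform leaves volumes bitwise unchanged (nearest)", {
  kn <- noiseless_knee()
  v <- kn$series$volumes[[1]]
  out <- apply_transform(v, rigid_transform(), "nearest")
  expect_identical(as.numeric(out), as.numeric(v))
})

test_that("whole-voxel translation is a circular shift on interior voxels", {
  kn <- noiseless_knee()
  v <- kn$series$volumes[[1]]
  sp <- spacing(v)
  tr <- rigid_transform(translation = c(sp[1], 0, 0))
  out <- apply_transform(v, tr, "nearest")
  d <- dim(v)
  # out[i] = v[i + 1] along x for interior voxels
  expect_identical(as.numeric(out[1:(d[1] - 1), , ]),
                   as.numeric(v[2:d[1], , ]))
})

test_that("linear interpolation of label volumes is refused", {
  kn <- noiseless_knee()
  expect_error(apply_transform(kn$atlas$labels, rigid_transform(), "linear"),
               "label")
  expect_silent(apply_transform(kn$atlas$labels, rigid_transform(), "nearest"))
})

test_that("self-registration returns (near) identity", {
  kn <- noiseless_knee()
  v <- kn$series$volumes[[1]]
  tr <- register_rigid(v, v)
  expect_lt(sqrt(sum(tr$angles^2)), 1e-3)
  expect_lt(sqrt(sum(tr$translation^2)), 1e-3)
})

test_that("planted rigid translation is recovered within 0.1 mm per axis", {
  pair <- deformed_pair()
  v <- pair$atlas$series$volumes[[1]]
  planted <- c(3.0, -2.0, 1.0)
  moved <- apply_transform(v, rigid_transform(translation = planted), "linear")
  est <- register_rigid(moved, v)
  # the estimate maps `moved` back onto `v`, so it should equal -planted
  expect_true(all(abs(est$translation + planted) < 0.1))
  expect_lt(max(abs(est$angles)), 0.01)
})

test_that("low-SNR later echoes register to t = 0 with < 0.2 mm spurious
           motion", {
  spec <- cohort_spec(dim = 48, spacing_mm = c(2, 2, 2), noise_sd = 20,
                      deform_amplitude_mm = 0, seed = 77)
  kn <- generate_subject_knee(spec, "A", seed = 77)
  t0v <- kn$series$volumes[[1]]
  last <- kn$series$volumes[[4]]  # TSL 80 ms, weakest signal
  est <- register_rigid(last, t0v)
  expect_lt(sqrt(sum(est$translation^2)), 0.2)
})

test_that("nonrigid self-registration yields a near-zero field", {
  pair <- deformed_pair()
  v <- pair$atlas$series$volumes[[1]]
  f <- register_nonrigid(v, v)
  mag_vox <- sqrt(rowSums(matrix(f$displacement, ncol = 3)^2)) /
    min(spacing(v))
  expect_lt(mean(mag_vox), 0.1)
})

test_that("planted nonrigid deformation: mask overlap and field recovery", {
  pair <- deformed_pair()
  v_a <- pair$atlas$series$volumes[[1]]
  v_s <- pair$subject$series$volumes[[1]]
  field <- register_nonrigid(v_s, v_a)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  ca <- as.integer(pair$atlas$atlas$labels) >= min(CARTILAGE_LABELS)
  cs <- as.integer(pair$subject$atlas$labels) >= min(CARTILAGE_LABELS)
  warped <- apply_transform(pair$subject$atlas$labels, field, "nearest")
  cw <- as.integer(warped) >= min(CARTILAGE_LABELS)
  expect_lte(dice(cs, ca), 0.6)   # planted deformation separates the masks
  expect_gte(dice(cw, ca), 0.8)   # registration restores the overlap
  # landmark error over cartilage drops substantially
  gt <- pair$subject$truth$deformation_to_atlas
  e0 <- mean(sqrt(rowSums(matrix(gt, ncol = 3)[ca, ]^2)))
  e1 <- mean(sqrt(rowSums(matrix(field$displacement - gt, ncol = 3)[ca, ]^2)))
  expect_lt(e1, 0.5 * e0)
  # diffeomorphic in practice
  J <- jacobian_determinant(field)
  fg <- as.numeric(v_s) > 100
  expect_gte(mean(J[fg] > 0), 0.99)
})

test_that("registration between two generated subjects raises cartilage Dice
           above 0.8", {
  pair <- deformed_pair()
  other <- generate_subject_knee(pair$spec, "B", seed = 4)
  field <- register_nonrigid(other$series$volumes[[1]],
                             pair$atlas$series$volumes[[1]])
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  ca <- as.integer(pair$atlas$atlas$labels) >= min(CARTILAGE_LABELS)
  warped <- apply_transform(other$atlas$labels, field, "nearest")
  cw <- as.integer(warped) >= min(CARTILAGE_LABELS)
  expect_gte(dice(cw, ca), 0.8)
})

test_that("inverse consistency: A->B composed with B->A is < 0.5 voxel", {
  pair <- deformed_pair()
  A <- pair$atlas$series$volumes[[1]]
  B <- pair$subject$series$volumes[[1]]
  fab <- register_nonrigid(A, B)
  fba <- register_nonrigid(B, A)
  d <- dim(fab$displacement)[1:3]
  sp <- fab$spacing
  comp <- array(0, dim(fab$displacement))
  for (c in 1:3)
    comp[, , , c] <- array(resample_field_cpp(fba$displacement[, , , c], d,
                                              sp, as.numeric(fab$displacement),
                                              FALSE, 0), d) +
      fab$displacement[, , , c]
  fg <- as.numeric(A) > 100
  res_vox <- sqrt(rowSums(matrix(comp, ncol = 3)[fg, ]^2)) / min(sp)
  expect_lt(mean(res_vox), 0.5)
})

test_that("transport-then-fit commutes with fit-then-transport within
           interpolation tolerance", {
  # thicker cartilage so an eroded interior core survives at this voxel size
  spec <- cohort_spec(dim = 48, spacing_mm = c(2, 2, 2), noise_sd = 0,
                      deform_amplitude_mm = 8, shell_mm = 7, seed = 2)
  pair <- list(spec = spec,
               atlas = generate_subject_knee(spec, "B", seed = 99,
                                             atlas_mode = TRUE),
               subject = generate_subject_knee(spec, "B", seed = 3))
  field <- register_nonrigid(pair$subject$series$volumes[[1]],
                             pair$atlas$series$volumes[[1]])
  cs <- array(as.integer(pair$subject$atlas$labels) >= min(CARTILAGE_LABELS),
              dim(pair$subject$atlas$labels))
  # reference order (transform echoes first, then fit voxel-by-voxel)
  transported <- transport_series(pair$subject$series, field = field)
  all_mask <- array(TRUE, dim(cs))
  mA <- compute_map(transported, "T1rho", all_mask)
  # alternative order: fit in native space, then transport the map
  mB <- compute_map(pair$subject$series, "T1rho", array(cs, dim(cs)))
  tB <- apply_transform(mB$t, field, "linear")
  # compare on atlas-space cartilage, eroded clear of blurred edges
  ca <- array(as.integer(pair$atlas$atlas$labels) >= min(CARTILAGE_LABELS),
              dim(cs))
  dist_out <- distance_transform(!ca, spacing = pair$spec$spacing_mm)
  core <- which(ca & dist_out > 4 & mA$valid & tB > 1)
  err <- abs(mA$t[core] - tB[core])
  expect_lt(mean(err), 0.5)
  # and the transported fit stays close to the atlas-space ground truth
  truth <- pair$atlas$truth$t1rho
  expect_lt(mean(abs(mA$t[core] - truth[core])), 2)
})
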