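# The cohort generator is first-class code: its contracts (timing structure,
# determinism, ground-truth consistency, invertible deformations) underpin
# every downstream test.

test_that("cohort spec validates acquisition timing and probabilities", {
  expect_error(cohort_spec(tsl_ms = c(10, 40, 80)), "start at 0")
  expect_error(cohort_spec(te_ms = c(0, 20, 15)), "increasing")
  bad <- default_grade_probs()
  bad$A$LFC <- c(0.5, 0.2, 0.2)
  expect_error(cohort_spec(grade_probs = bad), "sum to 1")
  spec <- cohort_spec()
  expect_identical(spec$tsl_ms, c(0, 10, 40, 80))
  expect_identical(spec$te_ms, c(0, 12.8, 25.7, 51.4))
})

test_that("series has 7 distinct volumes with a shared t = 0 image", {
  kn <- noiseless_knee()
  expect_length(kn$series$volumes, 7L)
  idx <- kn$series$index
  expect_identical(nrow(idx), 8L)  # 4 TSL + 4 TE rows
  v_t1 <- idx$volume[idx$parameter == "T1rho" & idx$time_ms == 0]
  v_t2 <- idx$volume[idx$parameter == "T2" & idx$time_ms == 0]
  expect_identical(v_t1, v_t2)
})

test_that("noiseless signals follow the closed-form exponential decay", {
  kn <- noiseless_knee()
  lab <- as.integer(kn$atlas$labels)
  mfc <- which(lab == CARTILAGE_LABELS[["MFC"]])
  idx <- kn$series$index
  t1 <- kn$truth$t1rho
  for (t in c(10, 40, 80)) {
    vi <- idx$volume[idx$parameter == "T1rho" & idx$time_ms == t]
    s <- as.numeric(kn$series$volumes[[vi]])[mfc]
    s0 <- as.numeric(kn$series$volumes[[1]])[mfc]
    expect_equal(s, s0 * exp(-t / as.numeric(t1)[mfc]), tolerance = 1e-12)
  }
})

test_that("generation is deterministic in the seed", {
  spec <- cohort_spec(dim = 28, spacing_mm = c(3, 3, 3), noise_sd = 15,
                      deform_amplitude_mm = 2)
  a <- generate_subject_knee(spec, "A", seed = 11)
  b <- generate_subject_knee(spec, "A", seed = 11)
  c <- generate_subject_knee(spec, "A", seed = 12)
  expect_identical(a$series$volumes[[3]], b$series$volumes[[3]])
  expect_false(identical(as.numeric(a$series$volumes[[3]]),
                         as.numeric(c$series$volumes[[3]])))
})

test_that("degenerate cartilage geometry is rejected", {
  spec <- cohort_spec(dim = 20, spacing_mm = c(5, 5, 5))
  expect_error(generate_subject_knee(spec, "A"), "thinner than 1 voxel")
})

test_that("superficial ground truth exceeds deep by the configured gradient", {
  spec <- test_spec(group_effect_pct = matrix(
    0, 6, 2, dimnames = list(CARTILAGE_COMPARTMENTS, c("deep", "superficial"))))
  kn <- generate_subject_knee(spec, "A", seed = 7)
  lab <- as.integer(kn$atlas$labels)
  depth <- as.numeric(kn$truth$depth)
  t1 <- as.numeric(kn$truth$t1rho)
  for (comp in CARTILAGE_COMPARTMENTS) {
    sel <- lab == CARTILAGE_LABELS[[comp]]
    sup <- mean(t1[sel & depth > 0.5])
    deep <- mean(t1[sel & depth <= 0.5])
    expect_equal(sup / deep, 1 + spec$layer_gradient, tolerance = 1e-12)
  }
})

test_that("stored deformation composed with its numeric inverse is identity", {
  pair <- deformed_pair()
  u <- pair$subject$truth$deformation_to_atlas
  sp <- pair$spec$spacing_mm
  w <- invert_displacement(u, sp)
  dims <- dim(u)[1:3]
  comp <- array(0, dim(u))
  for (c in 1:3)
    comp[, , , c] <- array(resample_field_cpp(u[, , , c], dims, sp,
                                              as.numeric(w), FALSE, 0),
                           dims) + w[, , , c]
  # evaluate away from the volume border where resampling pads with zero
  core <- array(FALSE, dims)
  core[5:(dims[1] - 4), 5:(dims[2] - 4), 5:(dims[3] - 4)] <- TRUE
  mag_vox <- sqrt(rowSums(matrix(comp, ncol = 3)[core, ]^2)) / min(sp)
  expect_lt(mean(mag_vox), 0.1)
})

test_that("phantom series match the two-by-three vial design", {
  ph0 <- generate_phantom_series(c(40, 60, 80), n_repeats = 2, noise_sd = 0)
  expect_identical(length(unique(ph0$vial)), 6L)
  cv0 <- coefficient_of_variation(ph0)
  expect_true(all(cv0$intra$cv_pct == 0))
  ph1 <- generate_phantom_series(c(40, 60, 80), n_repeats = 3, noise_sd = 5,
                                 seed = 9)
  ph2 <- generate_phantom_series(c(40, 60, 80), n_repeats = 3, noise_sd = 5,
                                 seed = 9)
  expect_identical(ph1, ph2)
  expect_false(all(ph1$signal ==
    generate_phantom_series(c(40, 60, 80), 3, 5, seed = 10)$signal))
})

test_that("subject table structure: bilateral knees, grades, prevalence", {
  spec <- cohort_spec(bilateral_prob = 1)
  tab <- generate_subject_table(spec, seed = 5)
  expect_identical(nrow(tab), 2L * (40L + 25L))
  expect_false(anyDuplicated(tab$knee_id) > 0)
  expect_true(all(unlist(tab[, grep("^noyes_", names(tab))]) %in% 0:2))
  # all grade mass on zero: no abnormal knee anywhere
  p0 <- lapply(default_grade_probs(), function(g)
    lapply(g, function(x) c(1, 0, 0)))
  tab0 <- generate_subject_table(cohort_spec(grade_probs = p0), seed = 5)
  expect_identical(build_exclusion_list(tab0), character(0))
  expect_equal(prevalence_table(tab0)$per_knee$pct_abnormal, c(0, 0))
})

test_that("abnormal-knee fraction matches the analytic generator expectation", {
  spec <- cohort_spec(bilateral_prob = 0)
  gp <- spec$grade_probs
  p_abn_a <- 1 - prod(vapply(gp$A, `[`, 0, 1))
  fracs <- vapply(seq_len(120), function(i) {
    tab <- generate_subject_table(spec, seed = 5000L + i)
    g <- tab[tab$group == "A", grep("^noyes_", names(tab))]
    mean(rowSums(g >= 1) > 0)
  }, 0)
  mc_se <- sqrt(p_abn_a * (1 - p_abn_a) / (120 * 40))
  expect_lt(abs(mean(fracs) - p_abn_a), 4 * mc_se)
})

test_that("bone population: zero-amplitude modes give identical shapes", {
  modes <- list(list(centre = c(1, 0, 0), sigma = 0.5, sd_mm = 0))
  bp <- generate_bone_population(5, modes, seed = 3, dim = 32,
                                 spacing_mm = c(2, 2, 2))
  for (s in 2:5) expect_identical(bp$masks[[1]], bp$masks[[s]])
  base <- decimate_mesh(extract_surface(bp$base_mask), 400)
  model <- build_shape_model(bone_pointsets(bp, base$vertices), n_modes = 3)
  expect_equal(model$total_variance, 0, tolerance = 1e-20)
  expect_true(all(model$scores == 0))
})

test_that("excessive mode amplitudes are rejected", {
  modes <- list(list(centre = c(1, 0, 0), sigma = 0.2, sd_mm = 30))
  expect_error(generate_bone_population(10, modes, seed = 1, dim = 32,
                                        spacing_mm = c(2, 2, 2)),
               "connectivity")
})

test_that("knee volumes round-trip through NIfTI", {
  kn <- noiseless_knee()
  dir <- withr::local_tempdir()
  write_knee(kn, dir, "K01")
  expect_true(file.exists(file.path(dir, "K01_t1rho_00.0ms.nii.gz")))
  v <- read_volume(file.path(dir, "K01_labels.nii.gz"))
  expect_equal(as.numeric(v), as.numeric(kn$atlas$labels), tolerance = 1e-6)
  expect_equal(spacing(v), spacing(kn$atlas$labels), tolerance = 1e-5)
})
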