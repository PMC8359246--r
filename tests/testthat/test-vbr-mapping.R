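# helper: build a stack directly from a values matrix (voxels x knees)
make_stack <- function(values, meta) {
  structure(list(values = values, voxel_index = seq_len(nrow(values)),
                 dim = c(nrow(values), 1L, 1L), spacing = c(1, 1, 1),
                 meta = meta), class = "vbr_stack")
}

test_that("stacking fails loudly on grid or metadata mismatches", {
  kn <- noiseless_knee()
  cart <- array(as.integer(kn$atlas$labels) >= min(CARTILAGE_LABELS),
                dim(kn$atlas$labels))
  m <- compute_map(kn$series, "T1rho", cart)
  m$space <- "atlas"
  odd <- m
  odd$t <- as_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
  meta <- random_meta(3)
  maps <- setNames(list(m, m, odd), meta$knee_id)
  expect_error(stack_atlas_maps(maps, meta), meta$knee_id[3])
  maps_ok <- setNames(list(m, m, m), meta$knee_id)
  expect_error(stack_atlas_maps(maps_ok, meta[1:2, ]), "without maps|metadata")
  st <- stack_atlas_maps(maps_ok, meta, mask = cart)
  expect_identical(ncol(st$values), 3L)
  expect_identical(nrow(st$values), sum(cart))
})

test_that("stack depth equals cohort size minus the exclusion list", {
  spec <- cohort_spec()
  tab <- generate_subject_table(spec, seed = 303)
  excluded <- build_exclusion_list(tab)
  kept <- setdiff(tab$knee_id, excluded)
  expect_identical(length(kept) + length(excluded), nrow(tab))
  expect_true(all(vapply(kept, function(id) {
    g <- tab[tab$knee_id == id, grep("^noyes_", names(tab))]
    all(g == 0)
  }, NA)))
})

test_that("percentage-difference map: closed forms, antisymmetry, bounds", {
  expect_identical(as.numeric(percent_difference_map(3, 1)), 100)
  expect_identical(as.numeric(percent_difference_map(2, 2)), 0)
  set.seed(17)
  a <- runif(500, 20, 60); b <- runif(500, 20, 60)
  fwd <- percent_difference_map(a, b)
  rev <- percent_difference_map(b, a)
  expect_equal(as.numeric(fwd), -as.numeric(rev), tolerance = 1e-12)
  expect_true(all(abs(fwd) < 200))
  z <- percent_difference_map(c(1, 0), c(1, 0))
  expect_true(is.na(z[2]))
  expect_identical(attr(z, "n_undefined"), 1L)
})

test_that("voxel-wise ANCOVA agrees with the compartmental ANCOVA at every
           voxel", {
  set.seed(31)
  meta <- random_meta(20)
  vals <- matrix(rnorm(50 * 20, 40, 2), 50, 20)
  st <- make_stack(vals, meta)
  sm <- voxelwise_ancova(st)
  for (v in c(1, 17, 50)) {
    r <- ancova_group_effect(vals[v, ], meta)
    expect_lt(abs(sm$F[v] - r$statistic), 1e-10)
    expect_lt(abs(sm$p[v] - r$p_value), 1e-10)
  }
})

test_that("null stacks reject at the nominal rate; planted effects localize", {
  set.seed(61)
  meta <- random_meta(24)
  null_vals <- matrix(rnorm(5000 * 24, 40, 3), 5000, 24)
  sm0 <- voxelwise_ancova(make_stack(null_vals, meta))
  rate <- mean(sm0$p < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
  # planted effect in a voxel block ("MFC"), none elsewhere ("LT")
  eff <- null_vals
  eff[1:1000, meta$group == "A"] <- eff[1:1000, meta$group == "A"] * 1.06
  sm1 <- voxelwise_ancova(make_stack(eff, meta))
  frac_mfc <- mean(sm1$p[1:1000] < 0.05)
  frac_lt <- mean(sm1$p[4001:5000] < 0.05)
  expect_gt(frac_mfc, 5 * frac_lt)
})

test_that("single-voxel p equals the independent F-distribution tail", {
  set.seed(5)
  meta <- random_meta(14)
  y <- rnorm(14, 40, 1) + (meta$group == "A") * 2
  st <- make_stack(matrix(y, 1, 14), meta)
  sm <- voxelwise_ancova(st)
  # independent computation: RSS of full and reduced models by QR
  X <- model.matrix(~ factor(group, levels = c("B", "A")) + factor(gender) +
                      bmi + factor(site), meta)
  rss <- sum(qr.resid(qr(X), y)^2)
  X0 <- X[, -2]  # drop the group column
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  Fo <- (rss0 - rss) / (rss / (14 - ncol(X)))
  expect_equal(sm$p[1], pf(Fo, 1, 14 - ncol(X), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("per-voxel validity is respected: undefined below min_n", {
  set.seed(71)
  meta <- random_meta(12)
  vals <- matrix(rnorm(10 * 12, 40, 2), 10, 12)
  vals[1, meta$group == "A"] <- NA  # no group-A data at voxel 1
  vals[2, which(meta$group == "A")[1:4]] <- NA  # only 2 A-knees left
  st <- make_stack(vals, meta)
  sm <- voxelwise_ancova(st, min_n = 3)
  expect_true(is.na(sm$p[1]))
  expect_true(is.na(sm$p[2]))
  expect_false(anyNA(sm$p[3:10]))
})

test_that("compartment roll-up: degenerate p-maps and planted monotonicity", {
  kn <- noiseless_knee()
  cart <- array(as.integer(kn$atlas$labels) >= min(CARTILAGE_LABELS),
                dim(kn$atlas$labels))
  vox <- which(cart)
  base <- list(p = rep(1, length(vox)), F = rep(0, length(vox)),
               effect_pct = rep(0, length(vox)), alpha = 0.05,
               n_undefined = 0L, correction = "none",
               voxel_index = vox, dim = dim(cart), spacing = c(2.4, 2.4, 2.4))
  class(base) <- "stat_map"
  r1 <- compartment_rollup(base, kn$atlas)
  expect_true(all(r1$pct_significant == 0))
  base$p <- rep(0, length(vox))
  r0 <- compartment_rollup(base, kn$atlas)
  expect_true(all(r0$pct_significant == 100))
  # planted-effect monotonicity across 0 / 2 / 6 percent prolongations
  set.seed(91)
  meta <- random_meta(24)
  mfc_vox <- as.integer(kn$atlas$labels)[vox] == CARTILAGE_LABELS[["MFC"]]
  fracs <- vapply(c(0, 2, 6), function(pct) {
    vals <- matrix(rnorm(length(vox) * 24, 40, 2), length(vox), 24)
    vals[mfc_vox, meta$group == "A"] <-
      vals[mfc_vox, meta$group == "A"] + 40 * pct / 100
    st <- structure(list(values = vals, voxel_index = vox, dim = dim(cart),
                         spacing = c(2.4, 2.4, 2.4), meta = meta),
                    class = "vbr_stack")
    sm <- voxelwise_ancova(st)
    r <- compartment_rollup(sm, kn$atlas)
    r$pct_significant[r$compartment == "MFC"]
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("roll-up is invariant to voxel ordering", {
  kn <- noiseless_knee()
  cart <- array(as.integer(kn$atlas$labels) >= min(CARTILAGE_LABELS),
                dim(kn$atlas$labels))
  vox <- which(cart)
  set.seed(3)
  sm <- list(p = runif(length(vox)), F = NULL,
             effect_pct = rnorm(length(vox)), alpha = 0.05, n_undefined = 0L,
             correction = "none", voxel_index = vox, dim = dim(cart),
             spacing = c(2.4, 2.4, 2.4))
  class(sm) <- "stat_map"
  r <- compartment_rollup(sm, kn$atlas)
  ord <- sample(length(vox))
  sm2 <- sm
  sm2$p <- sm$p[ord]; sm2$effect_pct <- sm$effect_pct[ord]
  sm2$voxel_index <- vox[ord]
  r2 <- compartment_rollup(sm2, kn$atlas)
  expect_equal(r$pct_significant, r2$pct_significant, tolerance = 1e-12)
  expect_equal(r$avg_pct_difference, r2$avg_pct_difference, tolerance = 1e-12)
})
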