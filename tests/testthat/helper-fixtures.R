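# Shared fixtures, built once per test run and cached in this environment.
# All fixtures are small (coarse grids) so the suite stays fast; the
# acceptance tests use the study-scale geometry where a criterion requires it.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

test_spec <- function(...) {
  args <- modifyList(list(dim = 40, spacing_mm = c(2.4, 2.4, 2.4),
                          noise_sd = 0, deform_amplitude_mm = 0,
                          seed = 101L), list(...))
  do.call(cohort_spec, args)
}

# noiseless, undeformed knee: ground truth and fits should agree exactly
noiseless_knee <- function() {
  fixture("noiseless_knee", function()
    generate_subject_knee(test_spec(), "A", seed = 7))
}

# deformed pair on a 48^3 / 2 mm grid for registration tests
deformed_pair <- function() {
  fixture("deformed_pair", function() {
    spec <- cohort_spec(dim = 48, spacing_mm = c(2, 2, 2), noise_sd = 0,
                        deform_amplitude_mm = 8, seed = 2)
    list(spec = spec,
         atlas = generate_subject_knee(spec, "B", seed = 99,
                                       atlas_mode = TRUE),
         subject = generate_subject_knee(spec, "B", seed = 3))
  })
}

# small bone population with two planted orthogonal modes (SD 2 mm and 1 mm)
two_mode_population <- function() {
  fixture("two_mode_population", function() {
    modes <- list(
      list(centre = c(1, 0.5, 0.4), sigma = 0.45, sd_mm = 2),
      list(centre = c(-0.6, -1, 0.5), sigma = 0.45, sd_mm = 1))
    generate_bone_population(30, modes, seed = 42, dim = 64,
                             spacing_mm = c(1.1, 1.1, 1.1))
  })
}

# voxelized sphere mask, radius 20 mm
sphere_mask <- function(dim = 48, radius = 20) {
  c0 <- (dim - 1) / 2
  co <- expand.grid(x = 0:(dim - 1), y = 0:(dim - 1), z = 0:(dim - 1))
  r <- sqrt((co$x - c0)^2 + (co$y - c0)^2 + (co$z - c0)^2)
  m <- array(r <= radius, rep(dim, 3))
  attr(m, "spacing") <- c(1, 1, 1)
  m
}

# balanced metadata whose covariates are exactly orthogonal to group
orthogonal_meta <- function(n_per_group = 6) {
  half <- data.frame(
    gender = rep(c("F", "M"), length.out = n_per_group),
    bmi = seq(20, 30, length.out = n_per_group),
    site = rep(1:3, length.out = n_per_group))
  meta <- rbind(cbind(group = "A", half), cbind(group = "B", half))
  meta$knee_id <- sprintf("k%02d", seq_len(nrow(meta)))
  meta
}

random_meta <- function(n, p_a = 0.5) {
  data.frame(knee_id = sprintf("k%03d", seq_len(n)),
             group = ifelse(seq_len(n) <= round(n * p_a), "A", "B"),
             gender = sample(c("F", "M"), n, replace = TRUE),
             bmi = rnorm(n, 25, 4),
             site = sample(1:3, n, replace = TRUE))
}

# brute-force planted-mode oracle: covariance of the planted displacement
# fields (rigid-motion components projected out, since pose is quotiented
# away by the alignment step) evaluated at the population mean shape
planted_mode_oracle <- function(population, point_sets) {
  mu <- Reduce(`+`, point_sets) / length(point_sets)
  V <- nrow(mu)
  fields <- population$mode_displacements(mu)
  mc <- sweep(mu, 2, colMeans(mu))
  rigid <- cbind(
    as.numeric(cbind(rep(1, V), 0, 0)), as.numeric(cbind(0, rep(1, V), 0)),
    as.numeric(cbind(0, 0, rep(1, V))),
    as.numeric(cbind(-mc[, 2], mc[, 1], 0)),
    as.numeric(cbind(0, -mc[, 3], mc[, 2])),
    as.numeric(cbind(mc[, 3], 0, -mc[, 1])))
  Qr <- qr.Q(qr(rigid))
  proj <- function(f) { v <- as.numeric(f); v - Qr %*% crossprod(Qr, v) }
  Fp <- vapply(fields, function(f) as.numeric(proj(f)), numeric(3 * V))
  X <- population$true_scores %*% t(Fp)
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = ncol(Fp))
  list(eigenvalues = sv$d[seq_len(ncol(Fp))]^2 / (nrow(X) - 1),
       basis = qr.Q(qr(Fp)))
}

subspace_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  max(acos(pmin(svd(crossprod(qa, qb))$d, 1))) * 180 / pi
}

# profiled 1-D grid-search oracle for the mono-exponential fit: for each
# candidate T the optimal S0 is closed-form, so the grid is exhaustive in T
grid_search_t <- function(times, values, t_grid = seq(1, 200, by = 0.05)) {
  E <- exp(outer(-times, 1 / t_grid))
  s0 <- as.numeric(crossprod(values, E)) / colSums(E * E)
  rss <- colSums((values - E * rep(s0, each = length(times)))^2)
  t_grid[which.min(rss)]
}
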