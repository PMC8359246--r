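# Synthetic knee cohort with known ground truth.
#
# The generator builds a stylized knee (ellipsoidal femur, tibia and patella
# with shell cartilage labelled into the six standard compartments), simulates
# the combined T1rho/T2 acquisition as mono-exponential decay sharing the t = 0
# image, plants compartment- and layer-localized group effects, and applies a
# smooth invertible subject-specific deformation. Every quantity the analysis
# estimates is returned as ground truth.

CARTILAGE_COMPARTMENTS <- c("LFC", "MFC", "TRO", "PAT", "LT", "MT")
BONE_LABELS <- c(femur = 1L, tibia = 2L, patella = 3L)
CARTILAGE_LABELS <- c(LFC = 11L, MFC = 12L, TRO = 13L, PAT = 14L,
                      LT = 15L, MT = 16L)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic knee cohort
#'
#' Defaults reproduce the structure of the study the package emulates: two
#' groups of 40 and 25 subjects, spin-lock times 0/10/40/80 ms and echo times
#' 0/12.8/25.7/51.4 ms sharing the first image, compartment baseline T1rho in
#' 34.3--46.3 ms and T2 in 25.0--32.9 ms, a +10% superficial-layer gradient,
#' medial group effects of a few percent, and Noyes grade probabilities
#' matching the observed per-compartment frequencies.
#'
#' @param n_group_a,n_group_b subjects per group
#' @param tsl_ms spin-lock times (ms), strictly increasing from 0
#' @param te_ms echo times (ms), strictly increasing from 0
#' @param compartment_t1rho_ms,compartment_t2_ms named baseline relaxation
#'   times (ms) for LFC, MFC, TRO, PAT, LT, MT
#' @param group_effect_pct 6 x 2 matrix (compartments x deep/superficial) of
#'   percent prolongation in group A relative to group B
#' @param layer_gradient fractional prolongation of the superficial layer
#'   relative to the deep layer (0.10 = +10%)
#' @param noise_sd additive Gaussian noise SD in signal units (S0 = 1000)
#' @param noise_model "gaussian" (default) or "rician"
#' @param deform_amplitude_mm cap on subject-specific displacement magnitude
#' @param grade_probs list with elements `A` and `B`, each a named list of
#'   length-3 Noyes grade probability vectors per compartment
#' @param dim grid size (isotropic); @param spacing_mm voxel spacing (mm)
#' @param shell_mm cartilage shell thickness along the short axis (mm)
#' @param s0 baseline signal at t = 0
#' @param bilateral_prob probability a subject contributes both knees
#' @param seed integer seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_group_a = 40, n_group_b = 25,
                        tsl_ms = c(0, 10, 40, 80),
                        te_ms = c(0, 12.8, 25.7, 51.4),
                        compartment_t1rho_ms = c(LFC = 42, MFC = 40, TRO = 44,
                                                 PAT = 46, LT = 36, MT = 38),
                        compartment_t2_ms = c(LFC = 29, MFC = 28, TRO = 31,
                                              PAT = 32.5, LT = 25.5, MT = 26.5),
                        group_effect_pct = default_group_effects(),
                        layer_gradient = 0.10,
                        noise_sd = 20, noise_model = c("gaussian", "rician"),
                        deform_amplitude_mm = 3,
                        grade_probs = default_grade_probs(),
                        dim = 96, spacing_mm = c(1, 1, 1), s0 = 1000,
                        shell_mm = 3, bilateral_prob = 0.6, seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_times <- function(t, nm) {
    if (t[1] != 0) stop(nm, " must start at 0")
    if (any(diff(t) <= 0)) stop(nm, " must be strictly increasing")
    if (any(t < 0)) stop(nm, " must be nonnegative")
  }
  check_times(tsl_ms, "tsl_ms"); check_times(te_ms, "te_ms")
  stopifnot(all(compartment_t1rho_ms > 0), all(compartment_t2_ms > 0),
            setequal(names(compartment_t1rho_ms), CARTILAGE_COMPARTMENTS),
            setequal(names(compartment_t2_ms), CARTILAGE_COMPARTMENTS))
  for (g in c("A", "B")) for (comp in CARTILAGE_COMPARTMENTS) {
    p <- grade_probs[[g]][[comp]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("grade probabilities must sum to 1 for group ", g, ", ", comp)
  }
  spec <- list(n_group_a = n_group_a, n_group_b = n_group_b,
               tsl_ms = tsl_ms, te_ms = te_ms,
               compartment_t1rho_ms = compartment_t1rho_ms[CARTILAGE_COMPARTMENTS],
               compartment_t2_ms = compartment_t2_ms[CARTILAGE_COMPARTMENTS],
               group_effect_pct = group_effect_pct,
               layer_gradient = layer_gradient,
               noise_sd = noise_sd, noise_model = noise_model,
               deform_amplitude_mm = deform_amplitude_mm,
               grade_probs = grade_probs,
               dim = rep(dim, length.out = 3), spacing_mm = spacing_mm,
               s0 = s0, shell_mm = shell_mm, bilateral_prob = bilateral_prob,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @rdname cohort_spec
#' @export
default_group_effects <- function() {
  m <- matrix(0, nrow = 6, ncol = 2,
              dimnames = list(CARTILAGE_COMPARTMENTS, c("deep", "superficial")))
  m["MFC", ] <- c(6, 7)    # medial femoral prolongation in group A
  m["MT", ] <- c(5, 5)     # medial tibial prolongation in group A
  m["LFC", "deep"] <- 2.5  # weaker lateral association
  m
}

#' @rdname cohort_spec
#' @export
default_grade_probs <- function() {
  # per-group, per-compartment Noyes grade 0/1/2 frequencies among imaged knees
  a <- list(LFC = c(58, 1, 6), MFC = c(64, 0, 1), TRO = c(63, 1, 1),
            PAT = c(57, 2, 6), LT = c(63, 0, 2), MT = c(65, 0, 0))
  b <- list(LFC = c(48, 0, 0), MFC = c(47, 1, 0), TRO = c(48, 0, 0),
            PAT = c(46, 0, 2), LT = c(48, 0, 0), MT = c(48, 0, 0))
  list(A = lapply(a, function(x) x / sum(x)),
       B = lapply(b, function(x) x / sum(x)))
}

# ---- stylized knee geometry --------------------------------------------------

knee_geometry <- function(dims, sp, shell_mm = 3) {
  L <- (dims - 1) * sp
  list(
    femur = list(centre = c(0.50, 0.52, 0.70) * L,
                 semi = c(0.30, 0.24, 0.22) * min(L)),
    tibia = list(centre = c(0.50, 0.50, 0.21) * L,
                 semi = c(0.32, 0.26, 0.18) * min(L)),
    patella = list(centre = c(0.50, 0.14, 0.62) * L,
                   semi = c(0.15, 0.085, 0.12) * min(L)),
    shell_mm = shell_mm,  # cartilage shell thickness along the short axis
    L = L)
}

ellipsoid_radius <- function(coords, centre, semi) {
  sqrt(((coords[, 1] - centre[1]) / semi[1])^2 +
       ((coords[, 2] - centre[2]) / semi[2])^2 +
       ((coords[, 3] - centre[3]) / semi[3])^2)
}

#' Build the atlas-space knee template: labels and normalized cartilage depth
#'
#' @param spec a [cohort_spec()]
#' @return list with `atlas` (a `compartment_atlas`), `depth` (volume of
#'   normalized cartilage depth, 0 at bone interface to 1 at the articular
#'   surface, 0 outside cartilage)
#' @export
knee_template <- function(spec) {
  dims <- spec$dim; sp <- spec$spacing_mm
  geo <- knee_geometry(dims, sp, if (is.null(spec$shell_mm)) 3 else spec$shell_mm)
  # reject degenerate cartilage geometry before building anything
  if (geo$shell_mm < max(sp))
    stop("cartilage shell thinner than 1 voxel; increase resolution or shell")
  co <- voxel_coordinates(as_volume(array(0, dims), spacing = sp))
  rf <- ellipsoid_radius(co, geo$femur$centre, geo$femur$semi)
  rt <- ellipsoid_radius(co, geo$tibia$centre, geo$tibia$semi)
  rp <- ellipsoid_radius(co, geo$patella$centre, geo$patella$semi)
  # normalized shell width per bone: fixed physical thickness on the short axis
  shf <- geo$shell_mm / min(geo$femur$semi)
  sht <- geo$shell_mm / min(geo$tibia$semi)
  shp <- geo$shell_mm / min(geo$patella$semi)
  lab <- integer(nrow(co))
  lab[rf <= 1] <- BONE_LABELS[["femur"]]
  lab[rt <= 1] <- BONE_LABELS[["tibia"]]
  lab[rp <= 1] <- BONE_LABELS[["patella"]]
  depth <- numeric(nrow(co))
  in_bone <- lab > 0L
  cx <- geo$L[1] / 2
  # femoral cartilage: inferior/anterior shell, split TRO / LFC / MFC
  fsh <- !in_bone & rf > 1 & rf <= 1 + shf & co[, 3] <= geo$femur$centre[3]
  ant <- co[, 2] <= geo$femur$centre[2] - 0.55 * geo$femur$semi[2]
  lab[fsh & ant] <- CARTILAGE_LABELS[["TRO"]]
  lab[fsh & !ant & co[, 1] > cx] <- CARTILAGE_LABELS[["LFC"]]
  lab[fsh & !ant & co[, 1] <= cx] <- CARTILAGE_LABELS[["MFC"]]
  depth[fsh] <- (rf[fsh] - 1) / shf
  # tibial cartilage: superior shell, lateral / medial
  tsh <- !in_bone & lab == 0L & rt > 1 & rt <= 1 + sht &
    co[, 3] >= geo$tibia$centre[3]
  lab[tsh & co[, 1] > cx] <- CARTILAGE_LABELS[["LT"]]
  lab[tsh & co[, 1] <= cx] <- CARTILAGE_LABELS[["MT"]]
  depth[tsh] <- (rt[tsh] - 1) / sht
  # patellar cartilage: posterior shell
  psh <- !in_bone & lab == 0L & rp > 1 & rp <= 1 + shp &
    co[, 2] >= geo$patella$centre[2]
  lab[psh] <- CARTILAGE_LABELS[["PAT"]]
  depth[psh] <- (rp[psh] - 1) / shp
  atlas <- compartment_atlas(as_volume(lab, dims, sp))
  list(atlas = atlas, depth = as_volume(depth, dims, sp))
}

# ground-truth relaxation fields on a labelled grid
relaxation_ground_truth <- function(spec, atlas, depth, group) {
  lab <- as.integer(atlas$labels)
  superf <- as.numeric(depth) > 0.5
  t1 <- numeric(length(lab)); t2 <- numeric(length(lab))
  for (comp in CARTILAGE_COMPARTMENTS) {
    sel <- lab == CARTILAGE_LABELS[[comp]]
    eff <- if (group == "A") spec$group_effect_pct[comp, ] / 100 else c(0, 0)
    lay <- ifelse(superf[sel], 2L, 1L)
    gain <- (1 + c(eff[1], eff[2])[lay]) *
      (1 + spec$layer_gradient * (lay == 2L))
    t1[sel] <- spec$compartment_t1rho_ms[[comp]] * gain
    t2[sel] <- spec$compartment_t2_ms[[comp]] * gain
  }
  d <- dim(atlas$labels); sp <- spacing(atlas$labels)
  list(t1rho = as_volume(t1, d, sp), t2 = as_volume(t2, d, sp))
}

# ---- smooth invertible deformations -----------------------------------------

random_displacement <- function(dims, sp, amplitude_mm, n_ctrl = 5) {
  n <- prod(dims)
  u <- array(0, c(dims, 3))
  # small random affine about the volume centre
  ang <- runif(3, -1.5, 1.5) * pi / 180
  tr <- runif(3, -0.5, 0.5) * amplitude_mm
  R <- rotation_matrix(ang)
  centre <- (dims - 1) * sp / 2
  co <- voxel_coordinates(as_volume(array(0, dims), spacing = sp))
  aff <- sweep(co, 2, centre) %*% (t(R) - diag(3))
  aff <- sweep(aff, 2, tr, "+")
  # low-frequency random field from a coarse control grid
  for (c in 1:3) {
    ctrl <- array(rnorm(n_ctrl^3), rep(n_ctrl, 3))
    u[, , , c] <- array(resize_trilinear_cpp(ctrl, rep(n_ctrl, 3L), dims),
                        dims) + array(aff[, c], dims)
  }
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  mx <- max(mag)
  if (mx > 0) u <- u * (amplitude_mm / mx)
  u
}

#' Numerically invert a displacement field (fixed-point iteration)
#'
#' @param field displacement array (dims x 3) in mm on a grid with `spacing`
#' @param spacing voxel spacing (mm)
#' @param iters fixed-point iterations
#' @return displacement array of the inverse mapping
#' @export
invert_displacement <- function(field, spacing = c(1, 1, 1), iters = 25) {
  dims <- dim(field)[1:3]
  w <- array(0, dim(field))
  for (it in seq_len(iters)) {
    wn <- array(0, dim(field))
    for (c in 1:3)
      wn[, , , c] <- -array(resample_field_cpp(field[, , , c], dims, spacing,
                                               as.numeric(w), FALSE, 0), dims)
    w <- wn
  }
  w
}

apply_displacement_vol <- function(v, field, nearest = FALSE) {
  as_volume(resample_field_cpp(as.numeric(v), dim(v), spacing(v),
                               as.numeric(field), nearest, 0),
            dim(v), spacing(v))
}

# ---- per-knee synthesis ------------------------------------------------------

#' Generate one synthetic knee: image series, labels, and ground truth
#'
#' Signal volumes follow S(t) = S0 exp(-t / T) for each spin-lock time
#' (T = T1rho) and echo time (T = T2), sharing the t = 0 image, with additive
#' noise. A smooth invertible subject-specific deformation is applied to all
#' volumes; the displacement that maps the knee back onto the atlas grid is
#' stored in the ground truth.
#'
#' @param spec a [cohort_spec()]
#' @param group `"A"` or `"B"`
#' @param seed integer seed for this knee
#' @param atlas_mode if TRUE, no deformation is applied (used to designate the
#'   atlas subject)
#' @return list with `series` (a `mapped_series`), `atlas`
#'   (`compartment_atlas` in subject space), and `truth` (list: `t1rho`, `t2`,
#'   `s0`, `depth`, `deformation_to_atlas` or NULL)
#' @export
generate_subject_knee <- function(spec, group = c("A", "B"), seed = spec$seed,
                                  atlas_mode = FALSE) {
  group <- match.arg(group)
  tpl <- knee_template(spec)
  with_seed(seed, {
    gt <- relaxation_ground_truth(spec, tpl$atlas, tpl$depth, group)
    labels <- tpl$atlas$labels
    depth <- tpl$depth
    field_back <- NULL
    if (!atlas_mode && spec$deform_amplitude_mm > 0) {
      u <- random_displacement(spec$dim, spec$spacing_mm,
                               spec$deform_amplitude_mm)
      # subject volumes are the template pulled back through u; the stored
      # field is the numeric inverse, which transports the subject to atlas
      labels <- apply_displacement_vol(labels, u, nearest = TRUE)
      depth <- apply_displacement_vol(depth, u, nearest = TRUE)
      gt$t1rho <- apply_displacement_vol(gt$t1rho, u, nearest = TRUE)
      gt$t2 <- apply_displacement_vol(gt$t2, u, nearest = TRUE)
      field_back <- invert_displacement(u, spec$spacing_mm)
    }
    cart <- as.numeric(labels) >= min(CARTILAGE_LABELS)
    s0vol <- numeric(length(cart))
    s0vol[cart] <- spec$s0
    # modest bone/background signal so registration has structure to work with
    s0vol[as.numeric(labels) %in% BONE_LABELS] <- spec$s0 * 0.35
    d <- dim(labels); sp <- spacing(labels)
    decay <- function(tms, tvol) {
      s <- s0vol
      tv <- as.numeric(tvol)
      s[cart] <- spec$s0 * exp(-tms / tv[cart])
      if (spec$noise_sd > 0) {
        if (spec$noise_model == "gaussian") {
          s <- s + rnorm(length(s), 0, spec$noise_sd)
        } else {
          s <- sqrt((s + rnorm(length(s), 0, spec$noise_sd))^2 +
                    rnorm(length(s), 0, spec$noise_sd)^2)
        }
      }
      as_volume(s, d, sp)
    }
    vols <- list(decay(0, gt$t1rho))
    index <- data.frame(parameter = "T1rho", time_ms = 0, volume = 1L)
    vi <- 1L
    for (t in spec$tsl_ms[-1]) {
      vi <- vi + 1L
      vols[[vi]] <- decay(t, gt$t1rho)
      index <- rbind(index, data.frame(parameter = "T1rho", time_ms = t,
                                       volume = vi))
    }
    index <- rbind(index, data.frame(parameter = "T2", time_ms = 0,
                                     volume = 1L))  # shared first image
    for (t in spec$te_ms[-1]) {
      vi <- vi + 1L
      vols[[vi]] <- decay(t, gt$t2)
      index <- rbind(index, data.frame(parameter = "T2", time_ms = t,
                                       volume = vi))
    }
    series <- structure(list(volumes = vols, index = index),
                        class = "mapped_series")
    truth <- list(t1rho = gt$t1rho, t2 = gt$t2,
                  s0 = as_volume(s0vol, d, sp), depth = depth,
                  deformation_to_atlas = field_back)
    list(series = series,
         atlas = compartment_atlas(labels),
         truth = truth)
  })
}

#' @export
print.mapped_series <- function(x, ...) {
  cat(sprintf("<mapped_series> %d distinct volumes; %s\n", length(x$volumes),
              paste(sprintf("%s: %s ms", unique(x$index$parameter),
                            vapply(split(x$index$time_ms, x$index$parameter),
                                   function(t) paste(t, collapse = "/"), "")),
                    collapse = "; ")))
  invisible(x)
}

# ---- bone shape population ---------------------------------------------------

#' Generate a population of bone masks with planted low-rank shape modes
#'
#' Each planted mode is a smooth radial surface perturbation (a Gaussian bump
#' on the ellipsoid surface, e.g. scaling of the lateral plateau) whose
#' per-subject score is drawn from a normal distribution with the stated SD in
#' mm. The planted scores are returned for recovery testing.
#'
#' @param n population size (>= 2)
#' @param mode_spec list of modes; each a list with `centre` (unit-ellipsoid
#'   direction, length 3), `sigma` (angular width, normalized units) and
#'   `sd_mm` (score SD in mm)
#' @param seed integer seed
#' @param dim,spacing_mm grid geometry
#' @param standardize_scores if TRUE (default) drawn scores are centred,
#'   decorrelated across modes and rescaled so the planted score covariance
#'   is exactly diagonal with the nominal SDs
#' @param fixed_features list of asymmetric surface features (centre, sigma,
#'   amp_mm) shared by every subject; bones have no mirror symmetry, and
#'   these features anchor the mesh correspondence the way real anatomy does
#' @return list with `masks` (list of logical volumes), `true_scores`
#'   (n x n_modes, mm), and `mode_fields` (function giving each mode's radial
#'   weight at mesh points, for support checks)
#' @export
generate_bone_population <- function(n, mode_spec, seed = 1L, dim = 48,
                                     spacing_mm = c(1.5, 1.5, 1.5),
                                     standardize_scores = TRUE,
                                     fixed_features = list(
                                       list(centre = c(0.3, 1, -0.4),
                                            sigma = 0.5, amp_mm = 4),
                                       list(centre = c(-1, 0.2, 0.7),
                                            sigma = 0.45, amp_mm = -3),
                                       list(centre = c(0.6, -0.9, 0.8),
                                            sigma = 0.4, amp_mm = 3))) {
  stopifnot(n >= 2)
  dims <- rep(dim, length.out = 3)
  L <- (dims - 1) * spacing_mm
  centre <- L / 2
  semi <- c(0.38, 0.30, 0.24) * min(L)
  co <- voxel_coordinates(as_volume(array(0, dims), spacing = spacing_mm))
  r <- ellipsoid_radius(co, centre, semi)
  dirs <- sweep(sweep(co, 2, centre), 2, semi, "/")
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / pmax(nrm, 1e-9)
  rbar <- mean(semi)
  # per-mode angular weight, normalized so a unit score displaces the surface
  # by 1 mm RMS: planted variances are then exactly the squared score SDs
  fib <- (1 + sqrt(5)) * pi
  ii <- seq_len(2000) - 0.5
  thf <- acos(1 - 2 * ii / 2000); phf <- fib * ii
  dens <- cbind(sin(thf) * cos(phf), sin(thf) * sin(phf), cos(thf))
  mode_norm <- vapply(mode_spec, function(md) {
    cdir <- md$centre / sqrt(sum(md$centre^2))
    g <- exp(-rowSums(sweep(dens, 2, cdir)^2) / (2 * md$sigma^2))
    amag <- sqrt(rowSums(sweep(dens, 2, semi, "*")^2))
    sqrt(mean((g * amag / rbar)^2))
  }, 0)
  weights <- lapply(seq_along(mode_spec), function(m) {
    md <- mode_spec[[m]]
    cdir <- md$centre / sqrt(sum(md$centre^2))
    d2 <- rowSums(sweep(dirs, 2, cdir)^2)
    exp(-d2 / (2 * md$sigma^2)) / mode_norm[m]
  })
  base_bump <- numeric(nrow(co))
  for (ff in fixed_features) {
    cdir <- ff$centre / sqrt(sum(ff$centre^2))
    base_bump <- base_bump + ff$amp_mm *
      exp(-rowSums(sweep(dirs, 2, cdir)^2) / (2 * ff$sigma^2)) / rbar
  }
  with_seed(seed, {
    nm <- length(mode_spec)
    scores <- matrix(0, n, nm)
    for (m in seq_len(nm)) scores[, m] <- rnorm(n, 0, mode_spec[[m]]$sd_mm)
    if (standardize_scores && n > nm) {
      # the planted score covariance holds exactly, not just in expectation:
      # centre, orthogonalize across modes, and rescale to the nominal SDs
      sc <- sweep(scores, 2, colMeans(scores))
      sc <- qr.Q(qr(sc))
      sds <- vapply(mode_spec, function(md) md$sd_mm, 0)
      scores <- sweep(sc, 2, sqrt(n - 1) * sds, "*")
    }
    for (m in seq_len(nm)) {
      # truncate extreme draws so level-set masks stay connected
      lim <- 2.5 * mode_spec[[m]]$sd_mm
      scores[, m] <- pmin(pmax(scores[, m], -lim), lim)
    }
    masks <- vector("list", n)
    for (s in seq_len(n)) {
      bump <- base_bump
      for (m in seq_len(nm)) bump <- bump + scores[s, m] * weights[[m]] / rbar
      if (any(1 + bump <= 0.15))
        stop("mode amplitudes break mask connectivity")
      inside <- r <= 1 + bump
      mk <- as_volume(as.numeric(inside), dims, spacing_mm)
      masks[[s]] <- mk
    }
    base_mask <- as_volume(as.numeric(r <= 1 + base_bump), dims, spacing_mm)
    mode_field_at <- function(points_mm) {
      dd <- sweep(sweep(points_mm, 2, centre), 2, semi, "/")
      dn <- sqrt(rowSums(dd^2))
      dd <- dd / pmax(dn, 1e-9)
      sapply(seq_along(mode_spec), function(m) {
        md <- mode_spec[[m]]
        cdir <- md$centre / sqrt(sum(md$centre^2))
        exp(-rowSums(sweep(dd, 2, cdir)^2) / (2 * md$sigma^2)) / mode_norm[m]
      })
    }
    # analytic per-mode displacement field (mm per unit score) at mm points:
    # the derivative of the level-set surface with respect to the mode score
    mode_displacement_at <- function(points_mm) {
      dd <- sweep(sweep(points_mm, 2, centre), 2, semi, "/")
      dn <- sqrt(rowSums(dd^2))
      dhat <- dd / pmax(dn, 1e-9)
      adir <- sweep(dhat, 2, semi, "*")
      W <- mode_field_at(points_mm)
      lapply(seq_along(mode_spec), function(m) adir * (W[, m] / rbar))
    }
    list(masks = masks, base_mask = base_mask, true_scores = scores,
         mode_fields = mode_field_at,
         mode_displacements = mode_displacement_at,
         geometry = list(centre = centre, semi = semi, rbar = rbar))
  })
}

#' Corresponded surface point sets for a bone population
#'
#' Maps vertices sampled on the base (zero-score) bone surface onto each
#' subject's surface through the planted displacement fields, yielding point
#' sets in exact material correspondence: the reference input for shape-model
#' recovery tests, independent of any estimated mesh correspondence.
#'
#' @param population result of [generate_bone_population()]
#' @param base_vertices V x 3 matrix of points on the base surface (e.g.
#'   vertices of a decimated [extract_surface()] mesh of `base_mask`)
#' @param scores score matrix (default the population's true scores)
#' @return list of V x 3 matrices, one per row of `scores`
#' @export
bone_pointsets <- function(population, base_vertices,
                           scores = population$true_scores) {
  fields <- population$mode_displacements(base_vertices)
  lapply(seq_len(nrow(scores)), function(s) {
    P <- base_vertices
    for (m in seq_along(fields)) P <- P + scores[s, m] * fields[[m]]
    P
  })
}

# ---- phantom -----------------------------------------------------------------

#' Simulate the repeatability phantom: decaying series per vial and scanner
#'
#' The phantom holds two instances of three gel concentrations (six vials).
#' Each scanner images the phantom `n_repeats` times; decay series are
#' mono-exponential with additive Gaussian noise.
#'
#' @param reference_t_ms length-3 reference relaxation times (ms), one per
#'   concentration
#' @param n_repeats repeats per scanner (>= 2 for intra-scanner CV)
#' @param noise_sd additive noise SD (signal units, S0 = 1000)
#' @param seed integer seed
#' @param n_scanners number of scanners (>= 2 for inter-scanner CV)
#' @param times_ms sampling times of the decay (ms)
#' @param n_instances instances per concentration
#' @param scanner_bias_sd SD of the multiplicative between-scanner bias on T
#' @return data.frame with columns scanner, rep, vial, instance,
#'   reference_t_ms, time_ms, signal
#' @export
generate_phantom_series <- function(reference_t_ms, n_repeats, noise_sd,
                                    seed = 1L, n_scanners = 1,
                                    times_ms = c(0, 10, 40, 80),
                                    n_instances = 2, scanner_bias_sd = 0) {
  stopifnot(length(reference_t_ms) == 3, n_repeats >= 1)
  s0 <- 1000
  with_seed(seed, {
    out <- list()
    vial <- 0L
    for (inst in seq_len(n_instances)) for (cc in seq_along(reference_t_ms)) {
      vial <- vial + 1L
      for (sc in seq_len(n_scanners)) {
        bias <- if (scanner_bias_sd > 0) exp(rnorm(1, 0, scanner_bias_sd)) else 1
        for (rp in seq_len(n_repeats)) {
          sig <- s0 * exp(-times_ms / (reference_t_ms[cc] * bias))
          if (noise_sd > 0) sig <- sig + rnorm(length(sig), 0, noise_sd)
          out[[length(out) + 1L]] <-
            data.frame(scanner = sc, rep = rp, vial = vial, instance = inst,
                       reference_t_ms = reference_t_ms[cc],
                       time_ms = times_ms, signal = sig)
        }
      }
    }
    do.call(rbind, out)
  })
}

# ---- subject metadata --------------------------------------------------------

#' Generate the per-knee subject table
#'
#' Subjects contribute one or both knees (bilateral with probability
#' `spec$bilateral_prob`); per-knee Noyes grades are drawn from the spec's
#' per-group, per-compartment grade probabilities.
#'
#' @param spec a [cohort_spec()]
#' @param seed integer seed
#' @return data.frame with columns knee_id, subject_id, group, gender, bmi,
#'   site, and noyes_LFC ... noyes_MT
#' @export
generate_subject_table <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    rows <- list()
    for (g in c("A", "B")) {
      nsub <- if (g == "A") spec$n_group_a else spec$n_group_b
      bmi_mu <- if (g == "A") 24.6 else 25.4
      bmi_sd <- if (g == "A") 5.6 else 4.9
      for (s in seq_len(nsub)) {
        sid <- sprintf("%s%02d", g, s)
        knees <- if (runif(1) < spec$bilateral_prob) c("L", "R") else
          sample(c("L", "R"), 1)
        gender <- sample(c("F", "M"), 1)
        bmi <- max(16, rnorm(1, bmi_mu, bmi_sd))
        site <- sample(1:3, 1)
        for (kn in knees) {
          grades <- vapply(CARTILAGE_COMPARTMENTS, function(comp)
            sample(0:2, 1, prob = spec$grade_probs[[g]][[comp]]), 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            knee_id = paste0(sid, "_", kn), subject_id = sid, group = g,
            gender = gender, bmi = bmi, site = site,
            t(setNames(grades, paste0("noyes_", CARTILAGE_COMPARTMENTS))))
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })
}
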