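# Image registration: rigid alignment of echoes within a knee, and nonrigid
# morphing of each knee onto the atlas. Self-contained multi-resolution
# implementations with a documented plug-in seam (`backend` argument) so an
# external registration engine can be substituted; any backend must satisfy
# the same recovery invariants.

#' Rotation matrix from intrinsic ZYX Euler angles (radians)
#' @param angles length-3 angles (rx, ry, rz)
#' @return 3x3 rotation matrix
#' @export
rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Construct a rigid transform (rotation about the volume centre + translation)
#' @param angles rotation angles in radians (intrinsic ZYX)
#' @param translation offsets in mm
#' @param warning_flag TRUE when the optimizer failed to improve on identity
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            warning_flag = FALSE) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 convention = "intrinsic ZYX about volume centre",
                 warning_flag = warning_flag),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (deg): %s; translation (mm): %s%s\n",
              paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", "),
              if (x$warning_flag) " [identity fallback]" else ""))
  invisible(x)
}

is_label_volume <- function(v) {
  isTRUE(attr(v, "labels")) || inherits(v, "compartment_atlas")
}

volume_centre_mm <- function(v) (dim(v) - 1) * spacing(v) / 2

#' Apply a rigid transform or deformation field to a volume
#'
#' Intensity volumes should use linear interpolation and label volumes
#' nearest-neighbour; passing `interpolation = "linear"` for a volume flagged
#' as labels is an error (it would average label codes).
#'
#' @param volume a volume (array with spacing)
#' @param transform a `rigid_transform` or `deformation_field`
#' @param interpolation `"linear"` or `"nearest"`
#' @return the resampled volume on the target grid
#' @export
apply_transform <- function(volume, transform,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (interpolation == "linear" && is_label_volume(volume))
    stop("linear interpolation on a label volume; use interpolation = 'nearest'")
  nearest <- interpolation == "nearest"
  d <- dim(volume)[1:3]; sp <- spacing(volume)
  lab <- attr(volume, "labels")
  if (inherits(transform, "rigid_transform")) {
    R <- rotation_matrix(transform$angles)
    out <- resample_affine_cpp(as.numeric(volume), d, sp, R,
                               transform$translation, volume_centre_mm(volume),
                               nearest, 0)
  } else if (inherits(transform, "deformation_field")) {
    if (!identical(dim(transform$displacement)[1:3], d))
      stop("deformation field is not defined over the volume's grid")
    out <- resample_field_cpp(as.numeric(volume), d, sp,
                              as.numeric(transform$displacement), nearest, 0)
  } else stop("unknown transform type")
  v <- as_volume(out, d, sp)
  if (!is.null(lab)) attr(v, "labels") <- lab
  v
}

downsample_volume <- function(v, factor) {
  if (factor <= 1) return(v)
  d <- dim(v)
  nd <- pmax(as.integer(ceiling(d / factor)), 2L)
  sm <- smooth_volume(v, sigma_mm = 0.5 * factor * spacing(v))
  nsp <- (d - 1) * spacing(v) / (nd - 1)
  as_volume(resize_trilinear_cpp(as.numeric(sm), d, nd), nd, nsp)
}

# normalized mutual information from a Parzen-windowed joint histogram
nmi_similarity <- function(a, b, nbins = 32) {
  H <- hist2d_parzen_cpp(as.numeric(a), as.numeric(b), nbins,
                         min(a), max(a), min(b), max(b))
  P <- H / sum(H)
  pa <- rowSums(P); pb <- colSums(P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- ent(as.numeric(P))
  if (hj <= 0) return(2)
  (ent(pa) + ent(pb)) / hj
}

#' Rigidly register a moving volume to a fixed volume
#'
#' Multi-resolution search over 3 rotation angles and 3 translations,
#' maximizing normalized mutual information (Parzen-windowed joint histogram).
#' Deterministic: the optimizer is derivative-free from a fixed start.
#'
#' @param moving,fixed volumes on the same grid
#' @param levels downsampling factors, coarse to fine
#' @param nbins histogram bins for the similarity
#' @param maxit optimizer iterations per level
#' @param presmooth_vox Gaussian pre-smoothing (in voxels) applied to both
#'   images at every level; stabilizes the similarity on low-SNR echoes
#' @return a `rigid_transform` taking `moving` onto `fixed` (i.e.
#'   `apply_transform(moving, transform)` matches `fixed`); if the similarity
#'   could not be improved over identity, identity is returned with
#'   `warning_flag = TRUE`
#' @export
register_rigid <- function(moving, fixed, levels = c(4, 2, 1), nbins = 32,
                           maxit = 400, presmooth_vox = 0.75) {
  stop_if_grid_mismatch(moving, fixed)
  if (presmooth_vox > 0) {
    moving <- smooth_volume(moving, presmooth_vox * spacing(moving))
    fixed <- smooth_volume(fixed, presmooth_vox * spacing(fixed))
  }
  par <- rep(0, 6)
  for (f in levels) {
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    d <- dim(mv); sp <- spacing(mv); ctr <- volume_centre_mm(mv)
    obj <- function(p) {
      w <- resample_affine_cpp(as.numeric(mv), d, sp, rotation_matrix(p[1:3]),
                               p[4:6], ctr, FALSE, 0)
      -nmi_similarity(fx, w, nbins)
    }
    res <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12,
                                parscale = c(rep(0.01, 3), rep(1, 3))))
    par <- res$par
  }
  # guard: did the optimum actually improve on identity at full resolution?
  d <- dim(moving); sp <- spacing(moving); ctr <- volume_centre_mm(moving)
  score <- function(p) {
    w <- resample_affine_cpp(as.numeric(moving), d, sp,
                             rotation_matrix(p[1:3]), p[4:6], ctr, FALSE, 0)
    nmi_similarity(fixed, w, nbins)
  }
  if (score(par) < score(rep(0, 6)) - 1e-9) {
    warning("rigid registration failed to improve on identity")
    return(rigid_transform(warning_flag = TRUE))
  }
  rigid_transform(par[1:3], par[4:6])
}

#' Construct a deformation field on a reference grid
#' @param displacement (n1, n2, n3, 3) array of mm displacements
#' @param spacing voxel spacing of the reference (atlas) grid
#' @return object of class `deformation_field`
#' @export
deformation_field <- function(displacement, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(displacement)) == 4, dim(displacement)[4] == 3,
            all(is.finite(displacement)))
  structure(list(displacement = displacement, spacing = as.numeric(spacing)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
  cat(sprintf("<deformation_field> %s grid, |u| mean %.3f / max %.3f mm\n",
              paste(dim(x$displacement)[1:3], collapse = "x"),
              mean(mag), max(mag)))
  invisible(x)
}

#' Jacobian determinant of the mapping x -> x + u(x)
#' @param field a `deformation_field`
#' @return volume of determinants
#' @export
jacobian_determinant <- function(field) {
  d <- dim(field$displacement)[1:3]; sp <- field$spacing
  G <- array(0, c(prod(d), 3, 3))
  for (c in 1:3)
    G[, c, ] <- matrix(gradient_cpp(field$displacement[, , , c], d, sp),
                       ncol = 3)
  J <- (1 + G[, 1, 1]) * ((1 + G[, 2, 2]) * (1 + G[, 3, 3]) - G[, 2, 3] * G[, 3, 2]) -
    G[, 1, 2] * (G[, 2, 1] * (1 + G[, 3, 3]) - G[, 2, 3] * G[, 3, 1]) +
    G[, 1, 3] * (G[, 2, 1] * G[, 3, 2] - (1 + G[, 2, 2]) * G[, 3, 1])
  as_volume(J, d, sp)
}

robust_rescale <- function(v) {
  q <- quantile(as.numeric(v), c(0.01, 0.999))
  if (q[2] <= q[1]) return(as_volume(array(0, dim(v)), spacing = spacing(v)))
  as_volume(pmin(pmax((as.numeric(v) - q[1]) / (q[2] - q[1]), 0), 1),
            dim(v), spacing(v))
}

#' Nonrigid registration of a moving volume to the atlas
#'
#' Multi-resolution dense free-form registration: at each level a
#' displacement-field update driven by the intensity residual and the warped
#' image gradient (demons-type forces) is applied, with Gaussian fluid/elastic
#' regularization that keeps the field smooth and invertible in practice.
#' Coarse levels capture bulk shape differences; fine levels refine
#' cartilage-scale structure.
#'
#' @param moving volume to deform (subject t = 0 image)
#' @param atlas fixed reference volume on the same grid
#' @param config list of settings: `levels` (downsampling factors),
#'   `iterations` per level, `sigma_fluid_mm`, `sigma_elastic_mm`,
#'   `step_mm` (max update per iteration), `min_overlap` (required foreground
#'   overlap fraction)
#' @return a `deformation_field` `u` on the atlas grid such that
#'   `apply_transform(moving, u)` matches the atlas
#' @export
register_nonrigid <- function(moving, atlas, config = list()) {
  stop_if_grid_mismatch(moving, atlas)
  cfg <- modifyList(list(levels = c(4, 2, 1), iterations = c(200, 120, 60),
                         sigma_fluid_vox = 2.5, sigma_elastic_vox = 1.5,
                         presmooth_vox = 0.7, step_frac = 0.6,
                         min_overlap = 0.2), config)
  Mn <- robust_rescale(moving); Fn <- robust_rescale(atlas)
  fg_m <- as.numeric(Mn) > 0.05; fg_f <- as.numeric(Fn) > 0.05
  ov <- sum(fg_m & fg_f) / max(1, min(sum(fg_m), sum(fg_f)))
  if (ov < cfg$min_overlap)
    stop(sprintf("foreground overlap %.2f below %.2f: wrong anatomy?",
                 ov, cfg$min_overlap))
  u <- NULL
  for (li in seq_along(cfg$levels)) {
    f <- cfg$levels[li]
    Ml <- downsample_volume(Mn, f); Fl <- downsample_volume(Fn, f)
    d <- dim(Ml); sp <- spacing(Ml)
    if (cfg$presmooth_vox > 0) {
      Ml <- smooth_volume(Ml, cfg$presmooth_vox * sp)
      Fl <- smooth_volume(Fl, cfg$presmooth_vox * sp)
    }
    if (is.null(u)) {
      u <- array(0, c(d, 3))
    } else {
      uo <- u; do <- dim(uo)[1:3]
      u <- array(0, c(d, 3))
      for (c in 1:3)
        u[, , , c] <- array(resize_trilinear_cpp(uo[, , , c], do, d), d)
    }
    step_mm <- cfg$step_frac * min(sp)
    best <- Inf; best_u <- u; stall <- 0
    for (it in seq_len(cfg$iterations[li])) {
      Mw <- resample_field_cpp(as.numeric(Ml), d, sp, as.numeric(u), FALSE, 0)
      diffv <- as.numeric(Fl) - Mw
      ssd <- sum(diffv^2)
      if (!is.finite(best) || ssd < best * (1 - 1e-6)) {
        best <- ssd; best_u <- u; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= 4) break
      }
      g <- matrix(gradient_cpp(Mw, d, sp), ncol = 3)
      gn2 <- rowSums(g^2)
      denom <- gn2 + (diffv / min(sp))^2
      denom[denom < 1e-9] <- 1e-9
      vstep <- g * (diffv / denom)
      vmag <- sqrt(rowSums(vstep^2))
      cap <- pmin(1, step_mm / pmax(vmag, 1e-12))
      vstep <- vstep * cap
      vf <- array(vstep, c(d, 3))
      for (c in 1:3)
        vf[, , , c] <- array(gauss_smooth_cpp(vf[, , , c], d,
                                              rep(cfg$sigma_fluid_vox, 3)), d)
      u <- u + vf
      for (c in 1:3)
        u[, , , c] <- array(gauss_smooth_cpp(u[, , , c], d,
                                             rep(cfg$sigma_elastic_vox, 3)), d)
    }
    u <- best_u
  }
  # bring the field to the full-resolution atlas grid
  dfull <- dim(atlas); do <- dim(u)[1:3]
  uf <- array(0, c(dfull, 3))
  for (c in 1:3)
    uf[, , , c] <- array(resize_trilinear_cpp(u[, , , c], do, dfull), dfull)
  deformation_field(uf, spacing(atlas))
}

#' Transport every volume of a mapped series with a knee's transforms
#'
#' Applies the within-knee rigid transform (if any) followed by the nonrigid
#' field, mirroring the study's order: the transforms estimated on the t = 0
#' volume are applied to all other echo / spin-lock volumes, and maps are then
#' fitted in atlas space.
#'
#' @param series a `mapped_series`
#' @param rigid optional `rigid_transform` (applied first)
#' @param field optional `deformation_field`
#' @return the transported `mapped_series`
#' @export
transport_series <- function(series, rigid = NULL, field = NULL) {
  series$volumes <- lapply(series$volumes, function(v) {
    if (!is.null(rigid)) v <- apply_transform(v, rigid, "linear")
    if (!is.null(field)) v <- apply_transform(v, field, "linear")
    v
  })
  series
}
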