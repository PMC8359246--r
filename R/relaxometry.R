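# Voxel-wise mono-exponential relaxometry: S(t) = S0 * exp(-t / T).
#
# The fitter is a damped Gauss-Newton (Levenberg-Marquardt) iteration run
# simultaneously over all voxels, seeded by a log-linear regression of
# ln S on t over the positive samples. T is constrained to (0, t_max].

# Vectorized LM over columns of Y (one column per voxel).
monoexp_fit_matrix <- function(times, Y, t_max = 200, max_iter = 60,
                               tol = 1e-12, init = NULL) {
  nt <- length(times)
  nv <- ncol(Y)
  stopifnot(nrow(Y) == nt, nt >= 3)
  valid <- colSums(Y > 0) >= 2 & apply(Y, 2, function(col) any(col != 0))
  # log-linear initialization on positive samples
  if (is.null(init)) {
    s0 <- rep(NA_real_, nv); tt <- rep(NA_real_, nv)
    for (v in which(valid)) {
      pos <- Y[, v] > 0
      if (sum(pos) >= 2) {
        ly <- log(Y[pos, v]); tp <- times[pos]
        b <- cov(tp, ly) / max(var(tp), 1e-12)
        a <- mean(ly) - b * mean(tp)
        tt[v] <- if (b < 0) -1 / b else t_max
        s0[v] <- exp(a)
      } else {
        tt[v] <- t_max / 4; s0[v] <- max(Y[, v])
      }
    }
  } else {
    s0 <- rep(init[1], nv); tt <- rep(init[2], nv)
  }
  tt <- pmin(pmax(tt, 1e-3), t_max)
  s0 <- pmax(s0, 1e-9)
  lambda <- rep(1e-3, nv)
  act <- valid
  rss <- rep(NA_real_, nv)
  E <- exp(outer(-times, 1 / tt[act]))  # placeholder shape
  model_rss <- function(s0v, ttv, idx) {
    Efit <- exp(outer(-times, rep(1, length(idx))) * rep(1 / ttv, each = nt))
    R <- Y[, idx, drop = FALSE] - Efit * rep(s0v, each = nt)
    colSums(R^2)
  }
  idx_all <- which(valid)
  if (length(idx_all))
    rss[idx_all] <- model_rss(s0[idx_all], tt[idx_all], idx_all)
  converged <- !valid  # invalid voxels are "done" (flagged invalid later)
  for (it in seq_len(max_iter)) {
    idx <- which(!converged)
    if (!length(idx)) break
    s0i <- s0[idx]; tti <- tt[idx]
    Ei <- exp(outer(-times, 1 / tti))
    R <- Y[, idx, drop = FALSE] - Ei * rep(s0i, each = nt)
    # Jacobian columns: d(model)/dS0 = E; d(model)/dT = S0 * E * t / T^2
    J2 <- Ei * outer(times, 1 / tti^2) * rep(s0i, each = nt)
    a11 <- colSums(Ei * Ei)
    a12 <- colSums(Ei * J2)
    a22 <- colSums(J2 * J2)
    g1 <- colSums(Ei * R)
    g2 <- colSums(J2 * R)
    lam <- lambda[idx]
    d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    ds0 <- (d22 * g1 - a12 * g2) / det
    dtt <- (d11 * g2 - a12 * g1) / det
    s0n <- pmax(s0i + ds0, 1e-9)
    ttn <- pmin(pmax(tti + dtt, 1e-3), t_max)
    rssn <- model_rss(s0n, ttn, idx)
    better <- rssn < rss[idx]
    upd <- idx[better]
    if (length(upd)) {
      improve <- (rss[upd] - rssn[better]) / pmax(rss[upd], 1e-300)
      s0[upd] <- s0n[better]; tt[upd] <- ttn[better]
      rss[upd] <- rssn[better]
      lambda[upd] <- pmax(lambda[upd] / 4, 1e-10)
      converged[upd[improve < tol]] <- TRUE
    }
    worse <- idx[!better]
    lambda[worse] <- lambda[worse] * 6
    converged[worse[lambda[worse] > 1e10]] <- TRUE
  }
  fitted_ok <- valid & converged
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  list(s0 = s0, t = tt, rss = rss, r2 = r2,
       valid = valid & is.finite(tt) & tt > 0 & fitted_ok)
}

#' Fit a mono-exponential decay to one signal
#'
#' Least-squares fit of `values = S0 * exp(-times / T)` by damped Gauss-Newton
#' (Levenberg-Marquardt) iteration, seeded by log-linear regression on the
#' positive samples. Negative or zero samples (possible under noise) are
#' excluded from the seed but retained in the nonlinear objective. T is
#' constrained to `(0, t_max]`.
#'
#' @param times preparation times (ms), strictly increasing from 0
#' @param values signal intensities, same length as `times` (>= 3)
#' @param init optional c(S0, T) starting point
#' @param t_max upper bound on T (ms); default 200, a physiologic ceiling for
#'   cartilage
#' @return list with `s0`, `t` (ms), `rss`, `r2`, and `valid` (FALSE when the
#'   fit failed to converge or the signal carries no information)
#' @export
fit_monoexp <- function(times, values, init = NULL, t_max = 200) {
  stopifnot(length(times) == length(values), length(times) >= 3)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing from 0")
  Y <- matrix(values, ncol = 1)
  f <- monoexp_fit_matrix(times, Y, t_max = t_max, init = init)
  if (!is.null(init)) {
    # a poor user-supplied start must not trap the fit: also run from the
    # log-linear seed and keep whichever solution fits better
    f2 <- monoexp_fit_matrix(times, Y, t_max = t_max)
    if (f2$valid[1] && (!f$valid[1] || f2$rss[1] < f$rss[1])) f <- f2
  }
  list(s0 = f$s0[1], t = f$t[1], rss = f$rss[1], r2 = f$r2[1],
       valid = f$valid[1])
}

#' Compute a T1rho or T2 map from a mapped series
#'
#' Fits every voxel inside `mask` independently ("voxel-by-voxel"); the t = 0
#' volume is shared between the T1rho and T2 subsets of the series and is used
#' by both fits.
#'
#' @param series a `mapped_series` (co-registered volumes with a time index)
#' @param parameter `"T1rho"` or `"T2"`
#' @param mask logical array of voxels to fit
#' @param t_max upper bound on T (ms)
#' @return a `relaxation_map`: list of volumes `t`, `s0`, `r2`, `valid`, plus
#'   `parameter` and `space` tags
#' @export
compute_map <- function(series, parameter = c("T1rho", "T2"), mask,
                        t_max = 200) {
  parameter <- match.arg(parameter)
  rows <- series$index[series$index$parameter == parameter, ]
  rows <- rows[order(rows$time_ms), ]
  vols <- series$volumes[rows$volume]
  d <- dim(vols[[1]]); sp <- spacing(vols[[1]])
  for (v in vols) stop_if_grid_mismatch(vols[[1]], v, "series volumes")
  if (!identical(dim(mask)[1:3], d))
    stop("mask does not match the series grid")
  widx <- which(as.logical(mask))
  tvol <- array(0, d); s0vol <- array(0, d); r2vol <- array(0, d)
  validvol <- array(FALSE, d)
  if (length(widx)) {
    Y <- vapply(vols, function(v) as.numeric(v)[widx], numeric(length(widx)))
    f <- monoexp_fit_matrix(rows$time_ms, t(Y), t_max = t_max)
    tvol[widx] <- ifelse(f$valid, f$t, 0)
    s0vol[widx] <- ifelse(f$valid, f$s0, 0)
    r2vol[widx] <- ifelse(is.finite(f$r2), f$r2, 0)
    validvol[widx] <- f$valid
  }
  structure(list(t = as_volume(tvol, d, sp), s0 = as_volume(s0vol, d, sp),
                 r2 = as_volume(r2vol, d, sp), valid = validvol,
                 parameter = parameter, space = "native",
                 times_ms = rows$time_ms),
            class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("<relaxation_map> %s (%s space): %d valid voxels, mean %.2f ms\n",
              x$parameter, x$space, n,
              if (n) mean(x$t[x$valid]) else NA))
  invisible(x)
}

#' Quality-filter a relaxation map
#'
#' Intersects the valid mask with `{r2 >= r2_min and t within t_bounds}`.
#'
#' @param map a `relaxation_map`
#' @param r2_min minimum goodness of fit in `[0, 1]`
#' @param t_bounds length-2 admissible range for T (ms)
#' @return the filtered `relaxation_map`
#' @export
quality_filter <- function(map, r2_min = 0, t_bounds = c(0, Inf)) {
  stopifnot(r2_min >= 0, r2_min <= 1, length(t_bounds) == 2)
  keep <- map$valid & (map$r2 >= r2_min) &
    (map$t > t_bounds[1]) & (map$t <= t_bounds[2])
  map$valid <- array(keep, dim(map$t))
  map
}
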