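# Voxel-based relaxometry statistics in atlas space: stacking of registered
# maps, percentage-difference maps, voxel-wise covariate-adjusted ANCOVA, and
# per-compartment roll-ups.

#' Stack atlas-space relaxation maps into a voxel x knee matrix
#'
#' Knees with any compartment at Noyes >= 1 are expected to have been
#' excluded upstream (see [build_exclusion_list()]); the stack simply aligns
#' maps with metadata rows and fails loudly on any grid or id mismatch.
#'
#' @param maps named list of `relaxation_map`s in atlas space (names = knee
#'   ids)
#' @param meta subject table containing exactly the stacked knees (matched by
#'   `knee_id`)
#' @param mask logical array restricting the analysis (e.g. atlas cartilage);
#'   default: voxels valid in at least one map
#' @return object of class `vbr_stack`: `values` (voxels x knees matrix, NA
#'   where invalid), `voxel_index`, `dim`, `spacing`, `meta`
#' @export
stack_atlas_maps <- function(maps, meta, mask = NULL) {
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("maps must be a named list (knee ids)")
  missing_meta <- setdiff(names(maps), meta$knee_id)
  if (length(missing_meta))
    stop("no metadata for knees: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$knee_id, names(maps))
  if (length(extra_meta))
    stop("metadata rows without maps: ", paste(extra_meta, collapse = ", "))
  ref <- maps[[1]]
  for (id in names(maps)) {
    m <- maps[[id]]
    if (!same_grid(m$t, ref$t))
      stop("map for knee ", id, " is on a different grid")
    if (!identical(m$space, "atlas"))
      stop("map for knee ", id, " is not in atlas space")
  }
  d <- dim(ref$t); sp <- spacing(ref$t)
  if (is.null(mask)) {
    mask <- Reduce(`|`, lapply(maps, function(m) as.logical(m$valid)))
  }
  voxel_index <- which(array(mask, d))
  meta <- meta[match(names(maps), meta$knee_id), , drop = FALSE]
  vals <- vapply(maps, function(m) {
    tv <- as.numeric(m$t)[voxel_index]
    tv[!as.logical(m$valid)[voxel_index]] <- NA_real_
    tv
  }, numeric(length(voxel_index)))
  structure(list(values = vals, voxel_index = voxel_index, dim = d,
                 spacing = sp, meta = meta),
            class = "vbr_stack")
}

#' @export
print.vbr_stack <- function(x, ...) {
  cat(sprintf("<vbr_stack> %d voxels x %d knees (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(table(x$meta$group), collapse = "/")))
  invisible(x)
}

#' Per-voxel group mean maps
#'
#' @param stack a `vbr_stack`
#' @param min_n minimum valid knees per group for a voxel to be defined
#' @return list with `mean_a`, `mean_b`, `n_a`, `n_b` (vectors over the
#'   stack's voxels; NA where undefined)
#' @export
group_mean_map <- function(stack, min_n = 3) {
  ga <- stack$meta$group == "A"
  A <- stack$values[, ga, drop = FALSE]
  B <- stack$values[, !ga, drop = FALSE]
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  und <- na < min_n | nb < min_n
  ma[und] <- NA; mb[und] <- NA
  list(mean_a = ma, mean_b = mb, n_a = na, n_b = nb)
}

#' Percentage-difference map
#'
#' `100 * (mean_a - mean_b) / ((mean_a + mean_b) / 2)` per voxel. Voxels with
#' a nonpositive denominator are undefined (NA) and counted in the
#' `n_undefined` attribute.
#'
#' @param mean_a,mean_b per-voxel group means (vectors or arrays of equal
#'   shape)
#' @return percentage differences, same shape, with attribute `n_undefined`
#' @export
percent_difference_map <- function(mean_a, mean_b) {
  stopifnot(length(mean_a) == length(mean_b))
  denom <- (mean_a + mean_b) / 2
  out <- 100 * (mean_a - mean_b) / denom
  bad <- !is.na(denom) & denom <= 0
  out[bad] <- NA_real_
  attr(out, "n_undefined") <- sum(bad)
  out
}

# Vectorized OLS F-test of the group term for a block of voxels sharing one
# design (rows = knees present, columns = voxels).
ols_group_f <- function(X, Y) {
  gi <- which(colnames(X) == "groupA")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) return(NULL)  # no residual degrees of freedom
  qrX <- qr(X)
  if (qrX$rank < p) return(NULL)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  X0 <- X[, -gi, drop = FALSE]
  res0 <- Y - X0 %*% qr.coef(qr(X0), Y)
  rss0 <- colSums(res0^2)
  Fstat <- (rss0 - rss) / (rss / (n - p))
  pval <- pf(Fstat, 1, n - p, lower.tail = FALSE)
  list(F = Fstat, p = pval, df2 = n - p)
}

#' Voxel-wise covariate-adjusted group comparison (VBR statistics)
#'
#' Fits the same ANCOVA model as [ancova_group_effect()] independently at each
#' voxel of the stack; voxels are grouped by their pattern of valid knees so
#' the linear algebra is vectorized. No multiple-comparison correction is
#' applied by default; `correction = "fdr"` applies Benjamini-Hochberg.
#'
#' @param stack a `vbr_stack`
#' @param alpha significance threshold
#' @param covariates adjustment factors
#' @param min_n minimum valid knees per group per voxel
#' @param correction `"none"` (default) or `"fdr"`
#' @return object of class `stat_map`: `p`, `effect_pct` (vectors over stack
#'   voxels, NA where undefined), `alpha`, `n_undefined`, plus the stack
#'   geometry for expansion back to a volume
#' @export
voxelwise_ancova <- function(stack, alpha = 0.05,
                             covariates = c("gender", "bmi", "site"),
                             min_n = 3, correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  V <- nrow(stack$values)
  pvec <- rep(NA_real_, V); fvec <- rep(NA_real_, V)
  gm <- group_mean_map(stack, min_n = min_n)
  effect <- percent_difference_map(gm$mean_a, gm$mean_b)
  present <- !is.na(stack$values)
  ga <- stack$meta$group == "A"
  enough <- rowSums(present[, ga, drop = FALSE]) >= min_n &
    rowSums(present[, !ga, drop = FALSE]) >= min_n
  pat <- apply(present, 1, function(r) paste(which(r), collapse = ","))
  n_rankdef <- 0L
  for (pt in unique(pat[enough])) {
    vox <- which(pat == pt & enough)
    knees <- as.integer(strsplit(pt, ",")[[1]])
    X <- tryCatch(ancova_design(stack$meta[knees, , drop = FALSE], covariates),
                  error = function(e) NULL)
    if (is.null(X)) { n_rankdef <- n_rankdef + length(vox); next }
    Y <- t(stack$values[vox, knees, drop = FALSE])
    r <- ols_group_f(X, Y)
    if (is.null(r)) { n_rankdef <- n_rankdef + length(vox); next }
    pvec[vox] <- r$p; fvec[vox] <- r$F
  }
  if (correction == "fdr") {
    def <- !is.na(pvec)
    pvec[def] <- stats::p.adjust(pvec[def], method = "BH")
  }
  structure(list(p = pvec, F = fvec, effect_pct = as.numeric(effect),
                 alpha = alpha, n_undefined = sum(!enough) + n_rankdef,
                 correction = correction,
                 voxel_index = stack$voxel_index, dim = stack$dim,
                 spacing = stack$spacing),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  def <- !is.na(x$p)
  cat(sprintf("<stat_map> %d defined voxels, %.1f%% significant at alpha %.3g (%s)\n",
              sum(def), 100 * mean(x$p[def] < x$alpha), x$alpha, x$correction))
  invisible(x)
}

#' Expand a stat-map vector to a full volume
#' @param stat a `stat_map`
#' @param what one of "p", "effect_pct", "F"
#' @return volume with NA outside the analysis mask
#' @export
stat_map_volume <- function(stat, what = c("p", "effect_pct", "F")) {
  what <- match.arg(what)
  v <- array(NA_real_, stat$dim)
  v[stat$voxel_index] <- stat[[what]]
  as_volume(v, stat$dim, stat$spacing)
}

#' Per-compartment roll-up of voxel-wise statistics
#'
#' For each compartment: the fraction of defined voxels significant at
#' `alpha`, the average percentage difference over all defined voxels
#' (primary), and the average over significant voxels only (secondary).
#'
#' @param stat a `stat_map`
#' @param atlas a `compartment_atlas` on the same grid
#' @return data.frame compartment, n_defined, pct_significant,
#'   avg_pct_difference, avg_pct_difference_significant
#' @export
compartment_rollup <- function(stat, atlas) {
  if (!identical(dim(atlas$labels)[1:3], stat$dim))
    stop("atlas and stat map are on different grids")
  lv <- as.integer(atlas$labels)[stat$voxel_index]
  out <- list()
  for (comp in CARTILAGE_COMPARTMENTS) {
    sel <- lv == CARTILAGE_LABELS[[comp]]
    def <- sel & !is.na(stat$p)
    sig <- def & stat$p < stat$alpha
    out[[length(out) + 1L]] <- data.frame(
      compartment = comp, n_defined = sum(def),
      pct_significant = if (sum(def)) 100 * sum(sig) / sum(def) else NA_real_,
      avg_pct_difference = if (sum(def)) mean(stat$effect_pct[def],
                                              na.rm = TRUE) else NA_real_,
      avg_pct_difference_significant =
        if (sum(sig)) mean(stat$effect_pct[sig], na.rm = TRUE) else NA_real_)
  }
  do.call(rbind, out)
}
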