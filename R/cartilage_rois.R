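# Compartmental cartilage analysis: the six-compartment atlas, deep /
# superficial layer partitioning by normalized distance-transform depth, ROI
# summary statistics, and covariate-adjusted group comparison (ANCOVA).

#' Construct a compartment atlas from an integer label volume
#'
#' Labels: femur = 1, tibia = 2, patella = 3 (bone); LFC = 11, MFC = 12,
#' TRO = 13, PAT = 14, LT = 15, MT = 16 (cartilage); 0 = background.
#'
#' @param labels integer label volume (array with spacing)
#' @return object of class `compartment_atlas`
#' @export
compartment_atlas <- function(labels) {
  lv <- as.integer(labels)
  known <- c(0L, unname(BONE_LABELS), unname(CARTILAGE_LABELS))
  if (!all(lv %in% known))
    stop("unknown label codes: ", paste(setdiff(unique(lv), known),
                                        collapse = ", "))
  vol <- as_volume(lv, dim(labels),
                   if (is.null(attr(labels, "spacing"))) c(1, 1, 1)
                   else attr(labels, "spacing"))
  attr(vol, "labels") <- TRUE
  structure(list(labels = vol, spacing = spacing(vol)),
            class = "compartment_atlas")
}

#' @export
print.compartment_atlas <- function(x, ...) {
  lv <- as.integer(x$labels)
  counts <- vapply(CARTILAGE_LABELS, function(code) sum(lv == code), 0L)
  cat("<compartment_atlas> cartilage voxels:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}

#' Mask of one cartilage compartment
#' @param atlas a `compartment_atlas`
#' @param compartment one of LFC, MFC, TRO, PAT, LT, MT
#' @return logical array
#' @export
compartment_mask <- function(atlas, compartment) {
  array(as.integer(atlas$labels) == CARTILAGE_LABELS[[compartment]],
        dim(atlas$labels))
}

#' Mask of all bone voxels
#' @param atlas a `compartment_atlas`
#' @return logical array
#' @export
bone_mask <- function(atlas) {
  array(as.integer(atlas$labels) %in% BONE_LABELS, dim(atlas$labels))
}

#' Split a cartilage compartment into deep and superficial halves
#'
#' For each cartilage voxel the normalized depth is
#' `d = D_bone / (D_bone + D_surface)`, with both distances taken from
#' anisotropy-aware Euclidean distance transforms in physical mm: `D_bone` to
#' the subchondral bone interface and `D_surface` to the non-bone exterior.
#' Deep = `d <= 0.5` (ties go to the deep layer), superficial = `d > 0.5`.
#'
#' @param compartment_mask logical array for one compartment
#' @param bone logical array of bone voxels
#' @param spacing voxel spacing (mm)
#' @return list of class `layer_partition`: `deep`, `superficial` (logical
#'   arrays), `depth` (normalized depth, NA outside the compartment)
#' @export
split_layers <- function(compartment_mask, bone, spacing = c(1, 1, 1)) {
  compartment_mask <- array(as.logical(compartment_mask), dim(compartment_mask))
  bone <- array(as.logical(bone), dim(bone))
  stopifnot(identical(dim(compartment_mask), dim(bone)))
  d <- dim(compartment_mask)
  db <- sqrt(edt_sq_cpp(bone, d, spacing))
  if (min(db[compartment_mask]) > 1.5 * max(spacing))
    stop("compartment is not adjacent to the bone mask")
  exterior <- !compartment_mask & !bone
  ds <- sqrt(edt_sq_cpp(exterior, d, spacing))
  depth <- array(NA_real_, d)
  idx <- which(compartment_mask)
  depth[idx] <- db[idx] / (db[idx] + ds[idx])
  deep <- array(FALSE, d); superficial <- array(FALSE, d)
  deep[idx] <- depth[idx] <= 0.5
  superficial[idx] <- depth[idx] > 0.5
  structure(list(deep = deep, superficial = superficial, depth = depth),
            class = "layer_partition")
}

#' Layer partitions for every compartment of an atlas
#' @param atlas a `compartment_atlas`
#' @return named list of `layer_partition`s
#' @export
layer_partition_all <- function(atlas) {
  bm <- bone_mask(atlas)
  sp <- atlas$spacing
  setNames(lapply(CARTILAGE_COMPARTMENTS, function(comp)
    split_layers(compartment_mask(atlas, comp), bm, sp)),
    CARTILAGE_COMPARTMENTS)
}

#' Compartmental (and per-layer) summary of a relaxation map
#'
#' Means and SDs are computed over valid voxels only; compartments with no
#' valid voxel are retained with `n_voxels = 0` and flagged.
#'
#' @param map a `relaxation_map`
#' @param atlas a `compartment_atlas` on the same grid
#' @param partition optional list of `layer_partition`s (as from
#'   [layer_partition_all()]); when given, deep/superficial rows are added
#' @return data.frame with columns compartment, layer, mean_ms, sd_ms,
#'   n_voxels, flagged
#' @export
roi_summary <- function(map, atlas, partition = NULL) {
  stop_if_grid_mismatch(map$t, atlas$labels, "map and atlas")
  lv <- as.integer(atlas$labels)
  valid <- as.logical(map$valid)
  tv <- as.numeric(map$t)
  one_row <- function(comp, layer, sel) {
    sel <- sel & valid
    n <- sum(sel)
    data.frame(compartment = comp, layer = layer,
               mean_ms = if (n) mean(tv[sel]) else NA_real_,
               sd_ms = if (n > 1) sd(tv[sel]) else ifelse(n == 1, 0, NA_real_),
               n_voxels = n, flagged = n == 0)
  }
  out <- list()
  for (comp in CARTILAGE_COMPARTMENTS) {
    inc <- lv == CARTILAGE_LABELS[[comp]]
    out[[length(out) + 1L]] <- one_row(comp, "all", inc)
    if (!is.null(partition)) {
      p <- partition[[comp]]
      out[[length(out) + 1L]] <- one_row(comp, "deep", as.logical(p$deep))
      out[[length(out) + 1L]] <- one_row(comp, "superficial",
                                         as.logical(p$superficial))
    }
  }
  do.call(rbind, out)
}

# design matrix for the adjusted model; stops with the aliased terms named
ancova_design <- function(meta, covariates) {
  df <- data.frame(group = factor(meta$group, levels = c("B", "A")))
  if ("gender" %in% covariates) df$gender <- factor(meta$gender)
  if ("bmi" %in% covariates) df$bmi <- as.numeric(meta$bmi)
  if ("site" %in% covariates) df$site <- factor(meta$site)
  X <- model.matrix(~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient ANCOVA design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Covariate-adjusted group comparison of per-knee values (ANCOVA)
#'
#' Ordinary least squares of `value ~ group + gender + BMI + site` (site as
#' unordered categorical dummies). The group effect is tested with a 1-df
#' F test, which equals the square of the group t statistic. The percent
#' difference is computed from raw group means as
#' `100 * (mean_A - mean_B) / ((mean_A + mean_B) / 2)`; the same formula on
#' covariate-adjusted means is also reported.
#'
#' @param values numeric per-knee outcome, aligned with rows of `meta`
#' @param meta subject table with columns group, gender, bmi, site
#' @param covariates subset of c("gender", "bmi", "site"); empty for an
#'   unadjusted comparison (then F = t^2 of the pooled two-sample t test)
#' @return object of class `ancova_result`
#' @export
ancova_group_effect <- function(values, meta,
                                covariates = c("gender", "bmi", "site")) {
  stopifnot(length(values) == nrow(meta))
  ok <- is.finite(values)
  values <- values[ok]; meta <- meta[ok, , drop = FALSE]
  na <- sum(meta$group == "A"); nb <- sum(meta$group == "B")
  if (na < 2 || nb < 2) stop("need at least 2 knees per group")
  X <- ancova_design(meta, covariates)
  fit <- lm.fit(X, values)
  n <- length(values); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  gi <- which(colnames(X) == "groupA")
  beta <- fit$coefficients[gi]
  se <- sqrt(sigma2 * XtXinv[gi, gi])
  tstat <- beta / se
  Fstat <- tstat^2
  pval <- pf(Fstat, 1, n - p, lower.tail = FALSE)
  ma <- mean(values[meta$group == "A"]); mb <- mean(values[meta$group == "B"])
  # adjusted means: evaluate the fit at the overall covariate mean
  xbar <- colMeans(X)
  xa <- xbar; xa[gi] <- 1
  xb <- xbar; xb[gi] <- 0
  ma_adj <- sum(xa * fit$coefficients)
  mb_adj <- sum(xb * fit$coefficients)
  structure(list(
    adjusted_group_difference = unname(beta),
    percent_difference = 100 * (ma - mb) / ((ma + mb) / 2),
    percent_difference_adjusted = 100 * (ma_adj - mb_adj) /
      ((ma_adj + mb_adj) / 2),
    statistic = unname(Fstat), t_statistic = unname(tstat),
    p_value = unname(pval),
    df = c(1, n - p),
    n_per_group = c(A = na, B = nb),
    group_means = c(A = ma, B = mb),
    covariates_used = covariates), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(paste0("<ancova_result> adj. diff %.3f ms (%.2f%%), ",
                     "F(1, %d) = %.3f, p = %.4g; n = %d/%d\n"),
              x$adjusted_group_difference, x$percent_difference, x$df[2],
              x$statistic, x$p_value, x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' Per-knee compartment means for a cohort of relaxation maps
#'
#' @param maps named list of `relaxation_map`s (names = knee ids), all in
#'   atlas space
#' @param atlas the `compartment_atlas`
#' @param partition optional layer partitions
#' @return data.frame knee_id x (compartment, layer) long table of means
#' @export
cohort_roi_table <- function(maps, atlas, partition = NULL) {
  out <- list()
  for (id in names(maps)) {
    s <- roi_summary(maps[[id]], atlas, partition)
    s$knee_id <- id
    s$parameter <- maps[[id]]$parameter
    out[[length(out) + 1L]] <- s
  }
  do.call(rbind, out)
}
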