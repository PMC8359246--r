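# End-to-end orchestration of the study replica on a (synthetic) cohort:
# morphological accounting and exclusion -> within-knee rigid echo alignment
# -> nonrigid morph to atlas -> atlas-space map fitting -> ROI + layer ANCOVA
# -> voxel-wise statistics and roll-ups -> bone shape modeling -> report.
# Stages are cached on disk keyed by a hash of the configuration.

#' Default pipeline configuration
#'
#' @param spec a [cohort_spec()]; defaults to a reduced cohort sized for
#'   desk-scale runs
#' @param out_dir output directory (created); NULL disables caching and file
#'   output
#' @param seed master seed
#' @param ... overrides: `alpha`, `n_modes`, `do_rigid`, `do_nonrigid`,
#'   `ssm_exclude_noyes` (include all knees in shape modeling by default),
#'   `covariates`, `min_n`, `resume`
#' @return a `run_config` list
#' @export
run_config <- function(spec = NULL, out_dir = NULL, seed = 1L, ...) {
  if (is.null(spec))
    spec <- cohort_spec(n_group_a = 6, n_group_b = 5, dim = 48,
                        deform_amplitude_mm = 2, bilateral_prob = 0,
                        seed = seed)
  cfg <- modifyList(list(spec = spec, out_dir = out_dir, seed = seed,
                         alpha = 0.05, n_modes = 10,
                         do_rigid = TRUE, do_nonrigid = TRUE,
                         ssm_exclude_noyes = FALSE,
                         covariates = c("gender", "bmi", "site"),
                         min_n = 3, resume = TRUE,
                         nonrigid = list()),
                    list(...))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg, stage) {
  key <- cfg[setdiff(names(cfg), c("out_dir", "resume"))]
  txt <- paste(deparse(key, control = "all"), collapse = "")
  codes <- utf8ToInt(txt)
  h <- sum((codes * seq_along(codes)) %% 2147483647) %% 2147483647
  sprintf("%s-%08x", stage, h)
}

stage_cached <- function(cfg, stage, compute) {
  if (is.null(cfg$out_dir) || !isTRUE(cfg$resume)) return(compute())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, paste0(config_hash(cfg, stage), ".rds"))
  if (file.exists(path)) return(readRDS(path))
  res <- compute()
  saveRDS(res, path)
  res
}

#' Validate an input manifest
#'
#' Checks grids, label vocabularies, metadata completeness and acquisition
#' timing conventions. Reports problems; never mutates inputs.
#'
#' @param manifest list with elements `meta` (subject table), `tsl_ms`,
#'   `te_ms`, and optionally `volumes` (named list per knee), `labels`
#' @return character vector of problems (empty when the manifest is clean)
#' @export
validate_inputs <- function(manifest) {
  problems <- character(0)
  meta <- manifest$meta
  if (is.null(meta)) {
    problems <- c(problems, "manifest has no subject table (meta)")
  } else {
    need <- c("knee_id", "group", "gender", "bmi", "site",
              paste0("noyes_", CARTILAGE_COMPARTMENTS))
    miss <- setdiff(need, names(meta))
    if (length(miss))
      problems <- c(problems, paste("subject table missing columns:",
                                    paste(miss, collapse = ", ")))
    for (col in intersect(need, names(meta))) {
      bad <- which(is.na(meta[[col]]))
      for (b in bad)
        problems <- c(problems, sprintf("knee %s: missing %s",
                                        meta$knee_id[b], col))
    }
    if (!is.null(meta$knee_id) && anyDuplicated(meta$knee_id))
      problems <- c(problems, "duplicate knee_id values")
    gr <- unlist(meta[, grep("^noyes_", names(meta)), drop = FALSE])
    if (any(!is.na(gr) & !(gr %in% 0:2)))
      problems <- c(problems, "Noyes grades outside {0, 1, 2}")
  }
  for (tm in c("tsl_ms", "te_ms")) {
    t <- manifest[[tm]]
    if (is.null(t)) {
      problems <- c(problems, paste("manifest missing", tm))
    } else {
      if (t[1] != 0)
        problems <- c(problems, sprintf(
          "%s does not start at 0 (acquisition shares the t = 0 image)", tm))
      if (any(diff(t) <= 0))
        problems <- c(problems, paste(tm, "not strictly increasing"))
    }
  }
  if (!is.null(manifest$volumes)) {
    dims <- lapply(manifest$volumes, function(v) dim(v)[1:3])
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
      problems <- c(problems, "volumes are on different grids")
  }
  problems
}

#' Run the full study replica
#'
#' Executes synthesis, morphological accounting with Noyes >= 1 exclusion for
#' the compositional stages, within-knee rigid echo alignment, nonrigid
#' registration to the atlas (a designated undeformed subject), atlas-space
#' T1rho/T2 map fitting, compartmental and layer ANCOVA, voxel-wise
#' statistics with roll-ups, bone shape modeling with per-mode tests, phantom
#' QC, and report assembly. Shape and morphological stages use all knees; the
#' exclusion applies to compositional stages only.
#'
#' @param config a [run_config()]
#' @return a `study_report` list
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  spec <- cfg$spec
  t0 <- Sys.time()
  meta <- stage_cached(cfg, "meta", function()
    generate_subject_table(spec, seed = cfg$seed))
  prevalence <- prevalence_table(meta)
  excluded <- build_exclusion_list(meta)
  included <- setdiff(meta$knee_id, excluded)
  # atlas = designated generator subject with zero deformation ("atlas mode")
  atlas_knee <- stage_cached(cfg, "atlas", function()
    generate_subject_knee(spec, group = "B", seed = cfg$seed + 10000L,
                          atlas_mode = TRUE))
  atlas <- atlas_knee$atlas
  cart_mask <- array(as.integer(atlas$labels) >= min(CARTILAGE_LABELS),
                     dim(atlas$labels))
  partition <- stage_cached(cfg, "layers", function()
    layer_partition_all(atlas))
  knees <- stage_cached(cfg, "knees", function() {
    out <- list()
    for (i in seq_len(nrow(meta))) {
      id <- meta$knee_id[i]
      out[[id]] <- generate_subject_knee(spec, group = meta$group[i],
                                         seed = cfg$seed + i)
    }
    out
  })
  maps <- stage_cached(cfg, "maps", function() {
    res <- list(T1rho = list(), T2 = list())
    atlas_t0 <- atlas_knee$series$volumes[[1]]
    for (id in included) {
      kn <- knees[[id]]
      series <- kn$series
      rigid <- NULL
      if (isTRUE(cfg$do_rigid)) {
        t0v <- series$volumes[[1]]
        series$volumes <- c(series$volumes[1],
                            lapply(series$volumes[-1], function(v) {
                              tr <- register_rigid(v, t0v,
                                                   levels = c(4, 2))
                              apply_transform(v, tr, "linear")
                            }))
      }
      if (isTRUE(cfg$do_nonrigid)) {
        field <- register_nonrigid(series$volumes[[1]], atlas_t0,
                                   cfg$nonrigid)
        series <- transport_series(series, field = field)
      }
      for (par in c("T1rho", "T2")) {
        m <- compute_map(series, par, cart_mask)
        m <- quality_filter(m, r2_min = 0.5, t_bounds = c(0, 200))
        m$space <- "atlas"
        res[[par]][[id]] <- m
      }
    }
    res
  })
  meta_inc <- meta[match(included, meta$knee_id), , drop = FALSE]
  roi <- list(); vbr <- list()
  for (par in c("T1rho", "T2")) {
    roi_tab <- cohort_roi_table(maps[[par]], atlas, partition)
    anc <- list()
    for (comp in CARTILAGE_COMPARTMENTS) for (lay in c("all", "deep",
                                                       "superficial")) {
      vals <- vapply(included, function(id) {
        r <- roi_tab[roi_tab$knee_id == id & roi_tab$compartment == comp &
                       roi_tab$layer == lay, ]
        if (nrow(r)) r$mean_ms[1] else NA_real_
      }, 0)
      res <- tryCatch(ancova_group_effect(vals, meta_inc, cfg$covariates),
                      error = function(e) NULL)
      if (!is.null(res))
        anc[[length(anc) + 1L]] <- data.frame(
          parameter = par, compartment = comp, layer = lay,
          percent_difference = res$percent_difference,
          F = res$statistic, p = res$p_value)
    }
    stack <- stack_atlas_maps(maps[[par]], meta_inc, mask = cart_mask)
    stat <- voxelwise_ancova(stack, alpha = cfg$alpha,
                             covariates = cfg$covariates, min_n = cfg$min_n)
    roi[[par]] <- list(summaries = roi_tab, ancova = do.call(rbind, anc))
    vbr[[par]] <- list(stat = stat, rollup = compartment_rollup(stat, atlas))
  }
  ssm <- stage_cached(cfg, "ssm", function() {
    ids <- if (isTRUE(cfg$ssm_exclude_noyes)) included else meta$knee_id
    meshes <- lapply(ids, function(id) {
      bm <- array(as.integer(knees[[id]]$atlas$labels) ==
                    BONE_LABELS[["tibia"]], dim(atlas$labels))
      attr(bm, "spacing") <- spec$spacing_mm
      decimate_mesh(extract_surface(bm, spec$spacing_mm), 1200)
    })
    tpl <- meshes[[1]]
    pts <- lapply(meshes, function(m)
      spectral_correspondence(tpl, m, k = 5)$points)
    aligned <- align_pointsets(pts)
    model <- build_shape_model(aligned, n_modes = cfg$n_modes)
    tests <- tryCatch(
      mode_group_test(model, meta[match(ids, meta$knee_id), ],
                      covariates = cfg$covariates),
      error = function(e) {
        warning("per-mode group tests skipped: ", conditionMessage(e))
        data.frame(mode = integer(0), variance_pct = numeric(0),
                   F = numeric(0), p = numeric(0))
      })
    list(model = model, tests = tests, ids = ids,
         shaft_flags = flag_shaft_modes(model))
  })
  qc <- coefficient_of_variation(generate_phantom_series(
    c(40, 60, 80), n_repeats = 3, noise_sd = 5, seed = cfg$seed,
    n_scanners = 3, scanner_bias_sd = 0.05))
  report <- list(
    prevalence = prevalence,
    excluded_knees = excluded,
    roi = roi, vbr = vbr, ssm = ssm, qc = qc,
    provenance = list(seed = cfg$seed, alpha = cfg$alpha,
                      n_knees = nrow(meta), n_included = length(included),
                      covariates = cfg$covariates,
                      package_version = as.character(
                        utils::packageVersion("kneemap")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
  class(report) <- "study_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  knees: %d (%d excluded for Noyes >= 1)\n",
              x$provenance$n_knees, x$provenance$n_knees -
                x$provenance$n_included))
  cat(sprintf("  knee-level abnormality prevalence: A %.1f%%, B %.1f%%\n",
              x$prevalence$per_knee$pct_abnormal[1],
              x$prevalence$per_knee$pct_abnormal[2]))
  for (par in names(x$roi)) {
    sig <- x$roi[[par]]$ancova
    sig <- sig[sig$layer == "all" & sig$p < 0.05, ]
    cat(sprintf("  %s compartments significant (p < .05): %s\n", par,
                if (nrow(sig)) paste(sig$compartment, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$prevalence$per_compartment,
            file.path(out_dir, "prevalence_per_compartment.csv"),
            row.names = FALSE)
  write.csv(report$prevalence$per_knee,
            file.path(out_dir, "prevalence_per_knee.csv"), row.names = FALSE)
  for (par in names(report$roi)) {
    write.csv(report$roi[[par]]$ancova,
              file.path(out_dir, paste0("roi_ancova_", par, ".csv")),
              row.names = FALSE)
    write.csv(report$vbr[[par]]$rollup,
              file.path(out_dir, paste0("vbr_rollup_", par, ".csv")),
              row.names = FALSE)
  }
  write.csv(report$ssm$tests, file.path(out_dir, "ssm_mode_tests.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
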