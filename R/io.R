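# Standard-format I/O: NIfTI volumes with JSON sidecars for provenance,
# rigid transforms as JSON, deformation fields as 4-D NIfTI displacement
# volumes (mm, atlas grid).

#' Write a relaxation map as NIfTI volumes plus a JSON sidecar
#'
#' Writes `<prefix>_t.nii.gz`, `<prefix>_s0.nii.gz`, `<prefix>_r2.nii.gz`,
#' `<prefix>_valid.nii.gz` and `<prefix>.json` (parameter, times, space,
#' software version).
#'
#' @param map a `relaxation_map`
#' @param prefix output path prefix
#' @return the sidecar path, invisibly
#' @export
write_relaxation_map <- function(map, prefix) {
  write_volume(map$t, paste0(prefix, "_t.nii.gz"))
  write_volume(map$s0, paste0(prefix, "_s0.nii.gz"))
  write_volume(map$r2, paste0(prefix, "_r2.nii.gz"))
  write_volume(as_volume(as.numeric(map$valid), dim(map$t), spacing(map$t)),
               paste0(prefix, "_valid.nii.gz"))
  side <- list(parameter = map$parameter, space = map$space,
               times_ms = map$times_ms,
               software = paste0("kneemap ",
                                 as.character(utils::packageVersion("kneemap"))))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a relaxation map written by [write_relaxation_map()]
#' @param prefix path prefix used when writing
#' @return a `relaxation_map`
#' @export
read_relaxation_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  t <- read_volume(paste0(prefix, "_t.nii.gz"))
  structure(list(t = t,
                 s0 = read_volume(paste0(prefix, "_s0.nii.gz")),
                 r2 = read_volume(paste0(prefix, "_r2.nii.gz")),
                 valid = array(as.numeric(read_volume(
                   paste0(prefix, "_valid.nii.gz"))) > 0.5, dim(t)),
                 parameter = side$parameter, space = side$space,
                 times_ms = side$times_ms),
            class = "relaxation_map")
}

#' Write / read a rigid transform as JSON
#'
#' The convention tag (intrinsic ZYX rotation about the volume centre) is
#' stored with the parameters.
#'
#' @param transform a `rigid_transform`
#' @param path JSON path
#' @return the path / a `rigid_transform`
#' @export
write_rigid_transform <- function(transform, path) {
  jsonlite::write_json(list(angles_rad = transform$angles,
                            translation_mm = transform$translation,
                            convention = transform$convention,
                            warning_flag = transform$warning_flag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_transform
#' @export
read_rigid_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angles_rad, x$translation_mm, isTRUE(x$warning_flag))
}

#' Write / read a deformation field as a 4-D NIfTI displacement volume (mm)
#' @param field a `deformation_field`
#' @param path NIfTI path
#' @return the path / a `deformation_field`
#' @export
write_deformation_field <- function(field, path) {
  img <- RNifti::asNifti(field$displacement)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_deformation_field
#' @export
read_deformation_field <- function(path) {
  img <- RNifti::readNifti(path)
  deformation_field(as.array(img), RNifti::pixdim(img)[1:3])
}

#' Write a synthetic knee to disk in standard formats
#'
#' One NIfTI per TSL/TE volume (deterministic names from `knee_id`), the
#' label volume, ground-truth maps, and a JSON echo of the series index.
#'
#' @param knee result of [generate_subject_knee()]
#' @param dir output directory
#' @param knee_id identifier used in file names
#' @return the directory, invisibly
#' @export
write_knee <- function(knee, dir, knee_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- knee$series$index
  files <- character(0)
  for (i in seq_len(nrow(idx))) {
    f <- sprintf("%s_%s_%04.1fms.nii.gz", knee_id, tolower(idx$parameter[i]),
                 idx$time_ms[i])
    write_volume(knee$series$volumes[[idx$volume[i]]], file.path(dir, f))
    files <- c(files, f)
  }
  write_volume(knee$atlas$labels, file.path(dir, paste0(knee_id,
                                                        "_labels.nii.gz")))
  write_volume(knee$truth$t1rho, file.path(dir, paste0(knee_id,
                                                       "_gt_t1rho.nii.gz")))
  write_volume(knee$truth$t2, file.path(dir, paste0(knee_id,
                                                    "_gt_t2.nii.gz")))
  jsonlite::write_json(cbind(idx, file = files),
                       file.path(dir, paste0(knee_id, "_series.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
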