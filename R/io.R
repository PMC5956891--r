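#' Write a patient case to a directory of NIfTI volumes
#'
#' Each channel becomes `<name>.nii.gz`; the gland and truth masks are
#' written as uint8 label volumes; a JSON sidecar records patient id,
#' spacing and channel names.
#'
#' @param case a `patient_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$voxel_spacing
  for (nm in names(case$channels)) {
    img <- RNifti::asNifti(case$channels[[nm]], pixdim = sp)
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  for (nm in c("gland_mask", "truth_mask")) {
    img <- RNifti::asNifti(array(as.integer(case[[nm]]), dim(case[[nm]])),
                           pixdim = sp, datatype = "uint8")
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  meta <- list(patient_id = case$patient_id, voxel_spacing = sp,
               channels = names(case$channels))
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a patient case from a directory written by [write_patient_case]
#'
#' @param dir directory containing the NIfTI channels and `case.json`.
#' @return a `patient_case`.
#' @export
read_patient_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(nm)
    as.array(RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))))
  names(channels) <- meta$channels
  gl <- as.array(RNifti::readNifti(file.path(dir, "gland_mask.nii.gz"))) > 0
  tr <- as.array(RNifti::readNifti(file.path(dir, "truth_mask.nii.gz"))) > 0
  structure(list(channels = channels, gland_mask = gl, truth_mask = tr,
                 patient_id = meta$patient_id,
                 voxel_spacing = meta$voxel_spacing),
            class = "patient_case")
}

#' Region table of a detection result
#'
#' Flattens a stage's candidate regions into a data frame (one row per
#' region: id, slice, area, centroid, label, score) suitable for CSV
#' export.
#'
#' @param result a `detection_result`.
#' @return data.frame.
#' @export
region_table <- function(result) {
  if (length(result$regions) == 0)
    return(data.frame(region_id = integer(0), slice = integer(0),
                      area = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), label = logical(0),
                      score = numeric(0)))
  data.frame(
    region_id = vapply(result$regions, `[[`, 1L, "region_id"),
    slice = vapply(result$regions, `[[`, 1L, "slice_index"),
    area = vapply(result$regions, function(r) as.integer(r$area), 1L),
    centroid_row = vapply(result$regions, function(r) r$centroid[1], 1),
    centroid_col = vapply(result$regions, function(r) r$centroid[2], 1),
    label = result$labels,
    score = result$scores)
}
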