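#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving data, dimensions and voxel size.
#' 4D dynamic images, 3D parameter maps and integer label maps all round
#' trip.
#'
#' @param x numeric 3D or 4D array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size in mm, length 3.
#' @return `read_volume` returns a list with `data` (array) and `voxel_mm`;
#'   `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(x, path, voxel_mm) {
  stopifnot(length(dim(x)) %in% c(3L, 4L), length(voxel_mm) == 3)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(voxel_mm, if (length(dim(x)) == 4L) 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("NIfTI file lacks valid voxel-size metadata")
  list(data = array(as.numeric(img), dim(img)), voxel_mm = vox)
}

#' Load a study configuration
#'
#' Reads a YAML configuration describing one analysis: paths to the blood
#' table and frame schedule (optionally a 4D image and ROI labels),
#' estimator settings, noise calibration and seed.  Referenced files must
#' exist.  Every setting has a default matching the standard leucine
#' protocol.
#'
#' @param path YAML file path.
#' @return A list of validated settings (class `study_config`).
#' @export
study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    blood_table = NULL, schedule = NULL, image = NULL, labels = NULL,
    time_unit = "s", cp_unlabeled = 120, vd = 0.41,
    grid_size = 100, grid_range = c(0.0037, 1.33), band = c(0.02, 0.3),
    noise_level = "voxel", delay_range_s = c(0, 20), seed = 1
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("blood_table", "schedule", "image", "labels")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config references a missing file: ", cfg[[key]])
  }
  if (!cfg$time_unit %in% c("s", "min"))
    stop("'time_unit' must be \"s\" or \"min\"")
  if (!cfg$noise_level %in% c("voxel", "roi"))
    stop("'noise_level' must be \"voxel\" or \"roi\"")
  structure(cfg, class = "study_config")
}
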