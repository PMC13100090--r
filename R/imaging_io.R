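#' Dynamic 4D series container
#'
#' Holds a 4D dynamic contrast-enhanced acquisition: voxel array indexed
#' (x, y, z, frame), the voxel size in mm, and the acquisition time of each
#' frame in seconds. Frame times are supplied explicitly (sidecar or
#' argument) rather than inferred from the NIfTI TR, because dynamic renal
#' exams are commonly acquired in segments with gaps; non-uniform frame
#' times are supported throughout.
#'
#' @param voxels 4D numeric array `(x, y, z, frame)`, finite and
#'   non-negative.
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @param frame_times Numeric vector of frame acquisition times in seconds,
#'   strictly increasing, length equal to the 4th dimension.
#' @param subject_id Free-text identifier.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, voxel_size, frame_times, subject_id = "") {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4D array (x, y, z, frame)", call. = FALSE)
  if (any(dim(voxels)[1:3] < 1L))
    stop("spatial dimensions must be >= 1", call. = FALSE)
  if (dim(voxels)[4] < 10L)
    stop("a dynamic series needs at least 10 frames", call. = FALSE)
  if (length(frame_times) != dim(voxels)[4])
    stop("frame_times length must equal the frame count", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("all voxel values must be finite and >= 0", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 frame_times = as.numeric(frame_times),
                 subject_id = as.character(subject_id)[1]),
            class = "dynamic_series")
}

#' 3D region-of-interest mask
#'
#' @param mask 3D logical array on the spatial grid of its series.
#' @param label One of `"aorta"`, `"left_kidney"`, `"right_kidney"`.
#' @param voxel_volume Volume of one voxel in mL.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("aorta", "left_kidney", "right_kidney"),
                     voxel_volume) {
  label <- match.arg(label)
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!any(mask)) stop("mask must contain at least one voxel", call. = FALSE)
  if (!is.numeric(voxel_volume) || voxel_volume <= 0)
    stop("voxel_volume must be a positive volume in mL", call. = FALSE)
  structure(list(mask = mask, label = label,
                 voxel_volume = as.numeric(voxel_volume)),
            class = "roi_mask")
}

#' Read a 4D dynamic NIfTI series
#'
#' @param path Path to a 4D NIfTI-1 file.
#' @param frame_times Frame times in seconds; if `NULL` a JSON sidecar
#'   `<path minus extension>.json` containing `{"frame_times_s": [...]}` is
#'   read.
#' @param subject_id Identifier stored on the series.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, frame_times = NULL, subject_id = "") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D NIfTI, got %d dimensions", length(d)),
         call. = FALSE)
  if (is.null(frame_times)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    if (!file.exists(sidecar))
      stop("frame_times not given and no JSON sidecar found at ", sidecar,
           call. = FALSE)
    frame_times <- jsonlite::read_json(sidecar,
                                       simplifyVector = TRUE)$frame_times_s
  }
  vs <- RNifti::pixdim(img)[1:3]
  dynamic_series(array(as.numeric(img), dim = d), vs, frame_times, subject_id)
}

#' Write a dynamic series or mask to NIfTI
#'
#' @param series A [dynamic_series()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param frame_times_sidecar Write the JSON frame-time sidecar next to a
#'   series (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path, frame_times_sidecar = TRUE) {
  if (inherits(series, "dynamic_series")) {
    img <- RNifti::asNifti(series$voxels)
    RNifti::pixdim(img) <- c(series$voxel_size, 1)
    RNifti::writeNifti(img, path, datatype = "double")
    if (frame_times_sidecar) {
      sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
      jsonlite::write_json(list(frame_times_s = series$frame_times), sidecar,
                           auto_unbox = FALSE, digits = NA)
    }
  } else if (inherits(series, "roi_mask")) {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(series$mask),
                                             dim = dim(series$mask))),
                       path, datatype = "uint8")
  } else stop("not a dynamic_series or roi_mask", call. = FALSE)
  invisible(path)
}

#' Read a 3D ROI mask from NIfTI
#'
#' Non-zero voxels are in the region.
#'
#' @inheritParams roi_mask
#' @param path Path to a 3D NIfTI file.
#' @param voxel_volume Voxel volume in mL; if `NULL`, computed from the
#'   NIfTI pixdim.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, label, voxel_volume = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI mask", call. = FALSE)
  if (is.null(voxel_volume))
    voxel_volume <- prod(RNifti::pixdim(img)[1:3]) / 1000
  roi_mask(array(as.numeric(img) != 0, dim = d), label, voxel_volume)
}

#' Extract the ROI-mean signal curve from a dynamic series
#'
#' For each frame, the arithmetic mean over all voxels inside the mask. A
#' non-finite voxel inside the mask is an error rather than being silently
#' dropped: it almost always indicates a masking or registration defect
#' upstream.
#'
#' @param series A [dynamic_series()].
#' @param roi A [roi_mask()] on the same spatial grid.
#' @return A [signal_curve()] labelled after the ROI.
#' @export
extract_mean_curve <- function(series, roi) {
  stopifnot(inherits(series, "dynamic_series"), inherits(roi, "roi_mask"))
  if (!identical(dim(series$voxels)[1:3], dim(roi$mask)))
    stop("mask and series spatial grids differ; no resampling is attempted",
         call. = FALSE)
  nf <- dim(series$voxels)[4]
  idx <- which(roi$mask)
  flat <- matrix(series$voxels, ncol = nf)
  vals <- colMeans(flat[idx, , drop = FALSE])
  if (!all(is.finite(vals)))
    stop("non-finite voxel values inside the ROI", call. = FALSE)
  signal_curve(series$frame_times, vals, roi$label)
}

#' Kidney volume from an ROI mask
#'
#' @param roi A kidney [roi_mask()].
#' @return Volume in mL: true-voxel count times the voxel volume.
#' @export
kidney_volume <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  sum(roi$mask) * roi$voxel_volume
}
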