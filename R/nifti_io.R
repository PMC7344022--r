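#' Read a 4D BOLD volume from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file with 4 dimensions.
#' @return A 4D numeric array with attribute `pixdim` (grid spacing + TR)
#'   and attribute `nifti_ref` holding the source header for metadata
#'   copying on write.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI volume: ", path, call. = FALSE)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  attr(arr, "nifti_ref") <- img
  arr
}

#' Write a 4D BOLD volume to NIfTI
#'
#' @param vol 4D numeric array; if it carries a `nifti_ref` attribute the
#'   grid metadata is copied from it.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr Repetition time in seconds, stored in the time pixdim slot.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(vol, path, tr = 0.72) {
  ref <- attr(vol, "nifti_ref")
  arr <- as_array4d(vol)
  img <- if (!is.null(ref)) RNifti::asNifti(arr, reference = ref)
         else RNifti::asNifti(arr)
  if (is.null(ref)) RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer label atlas from NIfTI (+ JSON sidecar)
#'
#' The sidecar carries the parcel names and classes:
#' `{"rois": {"label": [...], "name": [...], "class": [...]}}` — the format
#' written by [write_atlas_nifti()].
#'
#' @param path NIfTI path of the 3D integer label volume.
#' @param sidecar JSON sidecar path; defaults to `<path>.rois.json`.
#' @return An [atlas_labels()] object.
#' @export
read_atlas_nifti <- function(path, sidecar = paste0(path, ".rois.json")) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rois <- as.data.frame(side$rois, stringsAsFactors = FALSE)
  atlas_labels(labels,
               stats::setNames(rois$name, as.character(rois$label)),
               stats::setNames(rois$class, as.character(rois$label)))
}

#' Write an atlas to NIfTI with its JSON sidecar
#'
#' @param atlas An [atlas_labels()] object.
#' @param path Output NIfTI path; sidecar goes to `<path>.rois.json`.
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas3d"))
  img <- RNifti::asNifti(atlas$labels, datatype = "int32")
  RNifti::writeNifti(img, path)
  ids <- atlas_label_ids(atlas)
  jsonlite::write_json(
    list(rois = data.frame(label = ids,
                           name = unname(atlas$label_names),
                           class = unname(atlas$label_class),
                           stringsAsFactors = FALSE)),
    paste0(path, ".rois.json"), dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' Write an entropy map to NIfTI with an undefined-voxel sidecar
#'
#' The value lattice goes to `path` (undefined voxels as NaN), the reason
#' lattice to `<stem>_reason.nii.gz`, and the undefined-voxel tally to a JSON
#' sidecar, so the missing-value encoding round-trips.
#'
#' @param map An `entropy_map`.
#' @param path Output NIfTI path for the values.
#' @return `path`, invisibly.
#' @export
write_entropy_nifti <- function(map, path) {
  stopifnot(inherits(map, "entropy_map"))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  reason <- map$reason
  reason[is.na(reason)] <- -1L  # out of mask
  RNifti::writeNifti(RNifti::asNifti(reason, datatype = "int32"),
                     paste0(stem, "_reason.nii.gz"))
  jsonlite::write_json(as.list(map$undefined_counts),
                       paste0(stem, "_undefined.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an entropy map written by [write_entropy_nifti()]
#'
#' @param path NIfTI path of the value lattice.
#' @return An `entropy_map`.
#' @export
read_entropy_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img))
  values[is.nan(values)] <- NA_real_
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  rimg <- RNifti::readNifti(paste0(stem, "_reason.nii.gz"))
  reason <- array(as.integer(round(as.numeric(rimg))), dim = dim(rimg))
  reason[reason == -1L] <- NA_integer_
  counts <- unlist(jsonlite::read_json(paste0(stem, "_undefined.json"),
                                       simplifyVector = TRUE))
  structure(list(values = values, reason = reason,
                 undefined_counts = counts),
            class = "entropy_map")
}
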