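#' Write and read MRI studies as NIfTI-1
#'
#' The three channels are written as \code{pre.nii.gz}, \code{post.nii.gz},
#' and \code{sub.nii.gz} in \code{dir}, with the voxel spacing carried in the
#' NIfTI header. \code{read_study} reconstructs the study (the subtraction
#' channel is recomputed as post - pre so the in-memory invariant holds
#' bitwise).
#'
#' @param study an \code{mri_study}.
#' @param dir output directory (created if needed).
#' @return \code{write_study} returns the paths invisibly;
#'   \code{read_study} returns an \code{mri_study}.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mri_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("pre.nii.gz", "post.nii.gz", "sub.nii.gz"))
  vols <- list(study$pre_contrast, study$post_contrast, study$subtraction)
  for (i in 1:3) {
    im <- RNifti::asNifti(vols[[i]])
    RNifti::pixdim(im) <- study$voxel_spacing_mm
    RNifti::writeNifti(im, paths[i])
  }
  invisible(paths)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  pre <- RNifti::readNifti(file.path(dir, "pre.nii.gz"))
  post <- RNifti::readNifti(file.path(dir, "post.nii.gz"))
  sp <- RNifti::pixdim(pre)
  new_mri_study(as.array(pre), as.array(post), sp)
}

#' Write and read tissue-label volumes as NIfTI-1
#'
#' Integer codes: 0 background, 1 fat, 2 fibroglandular, 3 tumor; voxel
#' spacing in the header.
#' @param labels a \code{tissue_labels} volume.
#' @param path output \code{.nii.gz} path.
#' @return \code{read_labels} returns a \code{tissue_labels} volume.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_labels"))
  im <- RNifti::asNifti(unclass(labels) + 0L)
  RNifti::pixdim(im) <- attr(labels, "voxel_spacing_mm")
  RNifti::writeNifti(im, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  im <- RNifti::readNifti(path)
  new_tissue_labels(array(as.integer(as.array(im)), dim(im)), RNifti::pixdim(im))
}

#' Write and read chest-wall annotations as JSON
#'
#' One entry per annotated slice: slice index mapped to the list of
#' (row, col) polyline vertices.
#' @param annotation a \code{chest_wall_annotation}.
#' @param path output \code{.json} path.
#' @return \code{read_annotation} returns a \code{chest_wall_annotation}.
#' @export
write_annotation <- function(annotation, path) {
  obj <- lapply(annotation$contours, function(ct)
    list(row = unname(ct[, 1]), col = unname(ct[, 2])))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- as.integer(names(obj))
  contours <- lapply(obj, function(e) cbind(row = e$row, col = e$col))
  names(contours) <- names(obj)
  structure(list(slice_indices = idx, contours = contours),
            class = "chest_wall_annotation")
}
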