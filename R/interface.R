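#' Tumor-fat interface voxels under 6-adjacency
#'
#' The interface is the set of fat voxels in direct face contact with the
#' tumor: a fat voxel qualifies when at least one of its 6 face neighbours
#' (one step along exactly one axis) is labelled tumor. Each qualifying fat
#' voxel is counted once, however many tumor neighbours it has; neighbours
#' outside the grid are treated as background. Note the definition is
#' one-sided: it is the fat-side shell, not the tumor-side one.
#'
#' @param labels a \code{tissue_labels} volume (codes 0 background, 1 fat,
#'   2 fibroglandular, 3 tumor) or a plain 3D integer array with those codes.
#' @param voxel_spacing_mm spacing override when \code{labels} is a plain
#'   array without a spacing attribute.
#' @return A list of class \code{interface_result}: \code{coords} (n x 3
#'   integer matrix of voxel indices), \code{count}, and \code{volume_cm3}
#'   (count x voxel volume in mm^3 / 1000).
#' @export
find_interface <- function(labels, voxel_spacing_mm = NULL) {
  sp <- voxel_spacing_mm %||% attr(labels, "voxel_spacing_mm")
  stopifnot(length(dim(labels)) == 3L)
  if (is.null(sp)) sp <- c(1, 1, 1)
  stopifnot(length(sp) == 3L, all(sp > 0))
  arr <- unclass(labels)
  tumor <- arr == 3L
  fat <- arr == 1L
  near_tumor <- shift_any(tumor)
  iface <- fat & near_tumor
  coords <- which(iface, arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  n <- nrow(coords)
  structure(list(coords = coords,
                 count = n,
                 volume_cm3 = n * prod(sp) / 1000),
            class = "interface_result")
}

# logical OR of the six face-shifted copies of a 3D logical array,
# out-of-bounds treated as FALSE
shift_any <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  # neighbour one step back/forward along each axis
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[-1, , ]    <- out[-1, , ]    | m[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, -1, ]    <- out[, -1, ]    | m[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out[, , -1]    <- out[, , -1]    | m[, , -d[3]]
  out
}

#' Volumetric summary of a labelled breast volume
#'
#' Counts fat, fibroglandular, and tumor voxels (optionally restricted to a
#' breast search-region mask), converts counts to cm^3 via the voxel volume,
#' and measures the tumor-fat interface with \code{\link{find_interface}}.
#' Breast volume is the sum of the three tissue volumes.
#'
#' @param labels a \code{tissue_labels} volume.
#' @param mask optional logical array (breast search region); defaults to
#'   all non-background voxels.
#' @param voxel_spacing_mm spacing override for plain arrays.
#' @return One-row \code{data.frame} of class \code{volumetric_summary} with
#'   the five cm^3 quantities (\code{breast_volume_cm3}, \code{fat_volume_cm3},
#'   \code{fgt_volume_cm3}, \code{tumor_volume_cm3},
#'   \code{interface_volume_cm3}) and the matching voxel counts.
#' @export
summarize_volumes <- function(labels, mask = NULL, voxel_spacing_mm = NULL) {
  sp <- voxel_spacing_mm %||% attr(labels, "voxel_spacing_mm")
  if (is.null(sp) || length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("voxel spacing is missing or non-positive")
  arr <- unclass(labels)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(arr)))
    arr <- arr * (mask != 0)
  }
  vox_cm3 <- prod(sp) / 1000
  n_fat <- sum(arr == 1L)
  n_fgt <- sum(arr == 2L)
  n_tum <- sum(arr == 3L)
  iface <- find_interface(new_tissue_labels(arr, sp))
  out <- data.frame(
    breast_volume_cm3 = (n_fat + n_fgt + n_tum) * vox_cm3,
    fat_volume_cm3 = n_fat * vox_cm3,
    fgt_volume_cm3 = n_fgt * vox_cm3,
    tumor_volume_cm3 = n_tum * vox_cm3,
    interface_volume_cm3 = iface$volume_cm3,
    breast_voxels = n_fat + n_fgt + n_tum,
    fat_voxels = n_fat,
    fgt_voxels = n_fgt,
    tumor_voxels = n_tum,
    interface_voxels = iface$count)
  class(out) <- c("volumetric_summary", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
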