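#' Interpolate the chest-wall surface from sparse slice contours
#'
#' Manual chest-wall delineation is done on every k-th slice; this
#' reconstructs, for every slice between the first and last annotated ones
#' and every left-right column, the anterior-posterior coordinate of the
#' wall. On annotated slices the surface passes through the polyline
#' vertices (linear interpolation across columns between vertices); between
#' annotated slices each column is interpolated linearly along the slice
#' axis.
#'
#' @param annotation a \code{chest_wall_annotation}: \code{slice_indices}
#'   (strictly increasing) and \code{contours}, one two-column matrix
#'   \code{(row, col)} per annotated slice with \code{row} the
#'   anterior-posterior wall coordinate at left-right column \code{col}.
#' @param grid_shape integer (nz, ny, nx) of the target grid.
#' @return nz x nx numeric matrix of wall depths; \code{NA} on slices
#'   outside the annotated range and columns outside the contour extent.
#' @export
interpolate_chest_wall <- function(annotation, grid_shape) {
  stopifnot(inherits(annotation, "chest_wall_annotation") ||
              (is.list(annotation) && !is.null(annotation$slice_indices)))
  idx <- annotation$slice_indices
  stopifnot(length(idx) >= 2L, all(diff(idx) > 0))
  nz <- grid_shape[1]; nx <- grid_shape[3]
  cols <- seq_len(nx)

  per_slice <- matrix(NA_real_, nrow = length(idx), ncol = nx)
  for (i in seq_along(idx)) {
    ct <- annotation$contours[[i]]
    stopifnot(is.matrix(ct), ncol(ct) == 2L, nrow(ct) >= 3L)
    if (anyDuplicated(ct[, 2]) &&
        any(tapply(ct[, 1], ct[, 2], function(v) diff(range(v))) > 1e-8))
      stop("contour on slice ", idx[i],
           " is not a function of the left-right coordinate (self-folding)")
    o <- order(ct[, 2])
    per_slice[i, ] <- stats::approx(ct[o, 2], ct[o, 1], xout = cols,
                                    rule = 1, ties = mean)$y
  }

  wall <- matrix(NA_real_, nrow = nz, ncol = nx)
  zr <- idx[1]:idx[length(idx)]
  for (j in cols) {
    v <- per_slice[, j]
    if (all(is.na(v))) next
    wall[zr, j] <- stats::approx(idx, v, xout = zr, rule = 1)$y
  }
  wall
}

#' Build the breast search-region mask
#'
#' The search region is the body tissue strictly anterior to the chest-wall
#' surface. Air is excluded by a global two-class intensity split of the
#' pre-contrast channel (1-D k-means with two centres; threshold at their
#' midpoint).
#'
#' @param study an \code{mri_study}.
#' @param wall nz x nx wall-depth matrix from
#'   \code{\link{interpolate_chest_wall}}.
#' @return Logical 3D array of class \code{breast_mask}.
#' @export
build_breast_mask <- function(study, wall) {
  stopifnot(inherits(study, "mri_study"))
  pre <- study$pre_contrast
  d <- dim(pre)
  stopifnot(nrow(wall) == d[1], ncol(wall) == d[3])

  v <- as.numeric(pre)
  if (diff(range(v)) < 1e-12)
    stop("empty breast mask: pre-contrast image is constant (no body region)")
  km <- stats::kmeans(v, centers = range(v), iter.max = 50)
  thr <- mean(km$centers)
  body <- pre > thr
  if (!any(body)) stop("empty breast mask: no voxels above the air threshold")

  y <- slice.index(pre, 2)
  wall_vol <- aperm(array(wall, dim = d[c(1, 3, 2)]), c(1, 3, 2))
  anterior <- !is.na(wall_vol) & y < wall_vol
  mask <- body & anterior
  if (!any(mask))
    stop("empty breast mask: no body voxels anterior to the chest wall")
  class(mask) <- c("breast_mask", class(mask))
  mask
}

#' Two-stage k-means tissue clustering
#'
#' Separates the breast search region into fat, tumor, and normal
#' fibroglandular tissue. Stage 1 clusters the pre-contrast intensities
#' within the mask into two classes; under the fat-suppressed convention the
#' lower-mean cluster is fat. Stage 2 clusters the subtraction intensities
#' of the remaining (non-fat) voxels into two classes; the higher-mean
#' cluster is the enhancing tumor, the other normal fibroglandular tissue.
#' Cluster-to-tissue assignment is always by cluster-mean ordering, never by
#' cluster index, so it is invariant to initialization and to monotone
#' affine rescaling of a channel. Each channel is standardized within its
#' voxel set before clustering.
#'
#' @param study an \code{mri_study}.
#' @param mask logical breast search-region mask.
#' @param seed integer seed controlling the k-means restarts.
#' @param nstart number of k-means restarts (default 10).
#' @return A \code{tissue_labels} volume (0 outside the mask).
#' @export
cluster_tissues <- function(study, mask, seed = 1L, nstart = 10L) {
  stopifnot(inherits(study, "mri_study"), identical(dim(mask), dim(study$pre_contrast)))
  if (!any(mask)) stop("breast mask is empty")
  pre <- study$pre_contrast[mask]
  sub <- study$subtraction[mask]
  if (any(!is.finite(pre)) || any(!is.finite(sub)))
    stop("non-finite intensities inside the breast mask")

  fat_in_mask <- withr::with_seed(seed, kmeans_two(pre, "stage 1 (fat vs non-fat)", nstart))
  nonfat <- which(!fat_in_mask)
  if (length(nonfat) < 2L)
    stop("no enhancing tissue detected: stage 1 left no non-fat voxels to split")
  stage2 <- withr::with_seed(seed + 1L,
                             kmeans_two(sub[nonfat],
                                        "stage 2 (tumor vs fibroglandular)", nstart))
  labels_in_mask <- integer(length(pre))
  labels_in_mask[fat_in_mask] <- 1L
  labels_in_mask[nonfat[stage2]] <- 2L
  labels_in_mask[nonfat[!stage2]] <- 3L

  out <- array(0L, dim(mask))
  out[mask] <- labels_in_mask
  new_tissue_labels(out, study$voxel_spacing_mm)
}

# 2-class 1-D k-means on standardized values; returns logical "low-mean
# cluster" membership. Errors on constant input or an empty cluster.
kmeans_two <- function(v, stage, nstart = 10L) {
  if (diff(range(v)) < 1e-12)
    stop(stage, ": intensities are constant, cannot form two clusters")
  z <- (v - mean(v)) / stats::sd(v)
  km <- stats::kmeans(z, centers = 2L, nstart = nstart, iter.max = 100)
  if (any(km$size == 0L)) stop(stage, ": k-means produced an empty cluster")
  low <- which.min(km$centers)
  km$cluster == low
}
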