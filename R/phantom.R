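#' Phantom configuration
#'
#' Builds the configuration for a synthetic multiphase breast-MRI phantom.
#' The phantom emulates the three image classes the measurement pipeline
#' consumes: a fat-suppressed pre-contrast T1 volume (fat is the darkest
#' tissue), a post-contrast volume, and their subtraction, in which only the
#' tumor enhances strongly. Geometry is a breast dome resting on a smooth
#' chest-wall surface, filled with fat and a central fibroglandular
#' compartment, with one or more ellipsoidal tumors whose surface contact
#' with fat is controllable.
#'
#' @param grid_shape integer vector (nz, ny, nx): voxels along the slice
#'   (superior-inferior), anterior-posterior, and left-right axes. All >= 8.
#' @param voxel_spacing_mm numeric (dz, dy, dx) in millimetres, all > 0.
#'   The default 3 x 0.8 x 0.8 mm is anisotropic like clinical breast MRI.
#' @param fat_fraction target fraction of breast voxels that are fat, in (0,1).
#' @param tumor_radius_mm radius of the ellipsoidal tumor(s) in mm (isotropic
#'   in physical space).
#' @param tumor_count number of lesions (placed side by side left-right).
#' @param tumor_margin_contact fraction in [0,1] of the tissue shell around
#'   each tumor assigned to fat (the rest is fibroglandular); 0 isolates the
#'   tumor from fat entirely, 1 embeds it fully in fat.
#' @param intensity_means 5 x 2 numeric matrix of per-tissue mean signal,
#'   rows \code{c("air","chest","fat","fgt","tumor")}, columns
#'   \code{c("pre","sub")}. Defaults follow the fat-suppressed convention:
#'   on \code{pre}, fat < fibroglandular; on \code{sub}, tumor > fibroglandular > fat.
#' @param noise_sd additive Gaussian noise s.d. per channel, >= 0.
#' @param seed integer random seed; the whole phantom is deterministic given it.
#' @param annotation_step annotate the chest wall on every k-th slice (default 5).
#' @param shell_mm thickness of the controlled-tissue shell around each tumor.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(64L, 128L, 128L),
                           voxel_spacing_mm = c(3, 0.8, 0.8),
                           fat_fraction = 0.6,
                           tumor_radius_mm = 12,
                           tumor_count = 1L,
                           tumor_margin_contact = 0.6,
                           intensity_means = default_intensity_means(),
                           noise_sd = 10,
                           seed = 1L,
                           annotation_step = 5L,
                           shell_mm = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            fat_fraction > 0, fat_fraction < 1,
            tumor_radius_mm > 0, tumor_count >= 1L,
            tumor_margin_contact >= 0, tumor_margin_contact <= 1,
            is.matrix(intensity_means),
            all(c("air", "chest", "fat", "fgt", "tumor") %in% rownames(intensity_means)),
            all(c("pre", "sub") %in% colnames(intensity_means)),
            noise_sd >= 0, annotation_step >= 1L, shell_mm >= 0)
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 fat_fraction = fat_fraction,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_count = as.integer(tumor_count),
                 tumor_margin_contact = tumor_margin_contact,
                 intensity_means = intensity_means,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 annotation_step = as.integer(annotation_step),
                 shell_mm = shell_mm),
            class = "phantom_config")
}

#' Default per-tissue mean signal for the phantom channels
#'
#' On the fat-suppressed pre-contrast channel fat is the lowest-mean tissue;
#' on the subtraction channel the tumor enhances far above fibroglandular
#' tissue and fat. Units are arbitrary scanner units.
#' @return 5 x 2 matrix, rows air/chest/fat/fgt/tumor, columns pre/sub.
#' @export
default_intensity_means <- function() {
  m <- rbind(air   = c(0,   0),
             chest = c(130, 5),
             fat   = c(100, 10),
             fgt   = c(150, 40),
             tumor = c(140, 180))
  colnames(m) <- c("pre", "sub")
  m
}

# Chest-wall depth (anterior-posterior voxel coordinate) as a smooth sheet:
# quadratic in the left-right coordinate, linear along the slice axis, so the
# every-k-th-slice polylines sample it losslessly under linear interpolation.
wall_depth <- function(z, x, grid_shape) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  cx <- (nx + 1) / 2
  base <- 0.62 * ny
  slope <- 0.06 * ny
  curve <- -0.08 * ny
  base + slope * (z - 1) / max(nz - 1, 1) + curve * ((x - cx) / (nx / 2))^2
}

# Signed anterior distance field d[z,y,x] = wall(z,x) - y (voxel units, > 0
# anterior to the wall), plus helper coordinate arrays.
phantom_geometry <- function(grid_shape) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  z <- slice.index(array(0, grid_shape), 1)
  y <- slice.index(array(0, grid_shape), 2)
  x <- slice.index(array(0, grid_shape), 3)
  wall <- wall_depth(z, x, grid_shape)
  list(z = z, y = y, x = x, wall = wall, d = wall - y)
}

#' Generate a synthetic multiphase breast-MRI study with known ground truth
#'
#' Constructs the tissue-label volume first (air, chest wall, fat,
#' fibroglandular tissue, tumor), then renders the pre-contrast and
#' subtraction channels from the per-tissue means plus independent Gaussian
#' noise; the post-contrast channel is pre + subtraction exactly. Chest-wall
#' contours are sampled from the parametric wall surface on every k-th slice.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return A list with components \code{study} (class \code{mri_study}:
#'   \code{pre_contrast}, \code{post_contrast}, \code{subtraction},
#'   \code{voxel_spacing_mm}), \code{annotation} (class
#'   \code{chest_wall_annotation}: \code{slice_indices}, \code{contours}),
#'   and \code{truth} (class \code{phantom_truth}: \code{labels} with the
#'   code table 0 background / 1 fat / 2 fibroglandular / 3 tumor, and
#'   \code{true_volumes}, the volumetric summary counted directly on the
#'   ground-truth labels).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  sp <- config$voxel_spacing_mm
  nz <- gs[1]; ny <- gs[2]; nx <- gs[3]
  geo <- phantom_geometry(gs)

  # breast dome: anterior of the wall, inside a half-ellipsoid resting on it
  cz <- (nz + 1) / 2; cx <- (nx + 1) / 2
  Rz <- 0.45 * nz; Ry <- 0.45 * ny; Rx <- 0.42 * nx
  dome <- (geo$d / Ry)^2 + ((geo$x - cx) / Rx)^2 + ((geo$z - cz) / Rz)^2
  breast <- geo$d > 0 & dome <= 1

  # central fibroglandular compartment scaled to the target fat fraction
  s <- (1 - config$fat_fraction)^(1 / 3)
  fgt <- geo$d > 0 & dome <= s^2    # same quadratic form, semi-axes scaled by s

  labels <- array(0L, gs)
  labels[breast] <- 1L
  labels[breast & fgt] <- 2L

  # tumors: ellipsoids isotropic in mm, centred in the fibroglandular
  # compartment, spread left-right when there are several
  r_vox <- config$tumor_radius_mm / sp                 # (z, y, x) semi-axes
  tz <- cz
  ty <- wall_depth(cz, cx, gs) - 0.45 * s * Ry
  n_t <- config$tumor_count
  offsets <- if (n_t == 1) 0 else seq(-1, 1, length.out = n_t) * 0.5 * s * Rx
  tumor <- array(FALSE, gs)
  for (off in offsets) {
    txc <- cx + off
    ell <- ((geo$z - tz) / r_vox[1])^2 + ((geo$y - ty) / r_vox[2])^2 +
      ((geo$x - txc) / r_vox[3])^2 <= 1
    if (any(ell & !breast))
      stop("tumor of radius ", config$tumor_radius_mm,
           " mm at (", round(tz), ",", round(ty), ",", round(txc),
           ") does not fit inside the breast region")
    tumor <- tumor | ell
  }

  # controlled shell: within shell_mm of a tumor surface, assign fat vs
  # fibroglandular by azimuthal wedge so a fraction tumor_margin_contact of
  # the tumor surface touches fat
  if (config$shell_mm > 0) {
    rs <- (config$tumor_radius_mm + config$shell_mm) / sp
    shell <- array(FALSE, gs)
    for (off in offsets) {
      txc <- cx + off
      shell <- shell | (((geo$z - tz) / rs[1])^2 + ((geo$y - ty) / rs[2])^2 +
                          ((geo$x - txc) / rs[3])^2 <= 1)
    }
    shell <- shell & !tumor & breast
    if (any(shell)) {
      ang <- atan2(geo$x - cx, geo$y - ty)  # (-pi, pi]
      frac <- (ang + pi) / (2 * pi)
      labels[shell] <- ifelse(frac[shell] < config$tumor_margin_contact, 1L, 2L)
    }
  }
  labels[tumor] <- 3L

  # render channels
  means <- config$intensity_means
  render_code <- array(0L, gs)              # 0 air, 1 chest, 2 fat, 3 fgt, 4 tumor
  render_code[geo$d <= 0] <- 1L             # chest slab posterior to the wall
  render_code[labels == 1L] <- 2L
  render_code[labels == 2L] <- 3L
  render_code[labels == 3L] <- 4L
  tissue_order <- c("air", "chest", "fat", "fgt", "tumor")
  pre <- array(means[tissue_order, "pre"][render_code + 1L], gs)
  sub <- array(means[tissue_order, "sub"][render_code + 1L], gs)
  if (config$noise_sd > 0) {
    withr::with_seed(config$seed, {
      pre <- pre + array(stats::rnorm(length(pre), 0, config$noise_sd), gs)
      sub <- sub + array(stats::rnorm(length(sub), 0, config$noise_sd), gs)
    })
  }
  study <- new_mri_study(pre, pre + sub, sp)

  # every-k-th-slice contours sampled from the parametric wall
  slice_idx <- unique(c(seq(1L, nz, by = config$annotation_step), nz))
  contours <- lapply(slice_idx, function(z) {
    xs <- seq_len(nx)
    cbind(row = wall_depth(z, xs, gs), col = xs)
  })
  names(contours) <- as.character(slice_idx)
  annotation <- structure(list(slice_indices = slice_idx, contours = contours),
                          class = "chest_wall_annotation")

  labels <- new_tissue_labels(labels, sp)
  truth <- structure(list(labels = labels,
                          true_volumes = summarize_volumes(labels)),
                     class = "phantom_truth")
  list(study = study, annotation = annotation, truth = truth)
}

#' Construct a co-registered multiphase MRI study
#'
#' @param pre_contrast,post_contrast 3D numeric arrays of identical shape;
#'   axis order is (slice, anterior-posterior, left-right).
#' @param voxel_spacing_mm numeric (dz, dy, dx) in mm.
#' @return An \code{mri_study}; the \code{subtraction} component is
#'   post - pre element-wise.
#' @export
new_mri_study <- function(pre_contrast, post_contrast, voxel_spacing_mm) {
  stopifnot(identical(dim(pre_contrast), dim(post_contrast)),
            length(dim(pre_contrast)) == 3L,
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  structure(list(pre_contrast = pre_contrast,
                 post_contrast = post_contrast,
                 subtraction = post_contrast - pre_contrast,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "mri_study")
}

#' Construct a tissue-label volume
#'
#' Wraps a 3D integer array with the fixed code table (0 background, 1 fat,
#' 2 fibroglandular, 3 tumor) and carries the voxel spacing as an attribute
#' so volumetric conversions stay attached to the data.
#' @param labels 3D array with values in 0..3.
#' @param voxel_spacing_mm numeric (dz, dy, dx), all > 0.
#' @return Integer array of class \code{tissue_labels}.
#' @export
new_tissue_labels <- function(labels, voxel_spacing_mm) {
  stopifnot(length(dim(labels)) == 3L, all(labels %in% 0:3),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  storage.mode(labels) <- "integer"
  attr(labels, "voxel_spacing_mm") <- as.numeric(voxel_spacing_mm)
  class(labels) <- c("tissue_labels", class(labels))
  labels
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Breast MRI phantom config:", paste(x$grid_shape, collapse = "x"),
      "voxels at", paste(x$voxel_spacing_mm, collapse = "x"), "mm\n")
  cat("  fat fraction", x$fat_fraction, "| tumor radius", x$tumor_radius_mm,
      "mm x", x$tumor_count, "| margin contact", x$tumor_margin_contact,
      "| noise sd", x$noise_sd, "| seed", x$seed, "\n")
  invisible(x)
}
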