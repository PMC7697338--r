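make_annotation <- function(slice_indices, contours) {
  structure(list(slice_indices = slice_indices, contours = contours),
            class = "chest_wall_annotation")
}

flat_contour <- function(depth, nx = 10) cbind(row = rep(depth, nx), col = 1:nx)

test_that("identical contours interpolate to a constant surface", {
  ann <- make_annotation(c(1L, 6L), list(flat_contour(20), flat_contour(20)))
  wall <- interpolate_chest_wall(ann, c(6L, 40L, 10L))
  expect_true(all(wall[1:6, ] == 20))
})

test_that("wall depth interpolates linearly along the slice axis", {
  ann <- make_annotation(c(1L, 6L), list(flat_contour(20), flat_contour(30)))
  wall <- interpolate_chest_wall(ann, c(6L, 40L, 10L))
  expect_equal(wall[3, 5], 24)      # two slices of five steps from 20 to 30
  expect_equal(wall[5, 2], 28)
})

test_that("self-folding contours are rejected with the slice named", {
  bad <- rbind(c(20, 1), c(20, 2), c(25, 2), c(20, 3))
  ann <- make_annotation(c(1L, 6L), list(flat_contour(20), bad))
  expect_error(interpolate_chest_wall(ann, c(6L, 40L, 10L)), "slice 6")
})

test_that("phantom-sampled contours reproduce the parametric wall surface", {
  cfg <- small_phantom_config(seed = 2)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  for (i in seq_along(ph$annotation$slice_indices)) {
    z <- ph$annotation$slice_indices[i]
    expect_lt(max(abs(wall[z, ] - ph$annotation$contours[[i]][, "row"])), 1)
  }
})

test_that("breast mask recovers the true breast region", {
  cfg <- small_phantom_config(seed = 6)          # default noise
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  expect_gte(dice(mask, unclass(ph$truth$labels) > 0), 0.95)
})

test_that("a wall at the posterior edge returns the whole body region", {
  cfg <- small_phantom_config(seed = 6, noise_sd = 0)
  ph <- generate_phantom(cfg)
  ny <- cfg$grid_shape[2]
  wall <- matrix(ny + 1, nrow = cfg$grid_shape[1], ncol = cfg$grid_shape[3])
  mask <- build_breast_mask(ph$study, wall)
  expect_identical(unclass(unname(mask)), unname(ph$study$pre_contrast > 50))
})

test_that("an all-air image cannot produce a mask", {
  study <- new_mri_study(array(0, c(8, 8, 8)), array(0, c(8, 8, 8)), c(1, 1, 1))
  wall <- matrix(9, 8, 8)
  expect_error(build_breast_mask(study, wall), "constant")
  study2 <- new_mri_study(array(rnorm(512, 0, 1e-3), c(8, 8, 8)),
                          array(rnorm(512, 0, 1e-3), c(8, 8, 8)), c(1, 1, 1))
  wall2 <- matrix(0, 8, 8)     # nothing anterior to the wall
  expect_error(build_breast_mask(study2, wall2), "anterior")
})

test_that("noiseless phantoms segment perfectly (Dice 1 per tissue)", {
  cfg <- small_phantom_config(seed = 8, noise_sd = 0)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  lab <- cluster_tissues(ph$study, mask, seed = 1)
  for (k in 1:3)
    expect_equal(dice(unclass(lab) == k, unclass(ph$truth$labels) == k), 1)
})

test_that("tissue labels partition the mask", {
  cfg <- small_phantom_config(seed = 10)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  lab <- cluster_tissues(ph$study, mask, seed = 1)
  expect_identical(sum(unclass(lab) > 0L), sum(mask))
  expect_identical(sum(unclass(lab) == 1) + sum(unclass(lab) == 2) +
                     sum(unclass(lab) == 3), sum(mask))
})

test_that("cluster-to-tissue assignment follows mean ordering, not index", {
  # swap the fat and fibroglandular pre-contrast means: the lower-mean
  # cluster must still be called fat, so stage-1 'fat' now covers the true
  # fibroglandular compartment
  means <- default_intensity_means()
  means["fat", "pre"] <- 150; means["fgt", "pre"] <- 100
  means["tumor", "pre"] <- 160
  cfg <- small_phantom_config(seed = 3, noise_sd = 0, intensity_means = means)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  lab <- cluster_tissues(ph$study, mask, seed = 1)
  truth <- unclass(ph$truth$labels)
  expect_equal(dice(unclass(lab) == 1, truth == 2), 1)   # labels swapped
})

test_that("labels are invariant to monotone affine rescaling of a channel", {
  cfg <- small_phantom_config(seed = 12)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  lab1 <- cluster_tissues(ph$study, mask, seed = 5)
  scaled <- new_mri_study(ph$study$pre_contrast,
                          ph$study$pre_contrast + 3 * ph$study$subtraction + 40,
                          cfg$voxel_spacing_mm)
  lab2 <- cluster_tissues(scaled, mask, seed = 5)
  expect_identical(unclass(lab1), unclass(lab2))
})

test_that("separable phantoms give seed-invariant labels", {
  cfg <- small_phantom_config(seed = 4)     # separation >> 4 x noise sd
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  ref <- cluster_tissues(ph$study, mask, seed = 1)
  for (s in 2:10)
    expect_identical(unclass(cluster_tissues(ph$study, mask, seed = s)),
                     unclass(ref))
})

test_that("degenerate clustering inputs raise stage-specific errors", {
  cfg <- small_phantom_config(seed = 2, noise_sd = 0)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  const <- new_mri_study(array(1, dim(mask)), array(2, dim(mask)),
                         cfg$voxel_spacing_mm)
  expect_error(cluster_tissues(const, mask, seed = 1), "stage 1")
})
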