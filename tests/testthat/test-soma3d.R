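test_that("preprocessing preserves constants and helps surface detection", {
  cfg <- somatect_config(equalize_contrast = FALSE)
  const <- array(0.3, c(24, 24, 10))
  expect_equal(preprocess_stack(const, cfg), const, tolerance = 1e-12)

  ## smoothing kernel is normalized: a delta integrates to 1
  delta <- array(0, c(9, 9, 9)); delta[5, 5, 5] <- 1
  sm <- somatect:::gaussian_smooth_3d(delta, 0.6, kernel_size = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-12)

  ph <- generate_ellipsoid_phantom(c(18, 15, 8), c(64, 64, 28), 0)
  noisy <- apply_noise_and_attenuation(0.1 + 0.8 * ph$stack,
                                       photon_scale = 30, seed = 9)
  f_raw <- pratt_fom(surface_measure_3d(noisy), ph$surface_voxels)
  f_pre <- pratt_fom(surface_measure_3d(preprocess_stack(noisy, cfg)),
                     ph$surface_voxels)
  expect_gte(f_pre, f_raw)
})

test_that("contrast equalization compensates depth attenuation", {
  sp <- phantom_spec(c(48, 48, 16),
                     somas = list(list(center = c(24, 24, 8),
                                       semi_axes = c(14, 14, 6))),
                     z_attenuation = 0.9)
  st <- generate_neuron_stack_3d(sp)$stack
  eq <- equalize_stack_contrast(st)
  q <- apply(eq, 3, max)
  expect_lt(max(q[4:12]) / min(q[4:12]), 1.15)  # soma slices re-leveled
})

make_detection <- function(labels) {
  structure(list(records = data.frame(id = sort(setdiff(unique(
    as.vector(labels)), 0L))), labels = labels),
    class = "soma_detection")
}

test_that("deblocking yields one disjoint substack per soma", {
  sp <- phantom_spec(c(96, 96, 12),
                     somas = list(
                       list(center = c(30, 30, 6), semi_axes = c(14, 14, 5)),
                       list(center = c(66, 66, 6), semi_axes = c(14, 14, 5))))
  r <- generate_neuron_stack_3d(sp)
  det <- make_detection(apply(r$truth$soma_labels, c(1, 2), max))
  subs <- deblock_stack(r$stack, det, somatect_config())
  expect_length(subs, 2)
  expect_equal(sum(subs[[1]]$mask & subs[[2]]$mask), 0)
  ## every truth voxel of each soma projects into its dilated mask
  for (i in 1:2) {
    vox <- which(r$truth$soma_labels == subs[[i]]$id, arr.ind = TRUE)
    expect_true(all(subs[[i]]$mask[vox[, 1:2]]))
  }

  none <- make_detection(matrix(0L, 96, 96))
  expect_warning(empty <- deblock_stack(r$stack, none, somatect_config()),
                 "deblock")
  expect_length(empty, 0)
})

test_that("bottom-support thresholding follows the 3-slice mean rule", {
  ## build a minimal substack by hand: constant slices -> strict > empties
  mc <- matrix(TRUE, 8, 8)
  dat <- array(0.5, c(8, 8, 8))
  ss <- structure(list(id = 1L, mask = mc, bbox = c(1, 8, 1, 8),
                       data = dat, mask_crop = mc), class = "substack")
  bot <- extract_bottom_support(ss)
  expect_equal(bot$z, 5:8)
  expect_true(all(!unlist(bot$masks)))

  ## a slice uniformly below its 3-slice mean has empty support
  dat2 <- dat; dat2[, , 6] <- 0.1
  ss2 <- structure(list(id = 1L, mask = mc, bbox = c(1, 8, 1, 8),
                        data = dat2, mask_crop = mc), class = "substack")
  bot2 <- extract_bottom_support(ss2)
  expect_false(any(bot2$masks[[which(bot2$z == 6)]]))

  short <- structure(list(id = 1L, mask = mc, bbox = c(1, 8, 1, 8),
                          data = dat[, , 1:3], mask_crop = mc),
                     class = "substack")
  expect_warning(extract_bottom_support(short), "fewer than 4")
})

test_that("bottom support recovers attenuated phantom cross-sections", {
  sp <- random_neuron_spec_3d(2, seed = 55)
  r <- generate_neuron_stack_3d(sp)
  cfg <- somatect_config()
  pre <- preprocess_stack(r$stack, cfg)
  det <- make_detection(apply(r$truth$soma_labels, c(1, 2), max))
  ss <- deblock_stack(pre, det, cfg)[[1]]
  bot <- extract_bottom_support(ss)
  k <- ss$id
  for (i in seq_along(bot$z)) {
    z <- bot$z[i]
    tm <- (r$truth$soma_labels[, , z] == k)[ss$bbox[1]:ss$bbox[2],
                                            ss$bbox[3]:ss$bbox[4]]
    if (sum(tm) < 100) next   # vanishing cross-sections near the pole
    dc <- segmentation_scores(confusion_counts(bot$masks[[i]], tm))$DC
    expect_gte(dc, 0.8)
  }
})

test_that("volume assembly combines surface top and thresholded bottom", {
  ph <- generate_ellipsoid_phantom(c(16, 14, 9), c(64, 64, 24), 0.6)
  mc <- matrix(TRUE, 64, 64)
  ss <- structure(list(id = 1L, mask = mc, bbox = c(1, 64, 1, 64),
                       data = ph$stack, mask_crop = mc), class = "substack")
  surf <- surface_measure_3d(ph$stack)
  surf_top <- surf[surf[, 3] <= 12, , drop = FALSE]
  bot <- extract_bottom_support(ss)
  vol <- assemble_soma_volume(surf_top, bot, ss)
  truth_n <- sum(somatect:::ellipsoid_q_3d(c(64, 64, 24), c(32.5, 32.5, 12.5),
                                           c(16, 14, 9)) <= 1)
  expect_lt(abs(vol$volume_voxels - truth_n) / truth_n, 0.15)
  expect_equal(vol$volume_um3, vol$volume_voxels * 0.28 * 0.28 * 1)

  ## empty bottom: volume reduces to the filled top region
  none <- list(z = integer(0), masks = list())
  vtop <- assemble_soma_volume(surf_top, none, ss)
  expect_true(all(vtop$voxels[, 3] <= 12))
  expect_gt(vtop$volume_voxels, 0)
})

test_that("3D pipeline finds one volume per soma and none in empty stacks", {
  cfg <- somatect_config(segmenter = cached_segmenter_3d())
  sp <- random_neuron_spec_3d(2, seed = 451)
  r <- generate_neuron_stack_3d(sp)
  res <- suppressWarnings(detect_somas_3d(r$stack, cfg))
  expect_length(res$volumes, 2)
  ## volumes are voxel-disjoint and inside their substack footprints
  occ <- array(0L, dim(r$stack))
  for (v in res$volumes) {
    expect_true(all(occ[v$voxels] == 0))
    occ[v$voxels] <- v$id
  }

  flat <- array(0.05, c(96, 96, 12))
  expect_warning(res0 <- detect_somas_3d(flat, cfg))
  expect_length(res0$volumes, 0)
})
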