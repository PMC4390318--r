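## 3D soma pipeline for thin confocal stacks: denoise and smooth, run the
## 2D detection on the maximum-intensity projection, deblock the stack into
## single-soma substacks using the 2D soma supports, detect the upper soma
## surface with the pseudo-3D shearlet measure, recover the poorly
## contrasted bottom half by localized 3-slice-mean thresholding, and
## assemble the full volume.

#' Preprocess an image stack
#'
#' Each slice is denoised with the shearlet shrinkage routine; the contrast
#' of the deeper slices — which decays strongly with distance from the
#' light source — is then equalized ([equalize_stack_contrast()]), and the
#' whole stack is smoothed with a 3x3x3 Gaussian kernel of standard
#' deviation 0.6 voxels to even out the fluorescence signal before surface
#' detection.
#'
#' @param stack 3D numeric array.
#' @param config a [somatect_config()] list.
#' @return Array of the same shape.
#' @export
preprocess_stack <- function(stack, config = somatect_config()) {
  d <- dim(stack)
  stopifnot(length(d) == 3, all(d > 0))
  if (isTRUE(config$denoise)) {
    sys2d <- build_system_2d(d[1:2], n_scales = config$n_scales,
                             shears_per_scale = config$n_orientations,
                             filter_length = config$filter_length_fine)
    for (k in seq_len(d[3]))
      stack[, , k] <- shrink_denoise(stack[, , k], sys2d,
                                     list(k = config$shrinkage_k))
  }
  if (isTRUE(config$equalize_contrast))
    stack <- equalize_stack_contrast(stack,
                                     max_gain = config$equalize_max_gain)
  gaussian_smooth_3d(stack, config$smoothing_sigma,
                     kernel_size = config$smoothing_kernel)
}

#' Equalize per-slice contrast of a stack
#'
#' Rescales every slice so that its bright-signal level (the `prob`
#' intensity quantile) matches the brightest slice's, compensating the
#' multiplicative depth attenuation of confocal stacks. The gain is capped
#' at `max_gain` so that slices containing no signal do not have their
#' noise amplified without bound.
#'
#' @param stack 3D numeric array.
#' @param prob quantile used as the per-slice signal level (default 0.995).
#' @param max_gain maximum amplification per slice (default 4).
#' @return Array of the same shape.
#' @export
equalize_stack_contrast <- function(stack, prob = 0.995, max_gain = 4) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  q <- vapply(seq_len(d[3]),
              function(k) stats::quantile(stack[, , k], prob, names = FALSE),
              numeric(1))
  ref <- max(q)
  if (ref <= 0) return(stack)
  gain <- pmin(ref / pmax(q, ref / max_gain), max_gain)
  sweep(stack, 3, gain, `*`)
}

#' Deblock a stack into single-soma substacks
#'
#' Uses the 2D soma supports detected on the projection: each soma's mask,
#' dilated by `config$deblock_margin` pixels, selects the (x, y) footprint
#' of its substack across all slices. Dilated masks that collide are
#' resolved to the soma whose original support is nearest, so substack
#' footprints are pairwise disjoint and not necessarily rectangular.
#'
#' @param stack 3D numeric array.
#' @param detection a [detect_somas_2d()] result computed on the stack's
#'   projection.
#' @param config a [somatect_config()] list.
#' @return List of `substack` objects: `id`, `mask` (full-frame 2D
#'   support), `bbox` (`c(r0, r1, c0, c1)`), `data` (cropped volume, zero
#'   outside the mask), `mask_crop`.
#' @export
deblock_stack <- function(stack, detection, config = somatect_config()) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  lab <- detection$labels
  stopifnot(all(dim(lab) == d[1:2]))
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) {
    warning("no 2D somas detected; nothing to deblock")
    return(list())
  }
  margin <- config$deblock_margin
  brush <- EBImage::makeBrush(2 * margin + 1, "disc")
  dil <- lapply(ids, function(k) EBImage::dilate((lab == k) * 1, brush) > 0)
  ## resolve collisions between dilated supports: nearest original support
  if (length(ids) > 1) {
    dmaps <- lapply(ids, function(k)
      EBImage::distmap((lab != k) * 1))  # distance to soma k's support
    overlap_owner <- function(px) {
      dd <- vapply(dmaps, function(m) m[px], numeric(1))
      which.min(dd)  # ties resolve to the lower id
    }
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      both <- which(dil[[i]] & dil[[j]])
      for (px in both) {
        if (overlap_owner(px) == i) dil[[j]][px] <- FALSE
        else dil[[i]][px] <- FALSE
      }
    }
  }
  lapply(seq_along(ids), function(i) {
    m <- dil[[i]]
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    mc <- m[rr[1]:rr[2], cc[1]:cc[2]]
    sub <- stack[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
    sub <- sub * array(mc, dim(sub))
    structure(list(id = ids[i], mask = m,
                   bbox = c(rr[1], rr[2], cc[1], cc[2]),
                   data = sub, mask_crop = mc),
              class = "substack")
  })
}

top_half_slices <- function(nz) seq_len(ceiling(nz / 2))
bottom_half_slices <- function(nz) setdiff(seq_len(nz), top_half_slices(nz))

#' Extract the soma support in the bottom half of a substack
#'
#' For each bottom-half slice the scalar mean intensity of the masked
#' region over the three successive slices centered there (clamped at the
#' stack ends) is used as that slice's threshold; pixels strictly above it
#' form the support, cleaned by hole filling followed by one erosion with a
#' 3x3 cross. This simple localized thresholding works because the mask
#' tightly encases the soma.
#'
#' @param substack a [deblock_stack()] element.
#' @return List with `z` (bottom-half slice indices) and `masks` (list of
#'   cropped logical matrices).
#' @export
extract_bottom_support <- function(substack) {
  stopifnot(inherits(substack, "substack"))
  dat <- substack$data
  mc <- substack$mask_crop
  nz <- dim(dat)[3]
  zb <- bottom_half_slices(nz)
  all_slices <- nz < 4
  if (all_slices)
    warning("substack has fewer than 4 slices; ",
            "thresholds computed from all slices")
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  masks <- lapply(zb, function(i) {
    js <- if (all_slices) seq_len(nz) else intersect((i - 1):(i + 1),
                                                     seq_len(nz))
    vals <- unlist(lapply(js, function(j) dat[, , j][mc]))
    thr <- mean(vals)
    supp <- mc & dat[, , i] > thr
    if (any(supp)) {
      supp <- EBImage::fillHull(supp * 1) > 0
      supp <- EBImage::erode(supp * 1, cross) > 0
    }
    supp
  })
  list(z = zb, masks = masks)
}

#' Assemble a soma volume from its surface and bottom supports
#'
#' Top-half cross-sections are obtained by closing and filling the detected
#' surface voxels slice by slice; their union with the bottom-half supports
#' is reduced to its largest 26-connected component.
#'
#' @param surface_voxels integer matrix (row, col, slice) in substack
#'   coordinates, normally restricted to the top half.
#' @param bottom an [extract_bottom_support()] result.
#' @param substack the originating substack.
#' @param voxel_size micrometers per voxel (x, y, z).
#' @return Object of class `soma_volume`: `id`, `voxels` (n x 3, parent
#'   coordinates), `volume_voxels`, `volume_um3`, `bbox`, `mask_array`
#'   (cropped logical 3D array).
#' @export
assemble_soma_volume <- function(surface_voxels, bottom, substack,
                                 voxel_size = c(0.28, 0.28, 1)) {
  stopifnot(inherits(substack, "substack"))
  dc <- dim(substack$data)
  vol <- array(FALSE, dc)
  mc <- substack$mask_crop
  close_brush <- EBImage::makeBrush(5, "disc")
  surface_voxels <- rbind(surface_voxels)
  for (k in top_half_slices(dc[3])) {
    pts <- surface_voxels[surface_voxels[, 3] == k, , drop = FALSE]
    if (!nrow(pts)) next
    ring <- matrix(FALSE, dc[1], dc[2])
    ring[pts[, 1:2, drop = FALSE]] <- TRUE
    m <- EBImage::dilate(ring * 1, close_brush)
    m <- EBImage::fillHull(m)
    m <- EBImage::erode(m, close_brush) > 0
    vol[, , k] <- m & mc
  }
  for (i in seq_along(bottom$z))
    vol[, , bottom$z[i]] <- vol[, , bottom$z[i]] | bottom$masks[[i]]
  if (!any(vol)) {
    warning("empty soma volume")
    return(structure(list(id = substack$id,
                          voxels = matrix(integer(0), 0, 3),
                          volume_voxels = 0L, volume_um3 = 0,
                          bbox = substack$bbox, mask_array = vol),
                     class = "soma_volume"))
  }
  cc <- .cc_label_3d_cpp(as.vector(vol), dim(vol))
  keep <- which.max(tabulate(cc[cc > 0]))
  vol <- array(cc == keep, dim(vol))
  vox <- which(vol, arr.ind = TRUE)
  vox[, 1] <- vox[, 1] + substack$bbox[1] - 1L
  vox[, 2] <- vox[, 2] + substack$bbox[3] - 1L
  colnames(vox) <- c("row", "col", "slice")
  structure(list(id = substack$id, voxels = vox,
                 volume_voxels = nrow(vox),
                 volume_um3 = nrow(vox) * prod(voxel_size),
                 bbox = substack$bbox, mask_array = vol),
            class = "soma_volume")
}

#' @export
print.soma_volume <- function(x, ...) {
  cat("soma volume: id", x$id, "-", x$volume_voxels, "voxels (",
      round(x$volume_um3, 1), "um^3 )\n")
  invisible(x)
}

#' Detect soma volumes in a thin 3D confocal stack
#'
#' The full 3D pipeline: [preprocess_stack()], 2D detection on the
#' maximum-intensity projection, [deblock_stack()], per-substack
#' [surface_measure_3d()] on the top half plus [extract_bottom_support()]
#' on the bottom half, and [assemble_soma_volume()].
#'
#' @param stack 3D numeric array.
#' @param config a [somatect_config()] list.
#' @return List of class `soma_volumes`: `volumes` (list of `soma_volume`),
#'   `detection_2d` (the projected-image detection).
#' @export
detect_somas_3d <- function(stack, config = somatect_config()) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  pre <- preprocess_stack(stack, config)
  ## 2D soma localization on the projection of the raw stack (the 2D
  ## pipeline performs its own denoising); the contrast-equalized stack is
  ## reserved for surface detection and bottom-support extraction, where
  ## the depth attenuation would otherwise defeat a global threshold
  det2d <- detect_somas_2d(project_stack(stack, config$projection), config)
  subs <- if (nrow(det2d$records))
    deblock_stack(pre, det2d, config) else list()
  vols <- lapply(subs, function(ss) {
    surf <- surface_measure_3d(ss$data,
                               n_orientations = config$n_orientations,
                               threshold_frac = config$surface_threshold)
    surf <- surf[surf[, 3] <= ceiling(dim(ss$data)[3] / 2), , drop = FALSE]
    bottom <- extract_bottom_support(ss)
    assemble_soma_volume(surf, bottom, ss, config$voxel_size)
  })
  structure(list(volumes = vols, detection_2d = det2d),
            class = "soma_volumes")
}
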