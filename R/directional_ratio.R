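## The Directional Ratio: a per-pixel measure of directional coherence,
## defined as the ratio of the minimum to the maximum magnitude of the
## directional filter responses over orientation, at the scale set by the
## filter support length. Values near 1 indicate isotropic neighborhoods
## (inside a soma, every oriented window of length no larger than the soma
## diameter is filled the same way); values well below 1 indicate elongated
## structures (inside a neurite the window across the tube is mostly empty
## while the window along it is full).

#' Compute the Directional Ratio inside a segmentation mask
#'
#' The statistic is computed on the binary mask itself (the segmented
#' neuron), not on raw intensities, so it reflects shape only. At each
#' in-mask pixel the oriented averaging filters of the system's
#' `filter_length` are evaluated over all orientations and the ratio
#' min/max of their magnitudes is taken; where the maximum response is 0
#' the ratio is defined as 0.
#'
#' @param mask logical or 0/1 matrix (nonempty for a meaningful map).
#' @param system a [build_system_2d()] object whose shape matches `mask`
#'   and whose `filter_length` equals the `filter_length` argument.
#' @param filter_length directional filter support length in pixels.
#' @return Object of class `dr_map`: list with `values` (matrix in
#'   `[0, 1]`, 0 outside the mask), `mask`, and `filter_length`.
#' @export
compute_directional_ratio <- function(mask, system,
                                      filter_length = system$filter_length) {
  stopifnot(inherits(system, "shearlet_system"))
  if (filter_length != system$filter_length)
    stop("system was built with filter_length ", system$filter_length,
         ", not ", filter_length,
         "; build a system at the requested length")
  m <- as.logical(mask)
  dim(m) <- dim(mask)
  if (!all(dim(m) == system$image_shape))
    stop("mask shape does not match system shape")
  vals <- matrix(0, nrow(m), ncol(m))
  if (any(m)) {
    Fm <- stats::fft(m * 1)
    lo <- NULL; hi <- NULL
    for (K in system$dr_fft) {
      r <- abs(ifft_real(Fm * K))
      if (is.null(lo)) { lo <- r; hi <- r }
      else { lo <- pmin(lo, r); hi <- pmax(hi, r) }
    }
    ok <- m & hi > 0
    vals[ok] <- lo[ok] / hi[ok]
  }
  structure(list(values = vals, mask = m, filter_length = filter_length),
            class = "dr_map")
}

#' Extract seed regions strictly inside somas
#'
#' Connected components of the superlevel set `{D >= threshold}` with area
#' at least `min_area`. With the default threshold 0.9 these regions lie
#' strictly inside blob-like structures and serve as the initialization
#' fronts of the level-set evolution.
#'
#' @param drmap a [compute_directional_ratio()] result.
#' @param threshold fraction in (0, 1); default 0.9.
#' @param min_area minimum component area in px^2 (default 50).
#' @return Integer label matrix (0 = background); possibly all zero.
#' @export
extract_seed_regions <- function(drmap, threshold = 0.9, min_area = 50) {
  stopifnot(inherits(drmap, "dr_map"), threshold > 0, threshold < 1)
  sel <- drmap$mask & drmap$values >= threshold
  if (!any(sel)) return(matrix(0L, nrow(drmap$values), ncol(drmap$values)))
  lab <- EBImage::bwlabel(sel * 1)
  keep_components(lab, min_area)
}

## drop labeled components below min_area and relabel 1..n in raster order
keep_components <- function(lab, min_area) {
  lab <- round(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  new_id <- 0L
  for (k in keep) {
    new_id <- new_id + 1L
    out[lab == k] <- new_id
  }
  out
}
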