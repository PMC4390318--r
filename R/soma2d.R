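## 2D soma detection: project -> denoise -> segment -> Directional Ratio at
## filter length 20 -> seed regions at threshold 0.9 -> level-set completion
## -> 3-sigma area criterion -> coarse-scale (40 px) separation of clustered
## somas. Fully automatic.

#' Project an image stack along z
#'
#' @param stack 3D numeric array (`nrow x ncol x nslice`).
#' @param mode `"MIP"` (per-pixel maximum, the default used throughout this
#'   package) or `"AIP"` (per-pixel mean).
#' @return Numeric matrix.
#' @export
project_stack <- function(stack, mode = c("MIP", "AIP")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 1)
  if (mode == "MIP") apply(stack, c(1, 2), max) else apply(stack, c(1, 2), mean)
}

#' Fit the expected-soma-area model
#'
#' Sample mean and standard deviation of detected soma areas, with a
#' one-sample Kolmogorov-Smirnov check of the normality assumption behind
#' the 3-sigma rule. A rejected KS test (p < 0.05) produces a warning but
#' does not abort: the criterion is still applied.
#'
#' @param areas numeric vector of soma areas in px^2, length >= 3.
#' @return Object of class `area_model`: `mu`, `sigma`, `ks_stat`, `ks_p`.
#' @export
fit_area_model <- function(areas) {
  if (length(areas) < 3)
    stop("at least 3 soma areas are needed to fit the area model; ",
         "supply area_mu and area_sigma in the config instead")
  mu <- mean(areas)
  sigma <- stats::sd(areas)
  if (sigma == 0) stop("degenerate area model: all areas are equal")
  ks <- suppressWarnings(stats::ks.test(areas, "pnorm", mu, sigma))
  if (ks$p.value < 0.05)
    warning("soma areas deviate from normality (KS p = ",
            signif(ks$p.value, 3), "); the 3-sigma rule may be unreliable")
  structure(list(mu = mu, sigma = sigma,
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value),
            class = "area_model")
}

#' Flag regions whose area indicates multiple somas (3-sigma rule)
#'
#' A detected area compatible with `N` somas satisfies
#' `|area - N * mu| <= 3 * sigma`; the smallest such `N` is reported. If no
#' `N` is admissible the closest multiple is chosen, but an over-sized
#' region (`area > mu + 3 sigma`) is never assigned fewer than two somas.
#'
#' @param records data frame with at least `id` and `area` columns.
#' @param model an [fit_area_model()] object (or list with `mu`, `sigma`).
#' @return The records with columns `n_somas` (estimated count) and
#'   `flagged` (`n_somas > 1`) appended.
#' @export
flag_multi_soma_regions <- function(records, model) {
  stopifnot(!is.null(model$mu), !is.null(model$sigma), model$sigma > 0)
  n_est <- vapply(records$area, function(a)
    estimate_soma_count(a, model$mu, model$sigma), integer(1))
  records$n_somas <- n_est
  records$flagged <- n_est > 1L
  records
}

estimate_soma_count <- function(area, mu, sigma) {
  n_max <- max(1L, as.integer(ceiling(area / mu)) + 1L)
  adm <- which(abs(area - seq_len(n_max) * mu) <= 3 * sigma)
  if (length(adm)) return(as.integer(min(adm)))
  n_best <- which.min(abs(area - seq_len(n_max) * mu))
  if (area > mu + 3 * sigma) n_best <- max(n_best, 2L)
  as.integer(n_best)
}

#' Separate a clustered-soma region at the coarser directional scale
#'
#' Recomputes the Directional Ratio inside the flagged region with the
#' coarse (40 px, about one soma diameter) directional filters, extracts
#' new seed regions, and evolves level-set fronts that freeze on contact.
#' At the coarse scale the printed seed threshold 0.9 sits exactly at the
#' chord-to-filter-length ratio of a nominal soma, so when fewer seeds than
#' the expected `n_target` appear the threshold is relaxed in steps of 0.02
#' (down to `threshold_floor`) until the expected number emerges; the
#' `n_target` largest seed components are kept. If no more than one seed
#' can be found the region is returned unsplit with a warning.
#'
#' @param region logical matrix: the flagged region.
#' @param n_target expected number of somas in the region (from the
#'   3-sigma rule), >= 2.
#' @param system_coarse a [build_system_2d()] with the coarse filter
#'   length.
#' @param config a [somatect_config()] list.
#' @return Integer label matrix over the region with values `1..n` (`n >=
#'   1`), partitioning the region.
#' @export
separate_clustered <- function(region, n_target, system_coarse,
                               config = somatect_config(),
                               min_part_area = NULL) {
  stopifnot(n_target >= 2)
  if (is.null(min_part_area)) min_part_area <- 0.5 * config$area_mu
  dr <- compute_directional_ratio(region, system_coarse)
  seeds <- NULL
  thr_seq <- seq(config$dr_threshold, config$separation_threshold_floor,
                 by = -0.02)
  for (thr in thr_seq) {
    s <- extract_seed_regions(dr, thr, config$seed_min_area)
    if (max(s) >= n_target) { seeds <- s; break }
    if (max(s) >= 2 && thr == thr_seq[length(thr_seq)]) seeds <- s
  }
  if (is.null(seeds)) {
    warning("coarse-scale Directional Ratio yields a single seed; ",
            "region returned unsplit")
    return(matrix(as.integer(region), nrow(region), ncol(region)))
  }
  sizes <- tabulate(seeds[seeds > 0])
  keep <- sort(order(sizes, decreasing = TRUE)[seq_len(min(n_target,
                                                           length(sizes)))])
  relab <- matrix(0L, nrow(region), ncol(region))
  for (i in seq_along(keep)) relab[seeds == keep[i]] <- i
  sp <- build_speed_field(dr, region)
  lab <- evolve_fronts(relab, sp, region, config$evolve)
  ## hand any pixels the decelerating fronts left over to the nearest front
  if (any(region & lab == 0)) {
    u <- matrix(1, nrow(region), ncol(region)) * region
    lab <- evolve_fronts(lab, u, region,
                         list(tol = 0, window = 10L, max_iter = 100000L))
    lab[region & lab == 0] <- 0L
  }
  ## parts far below a plausible soma area are absorption artifacts
  ## (seeds raised in leaked or neck pixels): merge them into the
  ## neighboring part that reaches them first
  repeat {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes > 0 & sizes < min_part_area)
    if (!length(small) || length(sizes[sizes > 0]) <= 1) break
    drop_id <- small[which.min(sizes[small])]
    lab[lab == drop_id] <- 0L
    u <- matrix(1, nrow(region), ncol(region)) * region
    lab <- evolve_fronts(lab, u, region,
                         list(tol = 0, window = 10L, max_iter = 100000L))
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  relab2 <- matrix(0L, nrow(region), ncol(region))
  for (i in seq_along(ids)) relab2[lab == ids[i]] <- i
  relab2
}

## per-label morphological cleanup: remove thin leakages into neurites by
## opening with a disc smaller than a soma but wider than a neurite, then
## keep the component(s) holding that label's seed pixels
cleanup_labels <- function(lab, seeds, open_radius) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (open_radius < 1) return(lab)
  kern <- EBImage::makeBrush(2 * open_radius + 1, "disc")
  for (k in setdiff(sort(unique(as.vector(lab))), 0L)) {
    m <- lab == k
    mo <- EBImage::opening(m * 1, kern) > 0
    cc <- EBImage::bwlabel(mo * 1)
    ids <- setdiff(unique(cc[seeds == k]), 0)
    if (!length(ids)) {
      sizes <- tabulate(cc[cc > 0])
      if (!length(sizes)) next
      ids <- which.max(sizes)
    }
    out[cc %in% ids] <- k
  }
  out
}

soma_records_from_labels <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(ids))
    return(data.frame(id = integer(0), area = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      split_from_cluster = logical(0)))
  rows <- lapply(ids, function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    data.frame(id = k, area = nrow(px),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
               split_from_cluster = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect somas in a 2D image or a projected stack
#'
#' The complete automated 2D pipeline: z-projection (for stack input),
#' shearlet shrinkage denoising, neuron/background segmentation (the
#' trained SVM from `config$segmenter` when available, otherwise Otsu
#' thresholding), Directional Ratio at the fine 20 px filter length, seed
#' extraction at threshold 0.9, level-set completion with per-label
#' cleanup, area-model fitting, the 3-sigma multi-soma criterion, and
#' coarse-scale (40 px) separation of flagged regions.
#'
#' The area model is fitted from the image's own detections when at least
#' three are available (a robust median/MAD first pass flags outliers, then
#' mean/SD are refitted on the unflagged areas); otherwise the configured
#' `area_mu`/`area_sigma` are used.
#'
#' @param x numeric matrix, or 3D array (projected with
#'   `config$projection`).
#' @param config a [somatect_config()] list.
#' @return Object of class `soma_detection`: list with `records` (data
#'   frame: id, area, centroid, n_somas, flagged, split_from_cluster),
#'   `labels` (integer matrix), `mask` (segmentation), `area_model`.
#' @export
detect_somas_2d <- function(x, config = somatect_config()) {
  img <- if (length(dim(x)) == 3) project_stack(x, config$projection) else x
  stopifnot(is.matrix(img))
  shape <- dim(img)
  sys_fine <- build_system_2d(shape, n_scales = config$n_scales,
                              shears_per_scale = config$n_orientations,
                              filter_length = config$filter_length_fine)
  den <- if (isTRUE(config$denoise))
    shrink_denoise(img, sys_fine, list(k = config$shrinkage_k)) else img
  mask <- if (!is.null(config$segmenter)) {
    segment_image(den, config$segmenter)
  } else {
    thr <- EBImage::otsu(normalize01(den))
    m <- normalize01(den) > thr
    if (any(m)) keep_components(EBImage::bwlabel(m * 1),
                                config$min_component_area) > 0 else m
  }
  empty <- list(records = soma_records_from_labels(matrix(0L, 1, 1))[0, ],
                labels = matrix(0L, shape[1], shape[2]),
                mask = mask, area_model = NULL)
  class(empty) <- "soma_detection"
  if (!any(mask)) {
    warning("segmentation is empty; no somas detected")
    return(empty)
  }
  dr <- compute_directional_ratio(mask, sys_fine)
  seeds <- extract_seed_regions(dr, config$dr_threshold,
                                config$seed_min_area)
  if (max(seeds) == 0) {
    warning("no seed regions above the Directional Ratio threshold")
    return(empty)
  }
  sp <- build_speed_field(dr, mask)
  lab <- evolve_fronts(seeds, sp, mask, config$evolve)
  lab <- cleanup_labels(lab, seeds, config$open_radius)
  records <- soma_records_from_labels(lab)

  ## area model: robust first pass, refit on unflagged detections
  amodel <- area_model_for(records$area, config)
  records <- flag_multi_soma_regions(records, amodel)

  sys_coarse <- NULL
  out_lab <- matrix(0L, shape[1], shape[2])
  out_id <- 0L
  final <- list()
  for (r in seq_len(nrow(records))) {
    k <- records$id[r]
    if (!records$flagged[r]) {
      out_id <- out_id + 1L
      out_lab[lab == k] <- out_id
      final[[length(final) + 1]] <-
        data.frame(id = out_id, n_somas = 1L, split_from_cluster = FALSE)
      next
    }
    if (is.null(sys_coarse))
      sys_coarse <- build_system_2d(shape, n_scales = config$n_scales,
                                    shears_per_scale = config$n_orientations,
                                    filter_length = config$filter_length_coarse)
    parts <- separate_clustered(lab == k, records$n_somas[r], sys_coarse,
                                config, min_part_area = 0.5 * amodel$mu)
    npart <- max(parts)
    for (p in seq_len(npart)) {
      out_id <- out_id + 1L
      out_lab[parts == p] <- out_id
      final[[length(final) + 1]] <-
        data.frame(id = out_id, n_somas = 1L,
                   split_from_cluster = npart > 1L)
    }
  }
  records <- soma_records_from_labels(out_lab)
  meta <- do.call(rbind, final)
  records$split_from_cluster <- meta$split_from_cluster[match(records$id,
                                                              meta$id)]
  structure(list(records = records, labels = out_lab, mask = mask,
                 area_model = amodel),
            class = "soma_detection")
}

## The configured nominal soma-area model (mu, sigma) does a first flagging
## pass; when at least three detections look like single somas under it,
## the model is refitted on those unflagged areas (with a relative floor on
## sigma so that tiny homogeneous samples do not trigger spurious flags).
area_model_for <- function(areas, config) {
  prior <- structure(list(mu = config$area_mu, sigma = config$area_sigma,
                          ks_stat = NA_real_, ks_p = NA_real_),
                     class = "area_model")
  if (length(areas) >= 3) {
    single <- vapply(areas, function(a)
      estimate_soma_count(a, prior$mu, prior$sigma) == 1L, logical(1))
    if (sum(single) >= 3) {
      m <- try(suppressWarnings(fit_area_model(areas[single])),
               silent = TRUE)
      if (!inherits(m, "try-error")) {
        m$sigma <- max(m$sigma, 0.08 * m$mu)
        return(m)
      }
    }
  }
  prior
}

normalize01 <- function(x) {
  rg <- range(x)
  if (rg[2] > rg[1]) (x - rg[1]) / (rg[2] - rg[1]) else x * 0
}

#' @export
print.soma_detection <- function(x, ...) {
  cat("soma detection:", nrow(x$records), "soma(s)\n")
  if (nrow(x$records)) print(x$records)
  invisible(x)
}
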