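## Synthetic neuron phantoms with exact ground truth.
##
## Somas are rendered as bright ellipses (2D) or ellipsoids (3D) of roughly
## 40 px diameter, neurites as constant-width stadium tubes along polylines,
## mirroring the appearance of MAP2-stained cultures: blob-like cell bodies
## connected to thin elongated processes. Truth labels are computed from the
## noiseless geometry and never altered by noise.

#' Specify a synthetic neuron phantom
#'
#' @param image_shape integer dims, length 2 (`c(nrow, ncol)`) or 3
#'   (`c(nrow, ncol, nslice)`; slice 1 is the top of the stack, nearest the
#'   light source).
#' @param somas list; each element a list with `center` (px), `semi_axes`
#'   (px, same length as `image_shape`) and optional `intensity` (default 1).
#' @param neurites list; each element a list with `path` (matrix of polyline
#'   vertices, one row per vertex), `width` (px) and optional `intensity`
#'   (default 0.6).
#' @param background_level baseline intensity (default 0.05).
#' @param photon_scale Poisson scaling factor; `NULL` disables noise. Larger
#'   values mean more photons, hence less noise.
#' @param z_attenuation per-slice multiplicative decay in (0, 1]; models the
#'   contrast loss toward the bottom of a confocal stack.
#' @param seed RNG seed for the noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape, somas = list(), neurites = list(),
                         background_level = 0.05, photon_scale = NULL,
                         z_attenuation = 1, seed = NULL) {
  nd <- length(image_shape)
  stopifnot(nd %in% c(2L, 3L), all(image_shape >= 4))
  stopifnot(z_attenuation > 0, z_attenuation <= 1, background_level >= 0)
  for (s in somas) {
    stopifnot(length(s$center) == nd, length(s$semi_axes) == nd,
              all(s$semi_axes > 0))
    if (any(s$center - s$semi_axes < 1) ||
        any(s$center + s$semi_axes > image_shape))
      stop("soma geometry extends outside image bounds")
  }
  for (p in neurites) {
    path <- rbind(p$path)
    stopifnot(ncol(path) == nd, nrow(path) >= 2, p$width > 0)
    if (any(t(path) - p$width / 2 < 1) ||
        any(t(path) + p$width / 2 > image_shape))
      stop("neurite geometry extends outside image bounds")
  }
  structure(list(image_shape = as.integer(image_shape), somas = somas,
                 neurites = neurites, background_level = background_level,
                 photon_scale = photon_scale, z_attenuation = z_attenuation,
                 seed = seed),
            class = "phantom_spec")
}

## evaluate an expression with a temporary, restored RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## coordinate grids as n x d matrix-free helpers
grid_coords_2d <- function(shape) {
  list(Y = matrix(seq_len(shape[1]), shape[1], shape[2]),
       X = matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE))
}

## squared normalized ellipse/ellipsoid distance of every pixel/voxel
ellipse_q_2d <- function(shape, center, semi) {
  g <- grid_coords_2d(shape)
  ((g$Y - center[1]) / semi[1])^2 + ((g$X - center[2]) / semi[2])^2
}

## minimum distance from each 2D pixel to a polyline (stadium tube support)
polyline_dist_2d <- function(shape, path) {
  g <- grid_coords_2d(shape)
  d2 <- matrix(Inf, shape[1], shape[2])
  for (k in seq_len(nrow(path) - 1)) {
    a <- path[k, ]; b <- path[k + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    py <- g$Y - a[1]; px <- g$X - a[2]
    t <- if (L2 > 0) pmin(pmax((py * ab[1] + px * ab[2]) / L2, 0), 1) else 0
    d2 <- pmin(d2, (py - t * ab[1])^2 + (px - t * ab[2])^2)
  }
  sqrt(d2)
}

#' Generate a 2D neuron phantom with exact ground truth
#'
#' Renders the noiseless geometry (ellipse somas over stadium-tube
#' neurites over a constant background), derives exact truth masks, then
#' applies Poisson noise if `photon_scale` is set. Pixels inside several
#' overlapping somas are labeled by the soma whose normalized ellipse
#' distance is smallest (ties to the lower id), so overlapping somas keep
#' distinct labels.
#'
#' @param spec a [phantom_spec()] with 2D `image_shape`.
#' @return list with `image` (numeric matrix), and `truth`: `soma_labels`
#'   (integer matrix, 0 = background), `neurite_mask` (logical matrix).
#' @export
generate_neuron_image_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$image_shape) == 2)
  shape <- spec$image_shape
  img <- matrix(spec$background_level, shape[1], shape[2])
  neurite_mask <- matrix(FALSE, shape[1], shape[2])
  for (p in spec$neurites) {
    tube <- polyline_dist_2d(shape, rbind(p$path)) <= p$width / 2
    inten <- if (is.null(p$intensity)) 0.6 else p$intensity
    img[tube] <- pmax(img[tube], inten)
    neurite_mask <- neurite_mask | tube
  }
  labels <- matrix(0L, shape[1], shape[2])
  bestq <- matrix(Inf, shape[1], shape[2])
  for (i in seq_along(spec$somas)) {
    s <- spec$somas[[i]]
    q <- ellipse_q_2d(shape, s$center, s$semi_axes)
    inside <- q <= 1
    claim <- inside & q < bestq
    labels[claim] <- i
    bestq[claim] <- q[claim]
    inten <- if (is.null(s$intensity)) 1 else s$intensity
    img[inside] <- pmax(img[inside], inten)
  }
  if (!is.null(spec$photon_scale))
    img <- apply_noise_and_attenuation(img, spec$photon_scale, 1, spec$seed)
  list(image = img,
       truth = list(soma_labels = labels, neurite_mask = neurite_mask))
}

#' Generate a thin 3D neuron stack phantom with exact ground truth
#'
#' Somas are ellipsoids, neurites stadium tubes along 3D polylines. Depth
#' attenuation multiplies slice `z` (1 = top) by `z_attenuation^(z-1)`
#' before Poisson noise is applied, so the per-slice mean of the noiseless
#' render is non-increasing with depth whenever `z_attenuation < 1`.
#'
#' @param spec a [phantom_spec()] with a thin 3D `image_shape` (at most 40
#'   slices by default conventions of this package).
#' @return list with `stack` (3D array) and `truth`: `soma_labels` (integer
#'   3D array), `neurite_mask`, and `surface_voxels` (list, per soma, of
#'   integer n x 3 matrices of boundary voxel indices `(row, col, slice)`).
#' @export
generate_neuron_stack_3d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$image_shape) == 3)
  shape <- spec$image_shape
  arr <- array(spec$background_level, shape)
  labels <- array(0L, shape)
  bestq <- array(Inf, shape)
  neurite_mask <- array(FALSE, shape)
  for (p in spec$neurites) {
    tube <- polyline_tube_3d(shape, rbind(p$path), p$width)
    inten <- if (is.null(p$intensity)) 0.6 else p$intensity
    arr[tube] <- pmax(arr[tube], inten)
    neurite_mask <- neurite_mask | tube
  }
  for (i in seq_along(spec$somas)) {
    s <- spec$somas[[i]]
    q <- ellipsoid_q_3d(shape, s$center, s$semi_axes)
    inside <- q <= 1
    claim <- inside & q < bestq
    labels[claim] <- i
    bestq[claim] <- q[claim]
    inten <- if (is.null(s$intensity)) 1 else s$intensity
    arr[inside] <- pmax(arr[inside], inten)
  }
  surface <- lapply(seq_along(spec$somas), function(i)
    boundary_voxels(labels == i))
  if (spec$z_attenuation < 1 || !is.null(spec$photon_scale))
    arr <- apply_noise_and_attenuation(arr,
                                       photon_scale = spec$photon_scale,
                                       z_attenuation = spec$z_attenuation,
                                       seed = spec$seed)
  list(stack = arr,
       truth = list(soma_labels = labels, neurite_mask = neurite_mask,
                    surface_voxels = surface))
}

ellipsoid_q_3d <- function(shape, center, semi) {
  yy <- (seq_len(shape[1]) - center[1]) / semi[1]
  xx <- (seq_len(shape[2]) - center[2]) / semi[2]
  zz <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(yy^2, xx^2, `+`), zz^2, `+`)
}

polyline_tube_3d <- function(shape, path, width) {
  ## evaluate only within the tube's bounding box to stay cheap
  lo <- pmax(floor(apply(path, 2, min) - width / 2), 1)
  hi <- pmin(ceiling(apply(path, 2, max) + width / 2), shape)
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  G <- as.matrix(expand.grid(y = ys, x = xs, z = zs))
  d2 <- rep(Inf, nrow(G))
  for (k in seq_len(nrow(path) - 1)) {
    a <- path[k, ]; b <- path[k + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    rel <- sweep(G, 2, a)
    t <- if (L2 > 0) pmin(pmax(drop(rel %*% ab) / L2, 0), 1) else 0
    d2 <- pmin(d2, rowSums((rel - outer(t, ab))^2))
  }
  tube <- array(FALSE, shape)
  sel <- d2 <= (width / 2)^2
  tube[G[sel, , drop = FALSE]] <- TRUE
  tube
}

## voxels of a binary 3D region with at least one 6-neighbor outside
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift_and <- function(m, dy, dx, dz) {
    out <- array(FALSE, d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
    sy <- ys + dy; sx <- xs + dx; sz <- zs + dz
    ok_y <- sy >= 1 & sy <= d[1]; ok_x <- sx >= 1 & sx <= d[2]
    ok_z <- sz >= 1 & sz <= d[3]
    out[ys[ok_y], xs[ok_x], zs[ok_z]] <-
      m[sy[ok_y], sx[ok_x], sz[ok_z], drop = FALSE]
    out
  }
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_and(mask, s[1], s[2], s[3])
  which(mask & !interior, arr.ind = TRUE)
}

#' Binary ellipsoid test volume with optional Gaussian smoothing
#'
#' The reference object used to validate surface detection: a centered
#' binary ellipsoid, optionally convolved with an isotropic Gaussian. The
#' returned `surface_voxels` are the discrete boundary of the *unsmoothed*
#' ellipsoid (interior voxels with a 6-neighbor outside), which serve as the
#' analytic truth surface for Pratt figure-of-merit scoring.
#'
#' @param semi_axes length-3 positive vector (px).
#' @param image_shape length-3 dims; the ellipsoid is centered.
#' @param smoothing_sigma Gaussian standard deviation in voxels; 0 disables.
#' @return list with `stack` (values in `[0, 1]`) and `surface_voxels`
#'   (integer n x 3 matrix).
#' @export
generate_ellipsoid_phantom <- function(semi_axes, image_shape,
                                       smoothing_sigma = 0) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            length(image_shape) == 3)
  center <- (image_shape + 1) / 2
  if (any(center - semi_axes < 1) || any(center + semi_axes > image_shape))
    stop("ellipsoid does not fit in the volume")
  mask <- ellipsoid_q_3d(image_shape, center, semi_axes) <= 1
  surf <- boundary_voxels(mask)
  vol <- mask * 1
  if (smoothing_sigma > 0) {
    vol <- gaussian_smooth_3d(vol, smoothing_sigma)
    vol <- pmin(pmax(vol, 0), 1)  # clip FFT round-off
  }
  list(stack = vol, surface_voxels = surf)
}

## separable periodic Gaussian smoothing of a 3D array via FFT
gaussian_smooth_3d <- function(arr, sigma, kernel_size = NULL) {
  d <- dim(arr)
  k1 <- function(n) {
    if (is.null(kernel_size)) {
      off <- seq(-ceiling(4 * sigma), ceiling(4 * sigma))
    } else {
      h <- (kernel_size - 1) / 2
      off <- seq(-h, h)
    }
    w <- exp(-off^2 / (2 * sigma^2))
    w <- w / sum(w)
    k <- numeric(n)
    k[(off %% n) + 1] <- k[(off %% n) + 1] + w
    k
  }
  K <- outer(outer(stats::fft(k1(d[1])), stats::fft(k1(d[2]))),
             stats::fft(k1(d[3])))
  Re(stats::fft(stats::fft(arr) * K, inverse = TRUE)) / prod(d)
}

#' Apply depth attenuation and Poisson photon noise to a stack
#'
#' Slice `z` (1 = top) is multiplied by `z_attenuation^(z-1)`; each voxel
#' `v` is then replaced by `rpois(photon_scale * v) / photon_scale`,
#' emulating photon-counting noise whose relative strength decreases as
#' `photon_scale` grows. Deterministic under a fixed `seed` (the global RNG
#' state is restored afterwards).
#'
#' @param stack numeric array (2D or 3D), nonnegative.
#' @param photon_scale positive scalar, or `NULL` to skip the Poisson step.
#' @param z_attenuation per-slice decay factor in (0, 1].
#' @param seed RNG seed.
#' @return Array of the same shape.
#' @export
apply_noise_and_attenuation <- function(stack, photon_scale = NULL,
                                        z_attenuation = 1, seed = NULL) {
  if (any(stack < 0)) stop("input intensities must be nonnegative")
  stopifnot(z_attenuation > 0, z_attenuation <= 1)
  d <- dim(stack)
  if (z_attenuation < 1 && length(d) == 3) {
    fac <- z_attenuation^(seq_len(d[3]) - 1)
    stack <- sweep(stack, 3, fac, `*`)
  }
  if (!is.null(photon_scale)) {
    stopifnot(photon_scale > 0)
    stack <- with_seed(seed, {
      noisy <- stats::rpois(length(stack), photon_scale * as.vector(stack))
      array(noisy / photon_scale, if (is.null(d)) length(stack) else d)
    })
  }
  stack
}

#' Random 2D phantom of a small neuronal culture field
#'
#' Draws a field of `n_somas` round somas (radius about 20 px) with
#' `n_touching_pairs` of them placed as contiguous pairs, each soma sprouting
#' two thin neurites, under the default imaging conditions of this package
#' (Poisson noise at `photon_scale`, faint background). Used as the
#' self-contained benchmark family for the 2D pipeline.
#'
#' @param n_somas total number of somas (including touching pairs).
#' @param n_touching_pairs number of contiguous soma pairs (each pair counts
#'   as two somas).
#' @param image_shape 2D dims (default 256 x 256).
#' @param photon_scale Poisson scale (default 60).
#' @param seed RNG seed; also used for the noise.
#' @return A [phantom_spec()].
#' @export
random_neuron_spec_2d <- function(n_somas, n_touching_pairs = 0,
                                  image_shape = c(256, 256),
                                  photon_scale = 60, seed = 1) {
  stopifnot(n_somas >= 1, 2 * n_touching_pairs <= n_somas)
  with_seed(seed, {
    margin <- 34
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    ## groups: each entry is the center/radius footprint of one placement
    ## unit (a touching pair occupies a slightly larger footprint)
    clear_of_others <- function(cands, rads) {
      if (nrow(centers) == 0) return(TRUE)
      for (q in seq_len(nrow(cands))) {
        dd <- sqrt(rowSums(sweep(centers, 2, cands[q, ])^2))
        if (any(dd < radii + rads[q] + 14)) return(FALSE)
      }
      TRUE
    }
    n_singles <- n_somas - 2 * n_touching_pairs
    for (g in seq_len(n_touching_pairs + n_singles)) {
      is_pair <- g <= n_touching_pairs
      placed <- FALSE
      for (try in 1:3000) {
        r1 <- runif(1, 18, 22)
        c1 <- c(runif(1, margin, image_shape[1] - margin),
                runif(1, margin, image_shape[2] - margin))
        if (is_pair) {
          r2 <- runif(1, 18, 22)
          ang <- runif(1, 0, 2 * pi)
          c2 <- c1 + (r1 + r2 - 3) * c(cos(ang), sin(ang))
          if (any(c2 < margin) || any(c2 > image_shape - margin)) next
          if (!clear_of_others(rbind(c1, c2), c(r1, r2))) next
          centers <- rbind(centers, c1, c2); radii <- c(radii, r1, r2)
        } else {
          if (!clear_of_others(rbind(c1), r1)) next
          centers <- rbind(centers, c1); radii <- c(radii, r1)
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place all somas; enlarge image_shape")
    }
    somas <- lapply(seq_len(nrow(centers)), function(i)
      list(center = centers[i, ], semi_axes = rep(radii[i], 2),
           intensity = 1))
    neurites <- list()
    for (i in seq_len(nrow(centers))) {
      for (rep in 1:2) {
        for (try in 1:200) {
          ang <- runif(1, 0, 2 * pi)
          len <- runif(1, 45, 80)
          a <- centers[i, ] + (radii[i] - 4) * c(cos(ang), sin(ang))
          b <- centers[i, ] + (radii[i] + len) * c(cos(ang), sin(ang))
          if (all(b > 8) && all(b < image_shape - 8)) {
            ## avoid running into another soma
            dd <- sqrt(rowSums(sweep(centers, 2, b)^2))
            if (all(dd[-i] > radii[-i] + 12)) {
              neurites <- c(neurites, list(list(path = rbind(a, b),
                                                width = 6, intensity = 0.55)))
              break
            }
          }
        }
      }
    }
    phantom_spec(image_shape, somas = somas, neurites = neurites,
                 background_level = 0.05, photon_scale = photon_scale,
                 seed = seed + 7919L)
  })
}

#' Random thin-stack 3D phantom of a neuronal culture field
#'
#' Ellipsoidal somas (in-plane radius about 18 px, axial semi-axis about
#' 7 px) centered mid-stack, with in-plane neurites, depth attenuation and
#' Poisson noise — the thin-stack analogue of [random_neuron_spec_2d()].
#'
#' @param n_somas number of somas.
#' @param image_shape 3D dims (default 160 x 160 x 20).
#' @param photon_scale Poisson scale (default 60).
#' @param z_attenuation per-slice decay (default 0.93).
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
random_neuron_spec_3d <- function(n_somas, image_shape = c(160, 160, 20),
                                  photon_scale = 60, z_attenuation = 0.93,
                                  seed = 1) {
  stopifnot(n_somas >= 1, length(image_shape) == 3)
  with_seed(seed, {
    margin <- 30
    nz <- image_shape[3]
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n_somas)) {
      placed <- FALSE
      for (try in 1:3000) {
        r <- runif(1, 16, 20)
        c0 <- c(runif(1, margin, image_shape[1] - margin),
                runif(1, margin, image_shape[2] - margin))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, c0)^2)) > radii + r + 14)) {
          centers <- rbind(centers, c0); radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place all somas; enlarge image_shape")
    }
    rz <- pmin(runif(n_somas, 6, 8), (nz - 4) / 2)
    cz <- round(nz / 2 + runif(n_somas, -1, 1))
    somas <- lapply(seq_len(n_somas), function(i)
      list(center = c(centers[i, ], cz[i]),
           semi_axes = c(radii[i], radii[i], rz[i]), intensity = 1))
    neurites <- list()
    for (i in seq_len(n_somas)) {
      for (try in 1:200) {
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 35, 60)
        a <- c(centers[i, ] + (radii[i] - 4) * c(cos(ang), sin(ang)), cz[i])
        b <- c(centers[i, ] + (radii[i] + len) * c(cos(ang), sin(ang)),
               cz[i])
        if (all(b[1:2] > 8) && all(b[1:2] < image_shape[1:2] - 8)) {
          neurites <- c(neurites, list(list(path = rbind(a, b), width = 5,
                                            intensity = 0.55)))
          break
        }
      }
    }
    phantom_spec(image_shape, somas = somas, neurites = neurites,
                 background_level = 0.05, photon_scale = photon_scale,
                 z_attenuation = z_attenuation, seed = seed + 104729L)
  })
}

#' Write a phantom spec to a YAML file
#'
#' @param spec a [phantom_spec()].
#' @param path output file.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  ser <- list(
    image_shape = as.integer(spec$image_shape),
    somas = lapply(spec$somas, function(s)
      list(center = as.numeric(s$center),
           semi_axes = as.numeric(s$semi_axes),
           intensity = if (is.null(s$intensity)) 1 else s$intensity)),
    neurites = lapply(spec$neurites, function(p)
      list(path = apply(rbind(p$path), 1, as.numeric, simplify = FALSE),
           width = p$width,
           intensity = if (is.null(p$intensity)) 0.6 else p$intensity)),
    background_level = spec$background_level,
    photon_scale = spec$photon_scale,
    z_attenuation = spec$z_attenuation,
    seed = spec$seed)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a phantom spec from a YAML file
#'
#' @param path YAML file written by [write_phantom_spec()].
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  s <- yaml::read_yaml(path)
  phantom_spec(
    image_shape = s$image_shape,
    somas = lapply(s$somas, function(x)
      list(center = x$center, semi_axes = x$semi_axes,
           intensity = x$intensity)),
    neurites = lapply(s$neurites, function(x)
      list(path = do.call(rbind, x$path), width = x$width,
           intensity = x$intensity)),
    background_level = s$background_level,
    photon_scale = s$photon_scale,
    z_attenuation = s$z_attenuation,
    seed = s$seed)
}
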