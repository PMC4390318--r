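#' @useDynLib somatect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mad median sd quantile rnorm rpois runif ks.test
NULL

## ---- small FFT helpers (internal) ----

ifft <- function(X) stats::fft(X, inverse = TRUE) / length(X)
ifft_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

## DFT angular frequencies for length n, in radians, fft ordering
omega_1d <- function(n) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  2 * pi * k[1:n] / n
}

## cubic smoothstep ramp on [lo, hi]
ramp01 <- function(x, lo, hi) {
  t <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  t * t * (3 - 2 * t)
}

## ---- shearlet system construction ----

#' Build a 2D multiscale directional (shearlet-type) system
#'
#' Constructs a tight frame of frequency-domain windows on the given image
#' grid: a Meyer-type radial partition into `n_scales` band-pass annuli plus
#' one low-pass, each annulus split into `shears_per_scale` overlapping
#' angular wedges (raised-cosine, so the squared windows sum to one at every
#' frequency). The system also carries a bank of oriented spatial-domain
#' averaging kernels of prescribed support length `filter_length`, used by
#' [compute_directional_ratio()]: the length of these kernels relative to
#' the soma diameter is what makes the Directional Ratio discriminate
#' blob-like somas from vessel-like neurites.
#'
#' @param image_shape integer vector `c(nrow, ncol)` of the images the
#'   system will analyze.
#' @param n_scales number of band-pass scales (default 3).
#' @param shears_per_scale number of orientations per scale (default 12).
#' @param filter_length support length in pixels of the oriented directional
#'   kernels (default 20; use 40 for the coarser scale that separates
#'   clustered somas).
#' @param dr_filter_width cross-section width in pixels of the oriented
#'   kernels (default 3).
#' @return An object of class `shearlet_system`.
#' @export
build_system_2d <- function(image_shape, n_scales = 3, shears_per_scale = 12,
                            filter_length = 20, dr_filter_width = 3) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            n_scales >= 1, shears_per_scale >= 2)
  if (filter_length > min(image_shape))
    stop("filter_length (", filter_length, ") exceeds the smallest image ",
         "dimension (", min(image_shape), ")")
  nr <- image_shape[1]; nc <- image_shape[2]
  wy <- omega_1d(nr); wx <- omega_1d(nc)
  WX <- matrix(wx, nr, nc, byrow = TRUE)
  WY <- matrix(wy, nr, nc)
  rho <- sqrt(WX^2 + WY^2) / pi           # 0 .. sqrt(2), 1 = Nyquist
  theta <- atan2(WY, WX) %% pi            # orientation, period pi

  ## radial partition: transitions at t_j = 2^{-(J - j)}, j = 1..J
  J <- n_scales
  tj <- 2^(-(J - seq_len(J)))
  t0 <- tj[1] / 2
  edges <- c(t0, tj)
  u <- lapply(seq_len(J), function(j)
    ramp01(rho, edges[j], edges[j + 1]))
  radial <- vector("list", J + 1)
  radial[[1]] <- cos(pi / 2 * u[[1]])     # low-pass
  for (j in seq_len(J)) {
    rj <- sin(pi / 2 * u[[j]])
    if (j < J) rj <- rj * cos(pi / 2 * u[[j + 1]])
    radial[[j + 1]] <- rj                 # band j (j = J reaches the corners)
  }

  ## angular partition with period pi: L wedges of width 2*pi/L, cos profile
  L <- shears_per_scale
  angular <- lapply(seq_len(L), function(l) {
    d <- ((theta - (l - 1) * pi / L + pi / 2) %% pi) - pi / 2
    w <- cos(L * d / 2)
    w[abs(d) > pi / L] <- 0
    w
  })

  windows <- vector("list", 1 + J * L)
  index <- data.frame(scale = 0L, shear = 0L)
  windows[[1]] <- radial[[1]]
  b <- 1L
  for (j in seq_len(J)) for (l in seq_len(L)) {
    b <- b + 1L
    windows[[b]] <- radial[[j + 1]] * angular[[l]]
    index <- rbind(index, data.frame(scale = j, shear = l))
  }

  ## symmetrize under frequency negation (the Nyquist row/column of an
  ## even-sized grid is its own mirror, where the raw angular windows are
  ## not point-symmetric); real symmetric windows keep all bands real
  ri <- c(1, rev(seq_len(nr)[-1])); ci <- c(1, rev(seq_len(nc)[-1]))
  windows <- lapply(windows, function(w) (w + w[ri, ci]) / 2)

  ## enforce exact tight-frame normalization pointwise
  S <- Reduce(`+`, lapply(windows, function(w) w^2))
  S[S <= 0] <- 1
  scl <- 1 / sqrt(S)
  windows <- lapply(windows, function(w) w * scl)

  ## per-band white-noise gain (std of band coefficients for unit-variance
  ## white noise), used by the shrinkage thresholds
  gains <- vapply(windows, function(w) sqrt(mean(w^2)), numeric(1))

  ## oriented directional kernels (frequency domain) for Directional Ratio
  dr_fft <- lapply(seq_len(L), function(l)
    stats::fft(oriented_stick_kernel(image_shape, (l - 1) * pi / L,
                                     filter_length, dr_filter_width)))

  structure(list(
    image_shape = as.integer(image_shape),
    n_scales = as.integer(J),
    shears_per_scale = as.integer(L),
    filter_length = filter_length,
    dr_filter_width = dr_filter_width,
    windows = windows,
    index = index,
    gains = gains,
    dr_fft = dr_fft
  ), class = "shearlet_system")
}

#' @export
print.shearlet_system <- function(x, ...) {
  cat("2D shearlet-type system:", paste(x$image_shape, collapse = " x "),
      "grid,", x$n_scales, "scales x", x$shears_per_scale,
      "orientations, directional filter length", x$filter_length, "px\n")
  invisible(x)
}

## Oriented anti-aliased box kernel of given length/width at angle theta,
## normalized to sum 1, embedded in an image-sized matrix with its center at
## element (1, 1) (wrap-around), ready for circular convolution by FFT.
oriented_stick_kernel <- function(image_shape, theta, len, width) {
  nr <- image_shape[1]; nc <- image_shape[2]
  h <- ceiling(len / 2) + 1
  off <- seq(-h, h)
  X <- matrix(off, 2 * h + 1, 2 * h + 1, byrow = TRUE)  # column offset
  Y <- matrix(off, 2 * h + 1, 2 * h + 1)                # row offset
  ## rows grow downward; use (x, y) with y up so theta is the usual angle
  tt <- X * cos(theta) + Y * sin(theta)
  uu <- -X * sin(theta) + Y * cos(theta)
  val <- pmin(pmax(len / 2 - abs(tt) + 0.5, 0), 1) *
    pmin(pmax(width / 2 - abs(uu) + 0.5, 0), 1)
  val <- val / sum(val)
  K <- matrix(0, nr, nc)
  ii <- (matrix(off, 2 * h + 1, 2 * h + 1) %% nr) + 1
  jj <- (matrix(off, 2 * h + 1, 2 * h + 1, byrow = TRUE) %% nc) + 1
  for (a in seq_along(off)) for (b in seq_along(off)) {
    K[ii[a, b], jj[a, b]] <- K[ii[a, b], jj[a, b]] + val[a, b]
  }
  K
}

## ---- forward / inverse transform ----

#' Forward shearlet transform
#'
#' Maps an image into its band coefficients: for each frequency window the
#' image spectrum is multiplied by the window and returned to the spatial
#' domain, so band `b` at location `k` equals the inner product of the image
#' with the (circularly shifted) analyzing function of that band.
#'
#' @param f numeric matrix, same shape as the system.
#' @param system a [build_system_2d()] object.
#' @return An object of class `shearlet_coeffs`: a list with per-band
#'   coefficient matrices (`bands`), the band `index`, and system metadata.
#' @export
transform_forward <- function(f, system) {
  stopifnot(inherits(system, "shearlet_system"))
  if (!all(dim(f) == system$image_shape))
    stop("image shape ", paste(dim(f), collapse = "x"),
         " does not match system shape ",
         paste(system$image_shape, collapse = "x"))
  Fw <- stats::fft(f)
  bands <- lapply(system$windows, function(w) ifft_real(Fw * w))
  structure(list(bands = bands, index = system$index,
                 image_shape = system$image_shape,
                 n_scales = system$n_scales,
                 shears_per_scale = system$shears_per_scale),
            class = "shearlet_coeffs")
}

#' Inverse shearlet transform
#'
#' Reconstructs the image from its band coefficients. Because the squared
#' frequency windows sum to one (tight frame), `transform_inverse(
#' transform_forward(f, s), s)` recovers `f` up to floating-point error.
#'
#' @param coeffs a `shearlet_coeffs` object.
#' @param system the system that produced the coefficients.
#' @return Numeric matrix.
#' @export
transform_inverse <- function(coeffs, system) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"),
            inherits(system, "shearlet_system"))
  if (!all(coeffs$image_shape == system$image_shape) ||
      coeffs$n_scales != system$n_scales ||
      coeffs$shears_per_scale != system$shears_per_scale ||
      length(coeffs$bands) != length(system$windows))
    stop("coefficients do not match this system")
  acc <- matrix(0 + 0i, system$image_shape[1], system$image_shape[2])
  for (b in seq_along(coeffs$bands))
    acc <- acc + stats::fft(coeffs$bands[[b]]) * system$windows[[b]]
  ifft_real(acc)
}

## ---- shrinkage denoising ----

#' Shearlet shrinkage denoising
#'
#' Soft-thresholds the directional band coefficients with per-band
#' thresholds `k * sigma_hat * g_b`, where `sigma_hat` is a robust noise
#' estimate from the finest-scale coefficients (median absolute deviation,
#' rescaled by each band's white-noise gain `g_b`), then reconstructs by the
#' inverse transform. The low-pass band is never shrunk. Thresholding never
#' increases a coefficient magnitude, and a noiseless image yields near-zero
#' thresholds, so clean data pass through almost unchanged.
#'
#' @param f numeric matrix.
#' @param system a [build_system_2d()] object matching `dim(f)`.
#' @param shrinkage_params list; `k` is the threshold multiplier (default 3).
#' @return Denoised image, same shape as `f`.
#' @export
shrink_denoise <- function(f, system, shrinkage_params = list(k = 3)) {
  stopifnot(all(is.finite(f)))
  k <- if (is.null(shrinkage_params$k)) 3 else shrinkage_params$k
  co <- transform_forward(f, system)
  fine <- which(co$index$scale == system$n_scales)
  sig <- median(vapply(fine, function(b)
    stats::mad(co$bands[[b]], center = 0) / system$gains[b], numeric(1)))
  for (b in seq_along(co$bands)) {
    if (co$index$scale[b] == 0) next
    thr <- k * sig * system$gains[b]
    cb <- co$bands[[b]]
    co$bands[[b]] <- sign(cb) * pmax(abs(cb) - thr, 0)
  }
  transform_inverse(co, system)
}
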