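## Neuron/background segmentation: a binary SVM on per-pixel features built
## from multiscale isotropic Laplacian-of-Gaussian responses plus the raw
## intensity. The isotropic filters make the features self-steerable — the
## response bank commutes exactly with 90-degree rotations on square grids.

#' Multiscale isotropic Laplacian feature bank
#'
#' One scale-normalized Laplacian-of-Gaussian channel per requested scale
#' (computed in the frequency domain, periodic boundaries) plus the raw
#' intensity channel, so `length(scales) + 1` channels in total.
#'
#' @param f numeric matrix.
#' @param scales positive LoG standard deviations in px (default 1, 2, 4, 8).
#' @return Numeric array `nrow x ncol x (length(scales) + 1)` with the
#'   intensity in the last channel; attribute `scales` records the bank.
#' @export
compute_feature_bank <- function(f, scales = c(1, 2, 4, 8)) {
  if (length(scales) == 0) stop("at least one filter scale is required")
  stopifnot(all(scales > 0))
  nr <- nrow(f); nc <- ncol(f)
  wy <- omega_1d(nr); wx <- omega_1d(nc)
  R2 <- outer(wy^2, wx^2, `+`)
  Fw <- stats::fft(f)
  out <- array(0, c(nr, nc, length(scales) + 1))
  for (i in seq_along(scales)) {
    s <- scales[i]
    H <- -s^2 * R2 * exp(-s^2 * R2 / 2)   # scale-normalized isotropic LoG
    out[, , i] <- ifft_real(Fw * H)
  }
  out[, , length(scales) + 1] <- f
  attr(out, "scales") <- scales
  out
}

#' Train the neuron/background pixel classifier
#'
#' Fits a support vector machine (linear kernel by default, class-balanced
#' weights) on a balanced random sample of labeled pixels pooled over the
#' training images. Per-channel z-score statistics are estimated on the
#' training sample and stored in the model, so intensity rescaling between
#' acquisitions is absorbed at prediction time. Training needs to run only
#' once per imaging condition.
#'
#' @param features list of feature arrays from [compute_feature_bank()].
#' @param labels list of binary masks (TRUE/1 = neuron), same shapes.
#' @param params list: `kernel` ("linear"), `cost` (1), `n_samples` pixels
#'   per class per image (2000), `seed` (1), `min_component_area` (20).
#' @return Object of class `segmenter_model`.
#' @export
train_segmenter <- function(features, labels, params = list()) {
  stopifnot(length(features) >= 1, length(features) == length(labels))
  kernel <- params$kernel %||% "linear"
  cost <- params$cost %||% 1
  n_samples <- params$n_samples %||% 2000
  seed <- params$seed %||% 1
  samples <- with_seed(seed, lapply(seq_along(features), function(i) {
    fs <- features[[i]]
    lab <- as.logical(labels[[i]])
    Xi <- matrix(fs, ncol = dim(fs)[3])
    pos <- which(lab); neg <- which(!lab)
    if (length(pos) == 0 || length(neg) == 0)
      stop("training labels must contain both classes")
    pos <- sample(pos, min(n_samples, length(pos)))
    neg <- sample(neg, min(n_samples, length(neg)))
    list(X = Xi[c(pos, neg), , drop = FALSE],
         y = rep(1:0, c(length(pos), length(neg))))
  }))
  X <- do.call(rbind, lapply(samples, `[[`, "X"))
  y <- unlist(lapply(samples, `[[`, "y"))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  yf <- factor(y, levels = c(0, 1), labels = c("background", "neuron"))
  cw <- c(background = 1 / mean(y == 0), neuron = 1 / mean(y == 1))
  fit <- e1071::svm(Xs, yf, kernel = kernel, cost = cost, scale = FALSE,
                    class.weights = cw)
  ## orientation of the decision values w.r.t. the "neuron" class
  dv <- drop(attr(stats::predict(fit, Xs, decision.values = TRUE),
                  "decision.values"))
  sgn <- if (mean(dv[yf == "neuron"]) >= mean(dv[yf == "background"]))
    1 else -1
  w <- if (kernel == "linear") drop(t(fit$coefs) %*% fit$SV) else NULL
  structure(list(fit = fit, center = ctr, scale = scl,
                 scales = attr(features[[1]], "scales"),
                 w = w, rho = fit$rho, sign = sgn, kernel = kernel,
                 min_component_area = params$min_component_area %||% 20),
            class = "segmenter_model")
}

#' Segment neurons from background
#'
#' Applies the trained classifier pixelwise to the feature bank of `f` and
#' removes connected components smaller than the model's minimum area.
#'
#' @param f numeric matrix.
#' @param model a [train_segmenter()] model.
#' @return Logical matrix (TRUE = neuron).
#' @export
segment_image <- function(f, model) {
  if (!inherits(model, "segmenter_model")) stop("untrained or invalid model")
  fs <- compute_feature_bank(f, model$scales)
  X <- scale(matrix(fs, ncol = dim(fs)[3]), model$center, model$scale)
  if (!is.null(model$w)) {
    dec <- model$sign * (X %*% model$w - model$rho)
  } else {
    dec <- model$sign *
      attr(stats::predict(model$fit, X, decision.values = TRUE),
           "decision.values")
  }
  m <- matrix(dec > 0, nrow(f), ncol(f))
  if (any(m)) {
    m <- keep_components(EBImage::bwlabel(m * 1),
                         model$min_component_area) > 0
  }
  m
}
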