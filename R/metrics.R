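## Validation measures: pixel/voxel confusion counts, true-positive rate,
## the soma-normalized false-positive rate FP/(TP+FN) (false detections as a
## fraction of true soma size, since the conventional FP/(TN+FP) is
## vanishingly small on sparse neuronal images), the Dice coefficient, and
## Pratt's figure of merit for edge/surface detection.

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth logical (or 0/1) arrays of identical shape.
#' @return list of class `confusion_counts` with fields `TP`, `FP`, `FN`,
#'   `TN`; the four counts sum to the number of elements compared.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim0(pred) == dim0(truth)))
    stop("pred and truth have different shapes")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

dim0 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Segmentation scores from confusion counts
#'
#' Computes `TPR = TP / (TP + FN)`, the soma-normalized false-positive rate
#' `FPR = FP / (TP + FN)` (which may exceed 1), and the Dice coefficient
#' `DC = 2 TP / (2 TP + FN + FP)`. When both masks are empty the Dice
#' coefficient is defined as 1; TPR and FPR require a nonempty truth.
#'
#' @param c a [confusion_counts()] object or a list with TP/FP/FN fields.
#' @return list with `TPR`, `FPR`, `DC`.
#' @export
segmentation_scores <- function(c) {
  TP <- c$TP; FP <- c$FP; FN <- c$FN
  if (TP + FN == 0) {
    if (FP == 0) return(list(TPR = NA_real_, FPR = NA_real_, DC = 1))
    stop("TPR/FPR are undefined when the truth mask is empty (TP + FN = 0)")
  }
  list(TPR = TP / (TP + FN),
       FPR = FP / (TP + FN),
       DC = 2 * TP / (2 * TP + FN + FP))
}

#' Pratt's figure of merit
#'
#' `FOM = (1 / max(N_I, N_B)) * sum_i 1 / (1 + alpha * d_i^2)`, where the
#' sum runs over the `N_I` detected boundary points, `d_i` is the Euclidean
#' distance from detected point `i` to the nearest of the `N_B` true
#' boundary points, and `alpha` (default 1/9) is the usual calibration
#' constant. Works in any dimension (2D edges, 3D surfaces); equals 1
#' exactly when the detected and true point sets coincide.
#'
#' @param detected integer/numeric matrix, one point per row.
#' @param truth nonempty matrix with the same number of columns.
#' @param alpha calibration constant.
#' @return Scalar in `[0, 1]`.
#' @export
pratt_fom <- function(detected, truth, alpha = 1 / 9) {
  truth <- rbind(truth)
  if (nrow(truth) == 0) stop("truth point set must be nonempty")
  detected <- rbind(detected)
  if (nrow(detected) == 0) return(0)
  if (ncol(detected) != ncol(truth))
    stop("detected and truth have different dimensionality")
  d2 <- nearest_sq_dist(detected, truth)
  sum(1 / (1 + alpha * d2)) / max(nrow(detected), nrow(truth))
}

## squared distance from each row of A to its nearest row of B, chunked to
## bound memory on large surfaces
nearest_sq_dist <- function(A, B, chunk = 512L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    Ab <- A[i:j, , drop = FALSE]
    cross <- Ab %*% t(B)
    d2 <- outer(rowSums(Ab^2), nb2, `+`) - 2 * cross
    out[i:j] <- pmax(apply(d2, 1, min), 0)
    i <- j + 1L
  }
  out
}
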