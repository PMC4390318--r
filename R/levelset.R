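## Level-set completion of soma boundaries. The seed regions found by the
## Directional Ratio lie strictly inside each soma; their boundary curves
## are evolved outward with normal speed v = max(0, M - |grad D|), where D
## is the Directional Ratio map and M the maximum gradient magnitude, so the
## front decelerates where D changes rapidly (the soma boundary and the
## edge of the segmented region) and stalls there. Multiple fronts never
## overlap: each pixel belongs to the front that reaches it first, with
## simultaneous arrivals resolved to the lower label id.
##
## The arrival times solve the eikonal equation |grad T| = 1/v by a
## first-order upwind fast-marching scheme (the monotone-advance form of
## d(phi)/dt = v |grad phi|); the evolution is then stopped at the time
## where the labeled area stagnates, emulating a time-stepped front whose
## CFL-bounded step is dt = 0.5 / max(v).

#' Build the level-set speed field from a Directional Ratio map
#'
#' `v = max(0, M - |grad D|)` inside the mask (central-difference gradient,
#' with D taken as 0 outside the mask) and exactly 0 outside. `M` is the
#' maximum gradient magnitude over the mask. A constant map yields an
#' all-zero field with a warning.
#'
#' @param drmap a [compute_directional_ratio()] result.
#' @param mask logical matrix; defaults to the map's own mask.
#' @return Object of class `speed_field`: list with `values`, `M`, `mask`.
#' @export
build_speed_field <- function(drmap, mask = drmap$mask) {
  stopifnot(inherits(drmap, "dr_map"))
  D <- drmap$values
  D[!mask] <- 0
  g <- central_gradient(D)
  gm <- sqrt(g$gy^2 + g$gx^2)
  M <- max(gm[mask], 0)
  if (M == 0)
    warning("Directional Ratio map is constant on the mask; ",
            "speed field is identically zero")
  v <- pmax(M - gm, 0)
  v[!mask] <- 0
  structure(list(values = v, M = M, mask = mask), class = "speed_field")
}

central_gradient <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  gy <- (D[c(2:nr, nr), ] - D[c(1, 1:(nr - 1)), ]) / 2
  gx <- (D[, c(2:nc, nc)] - D[, c(1, 1:(nc - 1))]) / 2
  list(gy = gy, gx = gx)
}

#' Evolve labeled fronts outward through a speed field
#'
#' Each labeled seed region grows monotonically with the given nonnegative
#' speed, constrained to the mask; fronts freeze where they meet. Arrival
#' times come from the upwind fast-marching solver; the stopping time is the
#' first simulated iteration (time step `dt = 0.5 / max(v)`) at which the
#' relative labeled-area growth over the trailing `window` iterations falls
#' below `tol`, or `max_iter` iterations.
#'
#' @param seeds integer label matrix (0 = background); all seed pixels must
#'   lie inside `mask`.
#' @param speed a [build_speed_field()] object or a numeric matrix.
#' @param mask logical matrix constraining the evolution.
#' @param params list; `tol` (default 1e-3), `window` (default 10),
#'   `max_iter` (default 500).
#' @return Integer label matrix of the final fronts.
#' @export
evolve_fronts <- function(seeds, speed, mask, params = list()) {
  v <- if (inherits(speed, "speed_field")) speed$values else speed
  stopifnot(all(dim(seeds) == dim(v)), all(dim(mask) == dim(v)))
  if (any(seeds > 0 & !mask)) stop("seed pixels must lie inside the mask")
  tol <- params$tol %||% 1e-3
  window <- params$window %||% 10L
  max_iter <- params$max_iter %||% 500L
  v <- v * (mask * 1)
  if (all(v <= 0) || all(seeds == 0)) return(as_integer_labels(seeds))
  res <- .fmm_fronts_cpp(v, as_integer_labels(seeds))
  Tm <- res$arrival; lab <- res$labels
  dt <- 0.5 / max(v)
  ## simulated-iteration stopping on the arrival-time histogram
  tt <- Tm[is.finite(Tm) & lab > 0]
  counts <- cumsum(tabulate(pmin(floor(tt / dt) + 1, max_iter + window),
                            nbins = max_iter + window))
  k_stop <- max_iter
  for (k in seq(window + 1L, max_iter)) {
    a_now <- counts[k]; a_prev <- counts[k - window]
    if (a_now > 0 && (a_now - a_prev) / a_now < tol) { k_stop <- k; break }
  }
  out <- lab
  out[!is.finite(Tm) | Tm > k_stop * dt] <- 0L
  out[seeds > 0] <- as_integer_labels(seeds)[seeds > 0]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_integer_labels <- function(seeds) {
  s <- seeds
  storage.mode(s) <- "integer"
  s
}
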