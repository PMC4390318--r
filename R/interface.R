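## Configuration, TIFF stack I/O and result reports.

#' Default pipeline configuration
#'
#' Every tunable of the 2D and 3D pipelines with its default. Defaults
#' follow the method's standard operating point: Directional Ratio seed
#' threshold 0.9, fine/coarse directional filter lengths 20/40 px, 12
#' orientations, 3-sigma area criterion, 3x3x3 Gaussian stack smoothing
#' with sigma 0.6, Pratt constant alpha = 1/9, and a voxel size of
#' 0.28 x 0.28 x 1 micrometers typical of confocal culture stacks.
#'
#' @param ... named overrides of any default.
#' @return Named list.
#' @export
somatect_config <- function(...) {
  cfg <- list(
    dr_threshold = 0.9,
    filter_length_fine = 20,
    filter_length_coarse = 40,
    n_orientations = 12,
    n_scales = 3,
    seed_min_area = 50,
    min_component_area = 20,
    open_radius = 5,
    area_mu = pi * 20^2,
    area_sigma = 150,
    denoise = TRUE,
    shrinkage_k = 3,
    projection = "MIP",
    segmenter = NULL,
    feature_scales = c(1, 2, 4, 8),
    evolve = list(tol = 1e-3, window = 10L, max_iter = 500L),
    separation_threshold_floor = 0.78,
    smoothing_sigma = 0.6,
    smoothing_kernel = 3,
    deblock_margin = 2,
    equalize_contrast = TRUE,
    equalize_max_gain = 4,
    surface_threshold = 0.1,
    fom_alpha = 1 / 9,
    voxel_size = c(x = 0.28, y = 0.28, z = 1)
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are kept; missing keys fall back to [somatect_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(somatect_config, as.list(over))
}

#' Read a grayscale multi-page TIFF as an image stack
#'
#' @param path file path.
#' @param voxel_size length-3 numeric (micrometers per voxel along x, y, z).
#' @return 3D numeric array with attribute `voxel_size`; a single-page file
#'   yields one slice. Slice 1 is the top of the stack.
#' @export
read_stack <- function(path, voxel_size = c(0.28, 0.28, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3)
    stop("RGB/multi-channel TIFF is not supported; supply grayscale input")
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  attr(arr, "voxel_size") <- voxel_size
  arr
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities in `[0, 1]` are stored as 16-bit grayscale samples (the
#' native bit depth of confocal acquisitions), i.e. on the grid `k / 65535`;
#' values already on that grid round-trip bit-identically through
#' [read_stack()].
#'
#' @param stack 2D matrix or 3D array with values in `[0, 1]`.
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write detection results: 16-bit label TIFF plus JSON report
#'
#' @param labels integer label matrix or 3D array (0 = background, ids
#'   <= 65535).
#' @param records data frame of per-soma records (id, area, centroid, ...).
#' @param label_path,report_path output files; `NULL` skips that output.
#' @param voxel_size micrometers per voxel, used to add physical areas
#'   (`area_um2`) or volumes (`volume_um3`) to the report.
#' @return Invisibly, the report list.
#' @export
write_results <- function(labels, records, label_path = NULL,
                          report_path = NULL,
                          voxel_size = c(0.28, 0.28, 1)) {
  if (!is.null(label_path)) {
    if (max(labels) > 65535) stop("more than 65535 labels")
    write_label_tiff(labels, label_path)
  }
  rep <- list(n_somas = nrow(records),
              voxel_size_um = unname(voxel_size),
              somas = records)
  if (nrow(records) && "area" %in% names(records))
    rep$somas$area_um2 <- records$area * voxel_size[1] * voxel_size[2]
  if (nrow(records) && "volume_voxels" %in% names(records))
    rep$somas$volume_um3 <- records$volume_voxels * prod(voxel_size)
  if (!is.null(report_path))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(rep)
}

write_label_tiff <- function(labels, path) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1))
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(k) labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_results()]
#'
#' @param path file path.
#' @return Integer array of labels.
#' @export
read_label_tiff <- function(path) {
  arr <- read_stack(path)
  storage.mode(arr) <- "double"
  out <- array(as.integer(round(arr * 65535)), dim(arr))
  out
}
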