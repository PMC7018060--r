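#' Total signal index (TSI) of an axial slice
#'
#' The TSI is a subject-size surrogate computed from the scan itself:
#' `(mean FOV HU - air HU) * FOV area (mm^2) / 1e7`. Subtracting the
#' scanner's CT number for air (-1024 here, -1000 on some scanners) makes the
#' index non-negative for any physical slice, and the 1e7 divisor scales a
#' typical small-primate cohort into roughly (0, 10).
#'
#' @param mean_fov_hu mean HU over the field-of-view region.
#' @param fov_area_mm2 area of the FOV region in mm^2 (> 0).
#' @param air_hu scanner HU of air; default -1024.
#' @return TSI, dimensionless. Vectorized over `mean_fov_hu`/`fov_area_mm2`.
#' @export
#' @examples
#' compute_tsi(0, pi * 160^2)      # uniform water-equivalent 320 mm FOV
#' compute_tsi(-1024, pi * 160^2)  # all air -> 0
compute_tsi <- function(mean_fov_hu, fov_area_mm2, air_hu = -1024) {
  if (any(!is.finite(fov_area_mm2)) || any(fov_area_mm2 <= 0))
    stop("'fov_area_mm2' must be > 0", call. = FALSE)
  (mean_fov_hu - air_hu) * fov_area_mm2 / 1e7
}

# Logical mask of the reconstruction circle, centred in the matrix.
fov_mask <- function(dims, spacing, fov_diameter_mm) {
  cx <- (seq_len(dims[1]) - 1L) * spacing[1]
  cy <- (seq_len(dims[2]) - 1L) * spacing[2]
  centre <- c((dims[1] - 1L) * spacing[1] / 2, (dims[2] - 1L) * spacing[2] / 2)
  r2 <- (fov_diameter_mm / 2)^2
  outer(cx, cy, function(x, y) (x - centre[1])^2 + (y - centre[2])^2 <= r2)
}

#' TSI computed directly from a slice raster
#'
#' The FOV region is the reconstruction circle of diameter `fov_diameter_mm`
#' centred in the matrix; voxels outside it contribute to neither the mean HU
#' nor the area. The area is the voxel-counted area of the disc (count times
#' per-voxel area), so raster and analytic TSI agree up to discretization.
#'
#' @param slice 2-D HU matrix.
#' @param spacing in-plane voxel size, mm (length 2 or scalar).
#' @param fov_diameter_mm FOV diameter in mm.
#' @param air_hu scanner HU of air.
#' @return TSI scalar, with attributes `mean_fov_hu` and `fov_area_mm2`.
#' @export
tsi_from_slice <- function(slice, spacing, fov_diameter_mm, air_hu = -1024) {
  stopifnot(is.matrix(slice))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  m <- fov_mask(dim(slice), spacing, fov_diameter_mm)
  if (!any(m)) stop("FOV circle encloses no voxel centres", call. = FALSE)
  mean_hu <- mean(slice[m])
  area <- sum(m) * spacing[1] * spacing[2]
  structure(compute_tsi(mean_hu, area, air_hu),
            mean_fov_hu = mean_hu, fov_area_mm2 = area)
}

#' Tissue cross-sectional area (CSA) of an axial slice
#'
#' Area of x-ray-absorbing material in the slice, in mm^2 — the competing
#' size index. When `roi` is supplied (a hand-traced [ct_roi] polygon or a
#' logical mask) its area is returned directly. Otherwise an automatic
#' segmentation stands in for manual tracing: voxels above `threshold_hu`
#' (default -400 HU) are classified as material, then a morphological closing
#' (disc radius `closing_radius` voxels) and hole filling remove internal air
#' such as bowel gas or lung.
#'
#' @param slice 2-D HU matrix.
#' @param spacing in-plane voxel size, mm (length 2 or scalar).
#' @param threshold_hu HU above which a voxel counts as material.
#' @param closing_radius structuring-element radius in voxels; 0 disables.
#' @param fill_holes fill enclosed background regions.
#' @param roi optional [ct_roi] or logical mask overriding segmentation.
#' @return CSA in mm^2, with attribute `mask` (the material mask used).
#' @export
compute_csa <- function(slice, spacing, threshold_hu = -400,
                        closing_radius = 2, fill_holes = TRUE, roi = NULL) {
  stopifnot(is.matrix(slice))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  vox_area <- spacing[1] * spacing[2]
  if (!is.null(roi)) {
    m <- if (is.logical(roi)) roi else rasterize_roi(roi, dim(slice), spacing)
  } else {
    m <- slice > threshold_hu
    if (closing_radius > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L,
                                  shape = "disc")
      m <- as.array(EBImage::closing(EBImage::Image(m), brush)) > 0
    }
    if (fill_holes)
      m <- as.array(EBImage::fillHull(EBImage::Image(m))) > 0
  }
  structure(sum(m) * vox_area, mask = m)
}

#' Animal-level size index
#'
#' Averages per-slice size indices (typically three axial slices intersecting
#' the renal cortex ROIs) into one animal-level index.
#'
#' @param per_slice numeric vector of per-slice index values.
#' @param kind `"tsi"` or `"csa"` (recorded, not transformed).
#' @return list with `value` (arithmetic mean), `n_slices`, `index_kind`.
#' @export
animal_size_index <- function(per_slice, kind = c("tsi", "csa")) {
  kind <- match.arg(kind)
  per_slice <- as.numeric(per_slice)
  if (length(per_slice) == 0L)
    stop("'per_slice' must contain at least one value", call. = FALSE)
  if (any(!is.finite(per_slice)) || any(per_slice < 0))
    stop("size indices must be finite and non-negative", call. = FALSE)
  list(value = mean(per_slice), n_slices = length(per_slice),
       index_kind = kind)
}
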