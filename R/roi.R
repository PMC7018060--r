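#' Regions of interest on CT slices
#'
#' An ROI set is a list of named regions, each tied to exactly one slice of a
#' volume. Geometry is either a simple polygon (vertices in mm, in the slice
#' plane) or a boolean mask matching the slice raster. Rasterization follows a
#' single documented rule: a voxel belongs to a polygon iff its *centre* is
#' inside under the even-odd rule, so hand counts can replicate the result.
#'
#' Coordinates: slice indices are 0-based; in-plane physical coordinates are
#' mm at voxel centres with the origin at the centre of voxel (0, 0).
#'
#' @param label unique region name (e.g. `"cortex_1"`, `"P1"`, `"FOV"`).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slice 0-based slice index along the plane's normal axis.
#' @param vertices_mm n x 2 matrix of polygon vertices (mm), or `NULL` when a
#'   mask is given.
#' @param mask logical matrix matching the slice raster, or `NULL`.
#' @return A list of class `ct_roi`.
#' @export
ct_roi <- function(label, plane = c("axial", "coronal", "sagittal"),
                   slice, vertices_mm = NULL, mask = NULL) {
  plane <- match.arg(plane)
  stopifnot(is.character(label), length(label) == 1L)
  stop_if_not_scalar_number(slice, "slice")
  if (is.null(vertices_mm) == is.null(mask))
    stop("give exactly one of 'vertices_mm' or 'mask'", call. = FALSE)
  if (!is.null(vertices_mm)) {
    vertices_mm <- as.matrix(vertices_mm)
    if (ncol(vertices_mm) != 2L || nrow(vertices_mm) < 3L)
      stop("'vertices_mm' must be an n x 2 matrix with n >= 3", call. = FALSE)
    if (polygon_self_intersects(vertices_mm))
      stop("polygon for ROI '", label, "' is self-intersecting", call. = FALSE)
  }
  if (!is.null(mask) && !is.logical(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  structure(list(label = label, plane = plane, slice = as.integer(slice),
                 vertices_mm = vertices_mm, mask = mask),
            class = "ct_roi")
}

#' @rdname ct_roi
#' @param ... `ct_roi` objects (or one list of them).
#' @export
roi_set <- function(...) {
  rois <- list(...)
  if (length(rois) == 1L && !inherits(rois[[1]], "ct_roi")) rois <- rois[[1]]
  if (!all(vapply(rois, inherits, TRUE, "ct_roi")))
    stop("all elements must be ct_roi objects", call. = FALSE)
  labels <- vapply(rois, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("ROI labels must be unique within a set", call. = FALSE)
  names(rois) <- labels
  structure(rois, class = "roi_set")
}

# Segment-crossing check over non-adjacent edges; O(n^2), fine for hand-traced
# polygons.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Extract the 2-D raster and in-plane spacing for one ROI's slice.
roi_slice <- function(volume, roi) {
  d <- dim(volume$voxels)
  k <- roi$slice + 1L
  switch(roi$plane,
         axial = {
           if (k < 1L || k > d[3]) stop("slice out of range for ROI '",
                                        roi$label, "'", call. = FALSE)
           list(pix = volume$voxels[, , k], spacing = volume$spacing[1:2])
         },
         coronal = {
           if (k < 1L || k > d[2]) stop("slice out of range for ROI '",
                                        roi$label, "'", call. = FALSE)
           list(pix = volume$voxels[, k, ], spacing = volume$spacing[c(1, 3)])
         },
         sagittal = {
           if (k < 1L || k > d[1]) stop("slice out of range for ROI '",
                                        roi$label, "'", call. = FALSE)
           list(pix = volume$voxels[k, , ], spacing = volume$spacing[2:3])
         })
}

# Logical mask of raster voxels whose centres fall inside the ROI.
rasterize_roi <- function(roi, dims, spacing) {
  if (!is.null(roi$mask)) {
    if (!all(dim(roi$mask) == dims))
      stop("mask dims for ROI '", roi$label, "' do not match the slice",
           call. = FALSE)
    return(roi$mask)
  }
  cx <- (seq_len(dims[1]) - 1L) * spacing[1]
  cy <- (seq_len(dims[2]) - 1L) * spacing[2]
  g <- expand.grid(x = cx, y = cy)
  matrix(points_in_polygon(g$x, g$y, roi$vertices_mm),
         nrow = dims[1], ncol = dims[2])
}

#' Mean HU inside each ROI and across ROIs
#'
#' Computes the arithmetic mean HU of the voxels enclosed by each ROI, and an
#' overall value defined as the unweighted mean of the per-ROI means (the
#' convention used when three hand-traced cortical ROIs are averaged into one
#' kidney-level CT number).
#'
#' @param volume a [ct_volume].
#' @param rois a [roi_set] (or single [ct_roi]).
#' @return A list with `per_roi` (named numeric), `n_voxels` (named integer)
#'   and `mean_of_means`.
#' @export
roi_mean_hu <- function(volume, rois) {
  stopifnot(inherits(volume, "ct_volume"))
  if (inherits(rois, "ct_roi")) rois <- roi_set(rois)
  means <- numeric(length(rois))
  counts <- integer(length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    sl <- roi_slice(volume, roi)
    m <- rasterize_roi(roi, dim(sl$pix), sl$spacing)
    counts[i] <- sum(m)
    if (counts[i] == 0L)
      stop("ROI '", roi$label, "' encloses no voxel centres", call. = FALSE)
    means[i] <- mean(sl$pix[m])
  }
  names(means) <- names(counts) <- names(rois)
  list(per_roi = means, n_voxels = counts, mean_of_means = mean(means))
}

#' Read / write ROI sets as JSON
#'
#' The on-disk schema is a JSON object `{"rois": [...]}` where each entry has
#' `label`, `plane`, `slice` (0-based) and `vertices_mm` (array of `[x, y]`
#' pairs in mm). Mask ROIs are not serialized; they exist only in memory.
#'
#' @param path JSON file path.
#' @return `read_roi_set()`: a [roi_set]; `write_roi_set()`: `path`, invisibly.
#' @export
read_roi_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(seq_len(nrow(doc$rois)), function(i) {
    r <- doc$rois[i, ]
    v <- r$vertices_mm[[1]]
    if (!is.matrix(v)) v <- matrix(unlist(v), ncol = 2, byrow = TRUE)
    ct_roi(r$label, r$plane, r$slice, vertices_mm = v)
  })
  roi_set(rois)
}

#' @rdname read_roi_set
#' @param rois a [roi_set] of polygon ROIs.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  entries <- lapply(rois, function(r) {
    if (is.null(r$vertices_mm))
      stop("mask ROI '", r$label, "' cannot be serialized to JSON",
           call. = FALSE)
    list(label = r$label, plane = r$plane, slice = r$slice,
         vertices_mm = lapply(seq_len(nrow(r$vertices_mm)),
                              function(i) as.numeric(r$vertices_mm[i, ])))
  })
  jsonlite::write_json(list(rois = unname(entries)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
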