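#' Convert an RGB image to HSB on the ImageJ 0-255 scale
#'
#' Masson trichrome renders collagen blue and other tissue pink/red, so
#' fibrosis area is segmented in Hue/Saturation/Brightness colourspace. This
#' is the standard RGB -> HSV conversion with every channel mapped to the
#' 0-255 integer scale used by ImageJ's colour thresholder (hue 0-255 spans
#' 0-360 degrees; pure blue, 240 degrees, lands at 170).
#'
#' @param image `h x w x 3` array; either 0-255 values or `[0, 1]` doubles
#'   (e.g. from [png::readPNG()]), detected from the range.
#' @return `h x w x 3` integer array of H, S, B on 0-255.
#' @export
rgb_to_hsb <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("'image' must be an h x w x 3 RGB array", call. = FALSE)
  mx <- max(image)
  scale <- if (mx <= 1) 255 else 1
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]) * scale,
               as.vector(image[, , 2]) * scale,
               as.vector(image[, , 3]) * scale)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0L, dim = d)
  out[, , 1] <- as.integer(round(hsv[1, ] * 255))
  out[, , 2] <- as.integer(round(hsv[2, ] * 255))
  out[, , 3] <- as.integer(round(hsv[3, ] * 255))
  out
}

#' HSB threshold windows for "blue" (collagen) pixels
#'
#' Each window is `c(lo, hi)` on the 0-255 scale; a pixel is blue when all
#' three channels fall inside their windows. The hue window may wrap
#' (`lo > hi` selects `h >= lo | h <= hi`). The defaults (hue 140-200,
#' saturation >= 60, brightness >= 40) separate trichrome blue from pink
#' tissue (hue near 230-255) and from unstained white space (low
#' saturation); exact thresholds should be tuned on reference swatches for a
#' given stain batch and scanner, and every function accepts overrides.
#'
#' @param hue,saturation,brightness length-2 `c(lo, hi)` windows on 0-255.
#' @return list of class `hsb_thresholds`.
#' @export
hsb_thresholds <- function(hue = c(140, 200), saturation = c(60, 255),
                           brightness = c(40, 255)) {
  for (w in list(saturation, brightness)) {
    if (length(w) != 2L || w[1] > w[2])
      stop("saturation/brightness windows must be c(lo, hi) with lo <= hi",
           call. = FALSE)
  }
  if (length(hue) != 2L) stop("hue window must be length 2", call. = FALSE)
  all_w <- c(hue, saturation, brightness)
  if (any(all_w < 0 | all_w > 255))
    stop("thresholds must lie on the 0-255 scale", call. = FALSE)
  structure(list(hue = hue, saturation = saturation, brightness = brightness),
            class = "hsb_thresholds")
}

in_window <- function(x, w, wrap = FALSE) {
  if (wrap && w[1] > w[2]) x >= w[1] | x <= w[2] else x >= w[1] & x <= w[2]
}

#' Blue-area fraction of a trichrome image
#'
#' Counts pixels passing all three HSB windows and divides by the number of
#' pixels considered (the whole image, or the ROI mask when given). This is
#' the quantitative histological ground truth for fibrosis burden.
#'
#' @param image RGB array (see [rgb_to_hsb()]).
#' @param thresholds an [hsb_thresholds]; default blue window.
#' @param roi optional logical matrix (`h x w`) restricting the measurement.
#' @return fraction in `[0, 1]`, with attribute `n_blue` and `n_total`.
#' @export
blue_area_fraction <- function(image, thresholds = hsb_thresholds(),
                               roi = NULL) {
  stopifnot(inherits(thresholds, "hsb_thresholds"))
  hsb <- rgb_to_hsb(image)
  blue <- in_window(hsb[, , 1], thresholds$hue, wrap = TRUE) &
    in_window(hsb[, , 2], thresholds$saturation) &
    in_window(hsb[, , 3], thresholds$brightness)
  if (!is.null(roi)) {
    if (!is.logical(roi) || !all(dim(roi) == dim(blue)))
      stop("'roi' must be a logical matrix matching the image", call. = FALSE)
    if (!any(roi)) stop("ROI is empty", call. = FALSE)
    n_total <- sum(roi)
    n_blue <- sum(blue & roi)
  } else {
    n_total <- length(blue)
    n_blue <- sum(blue)
  }
  structure(n_blue / n_total, n_blue = n_blue, n_total = n_total)
}

#' Aggregate per-ROI blue fractions into a section-level value
#'
#' The protocol measures three cortical ROIs per section, each twice by a
#' masked reader; the section-level fibrosis area is the arithmetic mean of
#' the six values. Counts are configurable but enforced.
#'
#' @param fractions numeric vector of blue-area fractions, length
#'   `n_rois * n_reads`.
#' @param n_rois,n_reads expected design; defaults 3 and 2.
#' @return list with `section_mean`, `per_measurement`, `n_rois`, `n_reads`.
#' @export
aggregate_fibrosis_area <- function(fractions, n_rois = 3, n_reads = 2) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != n_rois * n_reads)
    stop(sprintf("expected %d values (%d ROIs x %d reads), got %d",
                 n_rois * n_reads, n_rois, n_reads, length(fractions)),
         call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  list(section_mean = mean(fractions), per_measurement = fractions,
       n_rois = n_rois, n_reads = n_reads)
}

#' Semiquantitative fibrosis score and its binarization
#'
#' Sections are scored twice on the 0-4 scale (0 = none, 1 = minimal,
#' 2 = less than half of fields fibrotic, 3 = more than half, 4 = all) and
#' the reads averaged. Fibrosis (the positive class of the diagnostic
#' analyses) is defined as a mean score of 1 or greater.
#'
#' @param reads numeric vector of reads (typically 2), each in `[0, 4]`.
#' @return list with `reads`, `mean_score`, `fibrotic`.
#' @export
semiquant_score <- function(reads) {
  reads <- as.numeric(reads)
  if (length(reads) < 1L || any(!is.finite(reads)) ||
      any(reads < 0 | reads > 4))
    stop("reads must lie in [0, 4]", call. = FALSE)
  m <- mean(reads)
  list(reads = reads, mean_score = m, fibrotic = binarize_fibrosis(m))
}

#' @rdname semiquant_score
#' @param mean_score mean fibrosis score(s) in `[0, 4]`.
#' @return `binarize_fibrosis()`: logical, `TRUE` iff `mean_score >= 1`.
#' @export
binarize_fibrosis <- function(mean_score) {
  if (any(!is.finite(mean_score)) || any(mean_score < 0 | mean_score > 4))
    stop("mean fibrosis score must lie in [0, 4]", call. = FALSE)
  mean_score >= 1
}

#' Read a trichrome image from PNG or TIFF
#'
#' @param path image file path.
#' @return `h x w x 3` array on 0-255.
#' @export
read_trichrome_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB image: ", path, call. = FALSE)
  img * 255
}

#' @rdname read_trichrome_image
#' @param image RGB array (0-255 or [0,1]).
#' @export
write_trichrome_image <- function(image, path) {
  if (max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}
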