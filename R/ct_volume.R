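#' CT volume container
#'
#' A `ct_volume` holds a 3-D array of Hounsfield-unit voxels together with the
#' physical metadata the size-index and ROI machinery needs. Voxel values must
#' already be in HU (any scanner rescale slope/intercept applied); the readers
#' in this package guarantee that.
#'
#' Conventions: the voxel array is indexed `[x, y, z]` with `z` the axial
#' (slice) axis; voxel indices are 0-based in all user-facing slice
#' references; physical coordinates are millimetres at voxel centres, with the
#' origin at the centre of voxel (0, 0) of each plane.
#'
#' @param voxels 3-D numeric array of HU values, dims `(nx, ny, nz)`.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param fov_diameter_mm reconstruction field-of-view diameter in mm (> 0).
#' @param orientation axis convention label; default `"axial"` means the third
#'   array axis is the axial slice axis.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, fov_diameter_mm, orientation = "axial") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)", call. = FALSE)
  stop_if_not_scalar_number(fov_diameter_mm, "fov_diameter_mm", positive = TRUE)
  structure(
    list(voxels = voxels, spacing = spacing,
         fov_diameter_mm = as.numeric(fov_diameter_mm),
         orientation = orientation),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  FOV diameter: %g mm; orientation: %s\n",
              x$fov_diameter_mm, x$orientation))
  cat(sprintf("  HU range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a CT volume from disk
#'
#' Reads either a NIfTI file (`.nii`/`.nii.gz`) or a directory containing one
#' DICOM series (explicit VR little endian). DICOM raw values are mapped to HU
#' with the stored rescale slope and intercept; files missing rescale metadata
#' are rejected, as is a directory mixing slices from more than one series
#' (the error names the offending file). For NIfTI, FOV and orientation
#' metadata are taken from a JSON sidecar (`<file>.json`) written by
#' [write_ct_volume()] when present, otherwise the FOV defaults to the largest
#' in-plane physical extent.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom"`; guessed from `path` by default.
#' @return A [ct_volume].
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else stop("cannot guess format of '", path, "'", call. = FALSE)
  }
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  switch(format,
         nifti = read_ct_nifti(path),
         dicom = read_ct_dicom_series(path))
}

#' Write a CT volume to disk
#'
#' NIfTI output stores spacing in the header and FOV/orientation in a JSON
#' sidecar; DICOM output writes one explicit-VR little-endian file per axial
#' slice with HU encoded through a rescale intercept of -1024.
#'
#' @param volume a [ct_volume].
#' @param path output file (`.nii`/`.nii.gz`) or directory (DICOM).
#' @param format `"nifti"` or `"dicom"`; guessed from `path` by default.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path, format = c("auto", "nifti", "dicom")) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "dicom"
  if (format == "nifti") {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
    jsonlite::write_json(
      list(fov_diameter_mm = volume$fov_diameter_mm,
           orientation = volume$orientation),
      paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write_ct_dicom_series(volume, path)
  }
  invisible(path)
}

read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fov <- meta$fov_diameter_mm
    orientation <- meta$orientation %||% "axial"
  } else {
    fov <- max(dim(vox)[1] * spacing[1], dim(vox)[2] * spacing[2])
    orientation <- "axial"
  }
  ct_volume(vox, spacing, fov, orientation)
}

## ---- minimal DICOM support ------------------------------------------------
## Explicit VR little endian only, covering the CT tags this pipeline needs.
## No R DICOM reader is available as a dependency, so the subset is
## implemented here; the writer emits files the reader (and pydicom) accept.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  n <- length(raw)
  elements <- list()
  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i:(i + 3L)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); data_start <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_start <- pos + 8L
    }
    if (len < 0L) stop("undefined-length element unsupported: ", path)
    bytes <- if (len > 0L) raw[data_start:(data_start + len - 1L)] else raw(0)
    tag <- dcm_tag(group, element)
    elements[[tag]] <- list(vr = vr, bytes = bytes)
    pos <- data_start + len
  }
  elements
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  bytes <- el$bytes[el$bytes != as.raw(0)]  # strip UI null padding
  trimws(rawToChar(bytes))
}

dcm_numeric <- function(el) {
  s <- dcm_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", n = length(el$bytes) / 2L, size = 2,
          endian = "little", signed = FALSE)
}

read_ct_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    el <- read_dicom_file(f)
    uid <- dcm_string(el[[dcm_tag(0x0020, 0x000E)]])
    if (is.null(uid)) stop("missing SeriesInstanceUID in ", f, call. = FALSE)
    slope <- dcm_numeric(el[[dcm_tag(0x0028, 0x1053)]])
    intercept <- dcm_numeric(el[[dcm_tag(0x0028, 0x1052)]])
    if (is.null(slope) || is.null(intercept))
      stop("missing rescale slope/intercept metadata in ", f, call. = FALSE)
    rows <- dcm_uint16(el[[dcm_tag(0x0028, 0x0010)]])
    cols <- dcm_uint16(el[[dcm_tag(0x0028, 0x0011)]])
    pix_rep <- dcm_uint16(el[[dcm_tag(0x0028, 0x0103)]]) %||% 1L
    spacing <- dcm_numeric(el[[dcm_tag(0x0028, 0x0030)]])
    pos <- dcm_numeric(el[[dcm_tag(0x0020, 0x0032)]]) %||% c(0, 0, 0)
    thickness <- dcm_numeric(el[[dcm_tag(0x0018, 0x0050)]]) %||% 1
    fov <- dcm_numeric(el[[dcm_tag(0x0018, 0x1100)]])
    pd <- el[[dcm_tag(0x7FE0, 0x0010)]]
    if (is.null(pd)) stop("missing PixelData in ", f, call. = FALSE)
    stored <- readBin(pd$bytes, "integer", n = length(pd$bytes) / 2L,
                      size = 2, endian = "little", signed = (pix_rep == 1L))
    hu <- slope * stored + intercept
    list(file = f, uid = uid, rows = rows, cols = cols, spacing = spacing,
         z = pos[3], thickness = thickness, fov = fov,
         pixels = matrix(hu, nrow = cols, ncol = rows))
  })
  uids <- vapply(slices, `[[`, "", "uid")
  if (length(unique(uids)) > 1L) {
    ref <- names(which.max(table(uids)))  # majority series
    bad <- slices[[which(uids != ref)[1]]]$file
    stop("directory mixes DICOM series; offending slice: ", bad, call. = FALSE)
  }
  ord <- order(vapply(slices, `[[`, 0, "z"))
  slices <- slices[ord]
  sp_xy <- slices[[1]]$spacing
  zs <- vapply(slices, `[[`, 0, "z")
  dz <- if (length(zs) > 1L) median(diff(zs)) else slices[[1]]$thickness
  vox <- array(NA_real_, dim = c(slices[[1]]$cols, slices[[1]]$rows,
                                 length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$pixels
  fov <- slices[[1]]$fov %||% max(dim(vox)[1] * sp_xy[1], dim(vox)[2] * sp_xy[2])
  ct_volume(vox, c(sp_xy[1], sp_xy[2], dz), fov)
}

dcm_element_bytes <- function(group, element, vr, bytes) {
  if (length(bytes) %% 2L == 1L)
    bytes <- c(bytes, as.raw(if (vr %in% c("UI")) 0L else 0x20))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4, endian = "little"), bytes)
  } else {
    c(head, writeBin(length(bytes), raw(), size = 2, endian = "little"), bytes)
  }
}

dcm_str_element <- function(group, element, vr, value) {
  dcm_element_bytes(group, element, vr, charToRaw(paste(value, collapse = "\\")))
}

write_ct_dicom_series <- function(volume, dir,
                                  series_uid = paste0("1.2.826.0.1.99999.",
                                                      format(Sys.time(), "%Y%m%d%H%M%S")),
                                  intercept = -1024, slope = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$voxels)
  for (k in seq_len(d[3])) {
    hu <- volume$voxels[, , k]
    stored <- as.integer(round((hu - intercept) / slope))
    if (any(stored < -32768 | stored > 32767))
      stop("HU values outside the 16-bit stored range", call. = FALSE)
    body <- c(
      dcm_str_element(0x0008, 0x0060, "CS", "CT"),
      dcm_str_element(0x0018, 0x0050, "DS", format(volume$spacing[3])),
      dcm_str_element(0x0018, 0x1100, "DS", format(volume$fov_diameter_mm)),
      dcm_str_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
      dcm_str_element(0x0020, 0x000E, "UI", series_uid),
      dcm_str_element(0x0020, 0x0032, "DS",
                      c("0", "0", format((k - 1) * volume$spacing[3]))),
      dcm_str_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
      dcm_element_bytes(0x0028, 0x0002, "US",
                        writeBin(1L, raw(), size = 2, endian = "little")),
      dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element_bytes(0x0028, 0x0010, "US",
                        writeBin(d[2], raw(), size = 2, endian = "little")),
      dcm_element_bytes(0x0028, 0x0011, "US",
                        writeBin(d[1], raw(), size = 2, endian = "little")),
      dcm_str_element(0x0028, 0x0030, "DS",
                      format(volume$spacing[1:2])),
      dcm_element_bytes(0x0028, 0x0100, "US",
                        writeBin(16L, raw(), size = 2, endian = "little")),
      dcm_element_bytes(0x0028, 0x0101, "US",
                        writeBin(16L, raw(), size = 2, endian = "little")),
      dcm_element_bytes(0x0028, 0x0102, "US",
                        writeBin(15L, raw(), size = 2, endian = "little")),
      dcm_element_bytes(0x0028, 0x0103, "US",
                        writeBin(1L, raw(), size = 2, endian = "little")),
      dcm_str_element(0x0028, 0x1052, "DS", format(intercept)),
      dcm_str_element(0x0028, 0x1053, "DS", format(slope)),
      dcm_element_bytes(0x7FE0, 0x0010, "OW",
                        writeBin(stored, raw(), size = 2, endian = "little"))
    )
    meta <- c(
      dcm_str_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str_element(0x0002, 0x0003, "UI", sprintf("%s.%d", series_uid, k)),
      dcm_str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
      dcm_str_element(0x0002, 0x0013, "SH", "renalqct")
    )
    meta <- c(dcm_element_bytes(0x0002, 0x0000, "UL",
                                writeBin(length(meta), raw(), size = 4,
                                         endian = "little")),
              meta)
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}
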