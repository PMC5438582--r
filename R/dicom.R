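## Minimal DICOM series I/O (explicit VR little endian, single-frame
## monochrome int16). This covers exactly what the pipeline contract needs:
## Rows/Columns, PixelSpacing, SliceThickness, ImagePositionPatient,
## RescaleSlope/RescaleIntercept and PixelData. Anything else (implicit VR,
## compressed transfer syntaxes, multiframe, colour) is a hard error.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# Parse one explicit-VR dataset from a raw vector starting at byte offset
# `pos` (1-based). Returns a named list tag -> list(vr, bytes).
dcm_parse_elements <- function(bytes, pos, stop_group = NULL) {
  out <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n + 1L && pos <= n - 7L) {
    group <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
    element <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                       signed = FALSE, endian = "little")
    if (!is.null(stop_group) && group != stop_group) break
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?) at tag (",
           dcm_tag(group, element), ")")
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      hdr_len <- 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      hdr_len <- 8L
    }
    if (len < 0L)
      stop("undefined-length DICOM element (", dcm_tag(group, element),
           ") is not supported")
    val_start <- pos + hdr_len
    out[[dcm_tag(group, element)]] <- list(
      vr = vr,
      bytes = if (len > 0L) bytes[val_start:(val_start + len - 1L)] else raw(0)
    )
    pos <- val_start + len
  }
  list(elements = out, pos = pos)
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  sub("[\\s\\0]+$", "", rawToChar(el$bytes), perl = TRUE)
}

dcm_ds <- function(el) {
  s <- dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", n = length(el$bytes) %/% 2L, size = 2L,
          signed = FALSE, endian = "little")
}

# Read one single-frame DICOM file; returns pixel matrix [row, col] in HU
# plus geometry.
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  meta <- dcm_parse_elements(bytes, 133L, stop_group = 2L)
  ts <- dcm_str(meta$elements[["0002,0010"]])
  if (is.null(ts) || ts != DCM_TS_EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax in ", path,
         " (only explicit VR little endian is supported)")
  ds <- dcm_parse_elements(bytes, meta$pos)$elements
  need <- function(tag, what) {
    el <- ds[[tag]]
    if (is.null(el))
      stop("DICOM file ", path, " is missing required tag (", tag, ") ",
           what)
    el
  }
  rows <- dcm_us(need("0028,0010", "Rows"))
  cols <- dcm_us(need("0028,0011", "Columns"))
  pixel_spacing <- dcm_ds(need("0028,0030", "PixelSpacing"))
  slope <- dcm_ds(need("0028,1053", "RescaleSlope"))
  intercept <- dcm_ds(need("0028,1052", "RescaleIntercept"))
  thickness <- dcm_ds(ds[["0018,0050"]])
  ipp <- dcm_ds(ds[["0020,0032"]])
  instance <- suppressWarnings(as.integer(dcm_str(ds[["0020,0013"]])))
  bits <- dcm_us(ds[["0028,0100"]]) %||% 16L
  pixrep <- dcm_us(ds[["0028,0103"]]) %||% 1L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported: ", path)
  px <- need("7FE0,0010", "PixelData")
  raw_vals <- readBin(px$bytes, "integer", n = length(px$bytes) %/% 2L,
                      size = 2L, signed = (pixrep == 1L), endian = "little")
  if (length(raw_vals) != rows * cols)
    stop("PixelData size does not match Rows*Columns in ", path)
  hu <- raw_vals * slope + intercept
  list(
    pixels = t(matrix(hu, nrow = cols, ncol = rows)),  # [row, col]
    rows = rows, cols = cols,
    # PixelSpacing is (row spacing, column spacing) = (dy, dx)
    dy = pixel_spacing[1], dx = pixel_spacing[2],
    thickness = if (is.null(thickness)) NA_real_ else thickness,
    z = if (is.null(ipp)) NA_real_ else ipp[3],
    instance = if (length(instance) && !is.na(instance)) instance else NA_integer_
  )
}

#' Read a DICOM series directory
#'
#' Reads all `.dcm` files in a directory as one axial series. Slices are
#' ordered cranio-caudally (decreasing patient z, falling back to
#' InstanceNumber). Spacing consistency across slices is enforced.
#'
#' @param path Directory containing one DICOM series.
#' @return A list with `data` (3D HU array `[slice, row, col]`) and
#'   `spacing` (`c(dx, dy, dz)` in mm).
#' @keywords internal
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no .dcm files found in ", path)
  slices <- lapply(files, read_dicom_file)
  dxs <- vapply(slices, `[[`, 0, "dx")
  dys <- vapply(slices, `[[`, 0, "dy")
  rws <- vapply(slices, `[[`, 0L, "rows")
  cls <- vapply(slices, `[[`, 0L, "cols")
  if (length(unique(dxs)) != 1L || length(unique(dys)) != 1L ||
      length(unique(rws)) != 1L || length(unique(cls)) != 1L)
    stop("mixed pixel spacing or matrix size across DICOM series in ", path)
  zs <- vapply(slices, `[[`, 0, "z")
  if (all(is.finite(zs)) && length(files) > 1L) {
    ord <- order(zs, decreasing = TRUE)   # cranial first
    dz_all <- abs(diff(sort(zs)))
    if (max(dz_all) - min(dz_all) > 1e-6 * max(dz_all))
      stop("inconsistent slice increment across DICOM series in ", path)
    dz <- dz_all[1]
  } else {
    inst <- vapply(slices, `[[`, 0L, "instance")
    if (any(is.na(inst)))
      stop("DICOM series in ", path,
           " has neither ImagePositionPatient nor InstanceNumber ordering")
    ord <- order(inst)
    dz <- slices[[1]]$thickness
    if (!is.finite(dz))
      stop("DICOM series in ", path, " is missing slice spacing ",
           "(no positions, no (0018,0050) SliceThickness)")
  }
  slices <- slices[ord]
  nz <- length(slices)
  if (nz == 1L) {
    dz <- slices[[1]]$thickness
    if (!is.finite(dz)) stop("single-slice series without SliceThickness")
  }
  vol <- array(NA_real_, dim = c(nz, rws[1], cls[1]))
  for (i in seq_len(nz)) vol[i, , ] <- slices[[i]]$pixels
  list(data = vol, spacing = c(dxs[1], dys[1], dz))
}

#' Write a DICOM series directory
#'
#' Writes a 3D HU array as an explicit-VR little-endian single-frame int16
#' series, one file per axial slice (`slice_###.dcm`), with
#' RescaleIntercept -1024 / RescaleSlope 1.
#'
#' @param vol 3D array `[slice, row, col]` of HU values.
#' @param spacing `c(dx, dy, dz)` mm.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @keywords internal
write_dicom_series <- function(vol, spacing, path) {
  stopifnot(length(dim(vol)) == 3L, length(spacing) == 3L)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol)[1]
  # z decreases with slice index: index 1 is most cranial.
  z0 <- (nz - 1L) * spacing[3]
  for (i in seq_len(nz)) {
    f <- file.path(path, sprintf("slice_%04d.dcm", i))
    write_dicom_slice(vol[i, , ], spacing, z = z0 - (i - 1L) * spacing[3],
                      instance = i, path = f)
  }
  invisible(path)
}

dcm_elem_short <- function(group, element, vr, value_bytes) {
  if (length(value_bytes) %% 2L) value_bytes <- c(value_bytes, as.raw(0L))
  c(writeBin(as.integer(c(group, element)), raw(), size = 2L,
             endian = "little"),
    charToRaw(vr),
    writeBin(length(value_bytes), raw(), size = 2L, endian = "little"),
    value_bytes)
}

dcm_elem_long <- function(group, element, vr, value_bytes) {
  if (length(value_bytes) %% 2L) value_bytes <- c(value_bytes, as.raw(0L))
  c(writeBin(as.integer(c(group, element)), raw(), size = 2L,
             endian = "little"),
    charToRaw(vr), raw(2L),
    writeBin(length(value_bytes), raw(), size = 4L, endian = "little"),
    value_bytes)
}

dcm_str_bytes <- function(x) charToRaw(paste(format(x, trim = TRUE,
                                                    scientific = FALSE),
                                             collapse = "\\"))

write_dicom_slice <- function(pixels, spacing, z, instance, path) {
  intercept <- -1024
  raw_vals <- as.integer(round(pixels - intercept))
  raw_vals <- pmin(pmax(raw_vals, -32768L), 32767L)
  # pixel data is row-major: transpose [row, col] so columns vary fastest
  rv <- matrix(raw_vals, nrow = nrow(pixels))
  px_bytes <- writeBin(as.integer(t(rv)), raw(), size = 2L,
                       endian = "little")
  ds <- c(
    dcm_elem_short(0x0008L, 0x0018L, "UI",
                   charToRaw(paste0("1.2.826.0.1.ctcomp.", instance))),
    dcm_elem_short(0x0018L, 0x0050L, "DS", dcm_str_bytes(spacing[3])),
    dcm_elem_short(0x0020L, 0x0013L, "IS", dcm_str_bytes(instance)),
    dcm_elem_short(0x0020L, 0x0032L, "DS", dcm_str_bytes(c(0, 0, z))),
    dcm_elem_short(0x0020L, 0x0037L, "DS", dcm_str_bytes(c(1, 0, 0, 0, 1, 0))),
    dcm_elem_short(0x0028L, 0x0002L, "US",
                   writeBin(1L, raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0010L, "US",
                   writeBin(nrow(pixels), raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0011L, "US",
                   writeBin(ncol(pixels), raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0030L, "DS",
                   dcm_str_bytes(c(spacing[2], spacing[1]))),
    dcm_elem_short(0x0028L, 0x0100L, "US",
                   writeBin(16L, raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0101L, "US",
                   writeBin(16L, raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0102L, "US",
                   writeBin(15L, raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x0103L, "US",
                   writeBin(1L, raw(), size = 2L, endian = "little")),
    dcm_elem_short(0x0028L, 0x1052L, "DS", dcm_str_bytes(intercept)),
    dcm_elem_short(0x0028L, 0x1053L, "DS", dcm_str_bytes(1)),
    dcm_elem_long(0x7FE0L, 0x0010L, "OW", px_bytes)
  )
  meta_body <- dcm_elem_short(0x0002L, 0x0010L, "UI",
                              charToRaw(DCM_TS_EXPLICIT_LE))
  meta <- c(
    dcm_elem_short(0x0002L, 0x0000L, "UL",
                   writeBin(length(meta_body), raw(), size = 4L,
                            endian = "little")),
    meta_body
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}
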