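# File I/O: raw-float container with text sidecar, 16-bit TIFF, a minimal
# DICOM reader, and sinogram serialization.

header_path <- function(path) paste0(tools::file_path_sans_ext(path), ".hdr")

write_text_header <- function(path, fields) {
  lines <- vapply(names(fields), function(k) {
    sprintf("%s: %s", k, as.character(fields[[k]]))
  }, character(1))
  writeLines(lines, path)
}

read_text_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' Write an image grid to disk
#'
#' Two formats are supported. `"raw"`: pixels as little-endian doubles in
#' column-major order plus a plain-text `.hdr` sidecar carrying the grid
#' metadata (and any provenance fields) -- a lossless round trip. `"tiff"`:
#' 16-bit grayscale TIFF with HU values offset by +1024 and clamped to
#' `[0, 65535]` (so air is 24 and the clinically relevant range survives),
#' plus the same `.hdr` sidecar; quantized to whole HU.
#'
#' @param image an [image_grid()].
#' @param path output file; format inferred from the extension
#'   (`.tif`/`.tiff` vs anything else = raw) unless given explicitly.
#' @param format `"raw"` or `"tiff"`.
#' @param provenance optional named list written into the sidecar header.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL, provenance = NULL) {
  stopifnot(inherits(image, "image_grid"))
  if (is.null(format)) {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  }
  fields <- c(list(type = "image", size = image$size,
                   pixel_spacing = image$pixel_spacing,
                   value_kind = image$value_kind, format = format),
              provenance)
  if (format == "raw") {
    con <- file(path, "wb")
    writeBin(as.vector(image$pixels), con, size = 8, endian = "little")
    close(con)
  } else if (format == "tiff") {
    if (image$value_kind != "HU") {
      stop("write_image: TIFF export is defined for HU images", call. = FALSE)
    }
    stored <- pmin(pmax(round(image$pixels + 1024), 0), 65535)
    tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16)
  } else {
    stop(sprintf("write_image: unknown format '%s'", format), call. = FALSE)
  }
  write_text_header(header_path(path), fields)
  invisible(path)
}

read_raw_image <- function(path, hdr) {
  size <- as.integer(hdr$size)
  con <- file(path, "rb")
  vals <- readBin(con, "double", n = size^2, size = 8, endian = "little")
  close(con)
  image_grid(matrix(vals, size, size), as.numeric(hdr$pixel_spacing),
             value_kind = hdr$value_kind)
}

read_tiff_image <- function(path, pixel_spacing = NULL) {
  hp <- header_path(path)
  if (is.null(pixel_spacing)) {
    if (!file.exists(hp)) {
      stop("read_image: TIFF without sidecar header; supply pixel_spacing",
           call. = FALSE)
    }
    pixel_spacing <- as.numeric(read_text_header(hp)$pixel_spacing)
  }
  stored <- tiff::readTIFF(path) * 65535
  image_grid(round(stored) - 1024, pixel_spacing, value_kind = "HU")
}

#' Read an image grid from disk
#'
#' Dispatches on the file type: the raw+header container round-trips
#' bit-exactly; 16-bit TIFF recovers HU up to the documented +1024-offset
#' quantization; DICOM files (uncompressed, single-frame, little-endian)
#' are read with the rescale slope/intercept applied so the result is in
#' HU, with pixel spacing taken from the DICOM header.
#'
#' @param path input file (`.raw`/`.bin` + `.hdr`, `.tif`/`.tiff`, or
#'   `.dcm`).
#' @param pixel_spacing optional override in mm (required for a TIFF with
#'   no sidecar).
#' @return an [image_grid()].
#' @export
read_image <- function(path, pixel_spacing = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("read_image: no such file '%s'", path), call. = FALSE)
  }
  if (grepl("\\.dcm$|\\.dicom$", path, ignore.case = TRUE)) {
    return(read_dicom(path))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    return(read_tiff_image(path, pixel_spacing))
  }
  hp <- header_path(path)
  if (!file.exists(hp)) {
    stop(sprintf("read_image: missing sidecar header '%s'", hp), call. = FALSE)
  }
  read_raw_image(path, read_text_header(hp))
}

#' Write / read a sinogram in the raw+header container
#'
#' Values are stored as little-endian doubles in ray order
#' (`c = (a-1) * n_detectors + d`) with a text sidecar recording the scan
#' geometry and any provenance fields (seed, config hash).
#'
#' @param sino a [sinogram()].
#' @param path output file (sidecar written next to it).
#' @param provenance optional named list for the sidecar.
#' @return `path` (write) or a [sinogram()] (read).
#' @export
write_sinogram <- function(sino, path, provenance = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  con <- file(path, "wb")
  writeBin(sino_to_vec(sino$values), con, size = 8, endian = "little")
  close(con)
  write_text_header(header_path(path), c(
    list(type = "sinogram", n_angles = g$n_angles,
         n_detectors = g$n_detectors, detector_spacing = g$detector_spacing,
         field_of_view = g$field_of_view),
    provenance))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  hdr <- read_text_header(header_path(path))
  g <- scan_geometry(as.integer(hdr$n_angles), as.integer(hdr$n_detectors),
                     as.numeric(hdr$detector_spacing),
                     as.numeric(hdr$field_of_view))
  con <- file(path, "rb")
  v <- readBin(con, "double", n = g$n_angles * g$n_detectors, size = 8,
               endian = "little")
  close(con)
  sinogram(vec_to_sino(v, g), g)
}

# ---- minimal DICOM reader -------------------------------------------------

dcm_u16 <- function(b) sum(as.integer(b) * c(1L, 256L))
dcm_u32 <- function(b) sum(as.numeric(b) * c(1, 256, 65536, 16777216))

#' Read a basic CT DICOM file
#'
#' A deliberately small reader for uncompressed, single-frame, little-endian
#' (explicit or implicit VR) CT slices: it extracts Rows, Columns,
#' PixelSpacing, BitsAllocated, PixelRepresentation, RescaleSlope/Intercept
#' and PixelData, applies `HU = slope * stored + intercept`, and returns the
#' image in HU. Sequences with undefined length, compressed transfer
#' syntaxes and multi-frame objects are rejected.
#'
#' @param path DICOM file.
#' @return an [image_grid()] in HU.
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
  }
  vrs16 <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
             "PN","SH","SL","SS","ST","TM","UI","UL","US")
  vrs32 <- c("OB","OW","OF","SQ","UT","UN")
  tags <- list()
  while (pos + 7 <= length(raw)) {
    group <- dcm_u16(raw[pos:(pos + 1)])
    elem <- dcm_u16(raw[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    vr <- rawToChar(raw[pos:(pos + 1)])
    if (vr %in% vrs16) {
      len <- dcm_u16(raw[(pos + 2):(pos + 3)])
      pos <- pos + 4L
    } else if (vr %in% vrs32) {
      len <- dcm_u32(raw[(pos + 4):(pos + 7)])
      pos <- pos + 8L
    } else {
      # implicit VR: 4-byte length follows the tag directly
      vr <- NA_character_
      len <- dcm_u32(raw[pos:(pos + 3)])
      pos <- pos + 4L
    }
    if (!is.finite(len) || len == 4294967295) {
      stop("read_dicom: undefined-length elements are not supported",
           call. = FALSE)
    }
    if (pos + len - 1 > length(raw)) {
      stop("read_dicom: truncated file", call. = FALSE)
    }
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- raw[pos:(pos + len - 1)][seq_len(len)]
    pos <- pos + as.integer(len)
    if (key == "7fe00010") break
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) {
      stop(sprintf("read_dicom: missing %s", what), call. = FALSE)
    }
    tags[[key]]
  }
  txt <- function(b) trimws(rawToChar(b))
  rows <- dcm_u16(need("00280010", "Rows"))
  cols <- dcm_u16(need("00280011", "Columns"))
  spacing <- as.numeric(strsplit(txt(need("00280030", "PixelSpacing")),
                                 "\\\\")[[1]])
  bits <- if (!is.null(tags[["00280100"]])) dcm_u16(tags[["00280100"]]) else 16
  if (bits != 16) {
    stop("read_dicom: only 16-bit pixel data is supported", call. = FALSE)
  }
  signed <- !is.null(tags[["00280103"]]) && dcm_u16(tags[["00280103"]]) == 1
  slope <- if (!is.null(tags[["00281053"]])) as.numeric(txt(tags[["00281053"]])) else 1
  intercept <- if (!is.null(tags[["00281052"]])) as.numeric(txt(tags[["00281052"]])) else 0
  px <- need("7fe00010", "PixelData")
  stored <- readBin(px, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (!signed) stored <- as.numeric(stored)
  hu <- slope * stored + intercept
  # DICOM pixel data is row-major, first row at the top
  image_grid(matrix(hu, rows, cols, byrow = TRUE), spacing[1],
             value_kind = "HU")
}
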