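# Minimal DICOM codec for single-frame axial CT slices.
#
# Scope: explicit and implicit VR little endian, uncompressed 16-bit
# monochrome pixel data, the geometry/rescale tags the pipeline needs.
# This is intentionally not a general DICOM implementation; unknown
# elements are skipped by length.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"

# VRs that use the 4-byte length form in explicit VR encoding
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tag dictionary used when reading implicit VR files
DICOM_DICT <- list(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0018,0050" = "DS",
  "0020,000d" = "UI", "0020,000e" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "7fe0,0010" = "OW"
)

uint16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x / 256) %% 256, (x / 65536) %% 256, (x / 16777216) %% 256) %/% 1)
}

pad_even <- function(value, pad = as.raw(0L)) {
  if (length(value) %% 2L == 1L) c(value, pad) else value
}

dicom_element <- function(group, element, vr, value) {
  if (vr %in% c("UI")) value <- pad_even(charToRaw(value), as.raw(0L))
  else if (vr %in% c("CS", "DS", "IS", "LO", "SH")) {
    value <- pad_even(charToRaw(value), charToRaw(" "))
  }
  header <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(header, as.raw(c(0L, 0L)), uint32le(length(value)), value)
  } else {
    c(header, uint16le(length(value)), value)
  }
}

ds_string <- function(x) {
  paste(vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                     digits = 10), ""), collapse = "\\")
}

write_dicom_file <- function(path, pixels, pixel_spacing, slice_thickness,
                             position, instance, series_uid,
                             slope = 1, intercept = -1024) {
  stopifnot(is.matrix(pixels))
  stored <- as.integer(round(pixels))
  sop_uid <- paste0(series_uid, ".", instance)

  # pixel data: row-major int16 (signed, PixelRepresentation = 1)
  px_raw <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")

  body <- c(
    dicom_element(0x0008, 0x0016, "UI", SOP_CT_IMAGE),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0008, 0x0060, "CS", "CT"),
    dicom_element(0x0018, 0x0050, "DS", ds_string(slice_thickness)),
    dicom_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    dicom_element(0x0020, 0x000E, "UI", series_uid),
    dicom_element(0x0020, 0x0013, "IS", as.character(instance)),
    dicom_element(0x0020, 0x0032, "DS", ds_string(position)),
    dicom_element(0x0020, 0x0037, "DS", ds_string(c(1, 0, 0, 0, 1, 0))),
    dicom_element(0x0028, 0x0002, "US", uint16le(1L)),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", uint16le(nrow(pixels))),
    dicom_element(0x0028, 0x0011, "US", uint16le(ncol(pixels))),
    dicom_element(0x0028, 0x0030, "DS", ds_string(pixel_spacing)),
    dicom_element(0x0028, 0x0100, "US", uint16le(16L)),
    dicom_element(0x0028, 0x0101, "US", uint16le(16L)),
    dicom_element(0x0028, 0x0102, "US", uint16le(15L)),
    dicom_element(0x0028, 0x0103, "US", uint16le(1L)),
    dicom_element(0x0028, 0x1052, "DS", ds_string(intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds_string(slope)),
    dicom_element(0x7FE0, 0x0010, "OW", px_raw)
  )

  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002, 0x0002, "UI", SOP_CT_IMAGE),
    dicom_element(0x0002, 0x0003, "UI", sop_uid),
    dicom_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dicom_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", uint32le(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

read_u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

raw_to_string <- function(value) {
  while (length(value) &&
         (value[length(value)] == as.raw(0L) ||
          value[length(value)] == as.raw(0x20))) {
    value <- value[-length(value)]
  }
  rawToChar(value)
}

parse_ds <- function(value) {
  as.numeric(strsplit(raw_to_string(value), "\\", fixed = TRUE)[[1]])
}

# Parse one data element starting at offset `at` (1-based); returns
# list(tag, value, next_at). `explicit` selects the VR encoding.
parse_element <- function(raw, at, explicit) {
  group <- read_u16(raw, at)
  element <- read_u16(raw, at + 2L)
  tag <- sprintf("%04x,%04x", group, element)
  if (explicit) {
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(raw, at + 8L)
      data_at <- at + 12L
    } else {
      len <- read_u16(raw, at + 6L)
      data_at <- at + 8L
    }
  } else {
    vr <- DICOM_DICT[[tag]]
    if (is.null(vr)) vr <- "UN"
    len <- read_u32(raw, at + 4L)
    data_at <- at + 8L
  }
  if (len == 0xFFFFFFFF) stop("undefined-length DICOM elements not supported")
  value <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0L)
  list(tag = tag, vr = vr, value = value, next_at = data_at + len)
}

# Read the subset of a CT slice file the pipeline needs.
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  at <- 133L
  transfer_syntax <- TS_EXPLICIT_LE
  elements <- list()
  while (at + 7L <= length(bytes)) {
    group <- read_u16(bytes, at)
    explicit <- if (group == 2L) TRUE else transfer_syntax != TS_IMPLICIT_LE
    el <- parse_element(bytes, at, explicit)
    elements[[el$tag]] <- el
    if (el$tag == "0002,0010") transfer_syntax <- raw_to_string(el$value)
    at <- el$next_at
  }
  if (!transfer_syntax %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
    stop("unsupported transfer syntax: ", transfer_syntax)
  }

  need <- function(tag) {
    el <- elements[[tag]]
    if (is.null(el)) stop("missing DICOM tag (", tag, ") in ", path)
    el$value
  }
  opt_ds <- function(tag) {
    el <- elements[[tag]]
    if (is.null(el)) NULL else parse_ds(el$value)
  }

  rows <- read_u16(need("0028,0010"), 1L)
  cols <- read_u16(need("0028,0011"), 1L)
  bits <- read_u16(need("0028,0100"), 1L)
  if (bits != 16L) stop("only 16-bit pixel data supported")
  signed <- read_u16(need("0028,0103"), 1L) == 1L

  px <- need("7fe0,0010")
  if (length(px) < 2L * rows * cols) stop("truncated pixel data in ", path)
  vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  pixels <- t(matrix(vals, nrow = cols, ncol = rows))  # stored row-major

  slope_el <- elements[["0028,1053"]]
  inter_el <- elements[["0028,1052"]]
  list(
    pixels = pixels,
    pixel_spacing = opt_ds("0028,0030"),
    slice_thickness = {
      st <- opt_ds("0018,0050"); if (is.null(st)) NULL else st[1]
    },
    position = opt_ds("0020,0032"),
    slope = if (is.null(slope_el)) NULL else parse_ds(slope_el$value)[1],
    intercept = if (is.null(inter_el)) NULL else parse_ds(inter_el$value)[1],
    series_uid = {
      el <- elements[["0020,000e"]]
      if (is.null(el)) stop("missing SeriesInstanceUID in ", path)
      raw_to_string(el$value)
    },
    instance = {
      el <- elements[["0020,0013"]]
      if (is.null(el)) NA_integer_ else as.integer(raw_to_string(el$value))
    }
  )
}
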