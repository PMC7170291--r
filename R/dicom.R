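# Minimal DICOM (Explicit VR Little Endian) writer/reader for flood images.
# Covers exactly the subset the QC pipeline needs: 16-bit unsigned grayscale
# pixel data plus the header attributes used for sorting and records. The
# writer always emits Explicit VR LE (transfer syntax 1.2.840.10008.1.2.1);
# the reader accepts only that syntax and raises a typed condition otherwise.

SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "2.25"

dicom_error <- function(msg) {
  stop(structure(class = c("sniqc_dicom_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

raw_u16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

# VRs that use the 4-byte length form with 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_u32(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) dicom_error("element value too long")
    c(head, raw_u16(length(value_raw)), value_raw)
  }
}

dcm_str_element <- function(group, elem, vr, s) {
  v <- charToRaw(as.character(s))
  if (length(v) %% 2 == 1)
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  dcm_element(group, elem, vr, v)
}

dcm_us_element <- function(group, elem, value)
  dcm_element(group, elem, "US", raw_u16(value))

# deterministic instance UID from the image content/metadata (keeps
# golden-file archives byte-stable across runs)
dcm_instance_uid <- function(pixels, station, stamp) {
  h1 <- sum(as.numeric(pixels) * (seq_along(pixels) %% 97 + 1)) %% 1e9
  h2 <- sum(utf8ToInt(paste0(station, stamp))) %% 1e6
  sprintf("%s.%.0f.%.0f.%.0f", UID_ROOT, h1, h2, length(pixels))
}

#' Write a flood image as a DICOM file
#'
#' Writes an Explicit VR Little Endian secondary-capture DICOM with 16-bit
#' unsigned pixels and the header attributes the pipeline sorts on: station
#' name, study/series description, acquisition date/time, pixel spacing,
#' isotope (radiopharmaceutical tag) and matrix size.
#'
#' @param flood a [flood_image()]; all counts must fit 16 bits (< 65536).
#' @param path output file path.
#' @param write_spacing if `FALSE`, the PixelSpacing element is omitted
#'   (some vendors do); readers then fall back to a 1 mm default.
#' @return `path`, invisibly.
#' @export
write_synthetic_dicom <- function(flood, path, write_spacing = TRUE) {
  stopifnot(inherits(flood, "flood_image"))
  px <- flood$pixels
  if (max(px) > 65535)
    dicom_error("pixel counts exceed the 16-bit stored representation")
  stamp <- format(flood$acquired_at, "%Y%m%d%H%M%S", tz = "UTC")
  date8 <- substr(stamp, 1, 8)
  time6 <- substr(stamp, 9, 14)
  uid <- dcm_instance_uid(px, flood$station, stamp)

  meta <- c(
    dcm_str_element(0x0002, 0x0002, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str_element(0x0002, 0x0003, "UI", uid),
    dcm_str_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    dcm_str_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".424242"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta))), meta)

  body <- c(
    dcm_str_element(0x0008, 0x0016, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str_element(0x0008, 0x0018, "UI", uid),
    dcm_str_element(0x0008, 0x0020, "DA", date8),
    dcm_str_element(0x0008, 0x0022, "DA", date8),
    dcm_str_element(0x0008, 0x0030, "TM", time6),
    dcm_str_element(0x0008, 0x0032, "TM", time6),
    dcm_str_element(0x0008, 0x0060, "CS", "NM"),
    dcm_str_element(0x0008, 0x1010, "SH", flood$station),
    dcm_str_element(0x0008, 0x1030, "LO", flood$study_description),
    dcm_str_element(0x0008, 0x103E, "LO", flood$series_description),
    dcm_str_element(0x0010, 0x0010, "PN", "FLOOD^QC"),
    dcm_str_element(0x0010, 0x0020, "LO", "QC"),
    dcm_str_element(0x0018, 0x0031, "LO", flood$isotope),
    dcm_us_element(0x0028, 0x0002, 1),
    dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us_element(0x0028, 0x0010, nrow(px)),
    dcm_us_element(0x0028, 0x0011, ncol(px))
  )
  if (write_spacing) {
    # DICOM convention: row spacing (dy) first, then column spacing (dx)
    body <- c(body, dcm_str_element(
      0x0028, 0x0030, "DS",
      sprintf("%.6g\\%.6g", flood$spacing[2], flood$spacing[1])))
  }
  body <- c(body,
    dcm_us_element(0x0028, 0x0100, 16),
    dcm_us_element(0x0028, 0x0101, 16),
    dcm_us_element(0x0028, 0x0102, 15),
    dcm_us_element(0x0028, 0x0103, 0),
    dcm_element(0x7FE0, 0x0010, "OW", raw_u16(as.vector(t(px))))
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

rd_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1])
rd_u32 <- function(raw, at)
  sum(as.numeric(raw[at:(at + 3)]) * c(1, 256, 65536, 16777216))

#' Read a flood-image DICOM file
#'
#' Parses an Explicit VR Little Endian DICOM file and returns a
#' [flood_image()]. Pixel spacing defaults to 1 mm (with
#' `spacing_assumed = TRUE`) when the PixelSpacing element is absent.
#' Total counts are taken from the pixel sum, never from a header tag.
#'
#' @param path file path.
#' @return A [flood_image()].
#' @export
read_flood_dicom <- function(path) {
  if (!file.exists(path)) dicom_error(paste("no such file:", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 140) dicom_error("file too short to be DICOM")
  raw <- readBin(path, "raw", n = sz)
  if (rawToChar(raw[129:132]) != "DICM")
    dicom_error("missing DICM magic: not a DICOM part-10 file")

  tags <- new.env(parent = emptyenv())
  pos <- 133L
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- rd_u16(raw, pos); elem <- rd_u16(raw, pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      dicom_error("unsupported encoding (expected Explicit VR Little Endian)")
    if (vr %in% LONG_VRS) {
      len <- rd_u32(raw, pos + 8)
      vstart <- pos + 12L
    } else {
      len <- rd_u16(raw, pos + 6)
      vstart <- pos + 8L
    }
    if (vstart + len - 1 > n) dicom_error("truncated DICOM element")
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- list(vr = vr, start = vstart, len = len)
    pos <- vstart + as.integer(len)
  }

  get_str <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    s <- rawToChar(raw[t$start:(t$start + t$len - 1)])
    gsub("[\\s\\0]+$", "", s, perl = TRUE)
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) dicom_error(paste("missing required element", key))
    rd_u16(raw, t$start)
  }

  ts <- get_str("00020010")
  if (!is.null(ts) && ts != TRANSFER_SYNTAX_EXPLICIT_LE)
    dicom_error(paste("unsupported transfer syntax:", ts))

  rows <- get_us("00280010"); cols <- get_us("00280011")
  pd <- tags[["7FE00010"]]
  if (is.null(pd)) dicom_error("no PixelData element")
  if (pd$len < 2 * rows * cols) dicom_error("PixelData shorter than Rows*Columns")
  vals <- readBin(raw[pd$start:(pd$start + 2 * rows * cols - 1)], "integer",
                  n = rows * cols, size = 2, signed = FALSE,
                  endian = "little")
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  sp_str <- get_str("00280030")
  if (is.null(sp_str) || !nzchar(sp_str)) {
    spacing <- c(1, 1); assumed <- TRUE
  } else {
    parts <- as.numeric(strsplit(sp_str, "\\\\")[[1]])
    spacing <- c(parts[2], parts[1])  # (dx, dy) from (row, col) spacing
    assumed <- FALSE
  }

  date8 <- get_str("00080022", get_str("00080020", "20000101"))
  time6 <- get_str("00080032", get_str("00080030", "000000"))
  stamp <- as.POSIXct(paste(date8, substr(time6, 1, 6)),
                      format = "%Y%m%d %H%M%S", tz = "UTC")
  if (is.na(stamp)) stamp <- as.POSIXct("2000-01-01", tz = "UTC")

  flood_image(
    pixels = px, spacing = spacing,
    station = get_str("00081010", "UNKNOWN"),
    acquired_at = stamp,
    isotope = get_str("00180031", "Co-57"),
    spacing_assumed = assumed,
    study_description = get_str("00081030", ""),
    series_description = get_str("0008103E", "")
  )
}
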