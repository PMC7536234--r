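# Minimal DICOM support: uncompressed Explicit VR Little Endian, 8-bit
# monochrome (MONOCHROME2), single frame. Covers exactly the image/mask pairs
# this pipeline writes and reads; anything else is rejected.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SC_IMAGE <- "1.2.840.10008.5.1.4.1.1.7" # secondary capture image storage
UID_IMPL <- "1.2.826.0.1.3680043.9.7777.1"  # implementation class (site UID root)

.u16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# one data element, explicit VR
.elem <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "LO", "SH", "DS", "IS", "DA", "TM", "PN")) {
    val <- charToRaw(value)
    if (length(val) %% 2L == 1L) {
      val <- c(val, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
  } else if (vr == "US") {
    val <- .u16le(as.integer(value))
  } else if (vr == "UL") {
    val <- .u32le(value)
  } else if (vr %in% c("OB", "OW")) {
    val <- value # already raw
    if (length(val) %% 2L == 1L) val <- c(val, as.raw(0L))
  } else {
    stop("unsupported VR: ", vr)
  }
  head <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), .u32le(length(val)), val)
  } else {
    if (length(val) > 65535L) stop("value too long for short-form VR")
    c(head, .u16le(length(val)), val)
  }
}

#' Write an 8-bit greyscale matrix as a single-frame DICOM file
#'
#' Writes an uncompressed Explicit VR Little Endian secondary-capture DICOM
#' with MONOCHROME2 photometric interpretation. The matrix is stored row by
#' row; values must already lie in 0..255.
#'
#' @param pixels integer/numeric matrix with values in 0..255.
#' @param path output file path.
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm/pixel.
#' @param tags named character list: `patient_id`, `machine`, `side`
#'   (`"left"`/`"right"`), `plane` (`"longitudinal"`/`"coronal"`).
#' @param sop_uid SOP instance UID; a deterministic default is derived from
#'   the tags when omitted.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, pixel_spacing = c(1, 1),
                        tags = list(), sop_uid = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 255)
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (is.null(sop_uid)) {
    sop_uid <- paste0(UID_IMPL, ".", abs(sum(px) %% 99991L), ".",
                      nrow(pixels), ".", ncol(pixels))
  }
  get_tag <- function(name, default) {
    v <- tags[[name]]
    if (is.null(v)) default else as.character(v)
  }
  meta <- c(
    .elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .elem(0x0002, 0x0002, "UI", UID_SC_IMAGE),
    .elem(0x0002, 0x0003, "UI", sop_uid),
    .elem(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    .elem(0x0002, 0x0012, "UI", UID_IMPL)
  )
  meta <- c(.elem(0x0002, 0x0000, "UL", length(meta)), meta)
  side <- get_tag("side", "left")
  body <- c(
    .elem(0x0008, 0x0016, "UI", UID_SC_IMAGE),
    .elem(0x0008, 0x0018, "UI", sop_uid),
    .elem(0x0008, 0x0060, "CS", "US"),
    .elem(0x0008, 0x103E, "LO", get_tag("plane", "longitudinal")),
    .elem(0x0008, 0x1090, "LO", get_tag("machine", "unknown")),
    .elem(0x0010, 0x0020, "LO", get_tag("patient_id", "anonymous")),
    .elem(0x0020, 0x0060, "CS", if (side == "right") "R" else "L"),
    .elem(0x0028, 0x0002, "US", 1L),
    .elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .elem(0x0028, 0x0010, "US", nrow(pixels)),
    .elem(0x0028, 0x0011, "US", ncol(pixels)),
    .elem(0x0028, 0x0030, "DS", paste0(format(pixel_spacing[1], digits = 10), "\\",
                                       format(pixel_spacing[2], digits = 10))),
    .elem(0x0028, 0x0100, "US", 8L),
    .elem(0x0028, 0x0101, "US", 8L),
    .elem(0x0028, 0x0102, "US", 7L),
    .elem(0x0028, 0x0103, "US", 0L),
    .elem(0x7FE0, 0x0010, "OB", as.raw(as.vector(t(px))))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

.rd_u16 <- function(bytes, off) {
  as.integer(bytes[off + 1L]) + 256L * as.integer(bytes[off + 2L])
}
.rd_u32 <- function(bytes, off) {
  as.numeric(bytes[off + 1L]) + 256 * as.numeric(bytes[off + 2L]) +
    65536 * as.numeric(bytes[off + 3L]) + 16777216 * as.numeric(bytes[off + 4L])
}

#' Read a single-frame 8-bit DICOM file written by this package
#'
#' Parses an uncompressed Explicit VR Little Endian monochrome DICOM and
#' returns the pixel matrix plus the tags the pipeline uses. Unknown data
#' elements are skipped.
#'
#' @param path DICOM file path.
#' @return list with `pixels` (integer matrix), `pixel_spacing` (row, col in
#'   mm/pixel), and `tags` (`patient_id`, `machine`, `side`, `plane`).
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  off <- 132L
  store <- list()
  while (off + 8L <= length(bytes)) {
    group <- .rd_u16(bytes, off); elem <- .rd_u16(bytes, off + 2L)
    vr <- rawToChar(bytes[(off + 5L):(off + 6L)])
    if (vr %in% long_vrs) {
      len <- .rd_u32(bytes, off + 8L)
      val_off <- off + 12L
    } else {
      len <- .rd_u16(bytes, off + 6L)
      val_off <- off + 8L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (key %in% c("00020010", "00081090", "0008103E", "00100020", "00200060",
                   "00280010", "00280011", "00280030", "00280004", "00280100",
                   "7FE00010") && len > 0) {
      store[[key]] <- bytes[(val_off + 1L):(val_off + len)]
    }
    off <- val_off + len
  }
  str_tag <- function(key) {
    v <- store[[key]]
    if (is.null(v)) return(NA_character_)
    trimws(rawToChar(v[v != as.raw(0L)]))
  }
  ts <- str_tag("00020010")
  if (!is.na(ts) && ts != TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  if (!is.null(store[["00280100"]]) && .rd_u16(store[["00280100"]], 0L) != 8L)
    stop("only 8-bit pixel data is supported")
  rows <- .rd_u16(store[["00280010"]], 0L)
  cols <- .rd_u16(store[["00280011"]], 0L)
  spacing <- as.numeric(strsplit(str_tag("00280030"), "\\\\")[[1]])
  if (length(spacing) != 2L || any(!is.finite(spacing))) spacing <- c(1, 1)
  px <- as.integer(store[["7FE00010"]][seq_len(rows * cols)])
  pixels <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  side <- str_tag("00200060")
  list(
    pixels = pixels,
    pixel_spacing = spacing,
    tags = list(
      patient_id = str_tag("00100020"),
      machine = str_tag("00081090"),
      side = if (identical(side, "R")) "right" else "left",
      plane = str_tag("0008103E")
    )
  )
}
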