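# Minimal single-frame CT DICOM I/O: uncompressed little-endian transfer
# syntaxes only (explicit VR written, explicit or implicit read), integer
# pixel data with a linear rescale. Phantom QC exports are plain CT slices;
# LUTs, multi-frame objects and compressed syntaxes are out of scope.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"

.raw16 <- function(n) writeBin(as.integer(n), raw(), size = 2, endian = "little")
.raw32 <- function(n) writeBin(as.integer(n), raw(), size = 4, endian = "little")

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# one data element, explicit VR little endian
.dcm_element <- function(group, element, vr, payload) {
  if (length(payload) %% 2L != 0L) stop("odd element payload")
  hdr <- c(.raw16(group), .raw16(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), .raw32(length(payload)), payload)
  } else {
    c(hdr, .raw16(length(payload)), payload)
  }
}

# string payload padded to even length: UI pads with NUL, text VRs with space
.str_payload <- function(s, pad = " ") {
  r <- charToRaw(as.character(s))
  if (length(r) %% 2L != 0L)
    r <- c(r, if (identical(pad, "nul")) as.raw(0L) else charToRaw(" "))
  r
}

.new_uid <- function() {
  # UUID-derived numeric-form UID root; digits drawn from the session RNG
  paste0("2.25.", paste(c(sample(1:9, 1), sample(0:9, 29, replace = TRUE)),
                        collapse = ""))
}

#' Write one HU image as a minimal CT DICOM file
#'
#' Encodes HU values as unsigned 16-bit stored values with rescale slope 1 and
#' intercept -1024 (so water is stored as 1024), explicit VR little endian.
#' Intended for fixtures and for exporting synthetic phantom stacks; HU are
#' preserved to within +/- 0.5 by integer rounding.
#'
#' @param image An [hu_image].
#' @param path Output file path.
#' @param instance_number Instance number written to the file (stack order).
#' @param series_uid,study_uid Optional UIDs shared across a stack.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(image, path, instance_number = 1L,
                              series_uid = .new_uid(), study_uid = .new_uid()) {
  stopifnot(is_hu_image(image))
  intercept <- -1024
  stored <- round(image$values) - intercept
  stored <- pmin(pmax(stored, 0), 32767)  # fits signed 16-bit writeBin
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  sop_uid <- .new_uid()
  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcm_element(0x0002, 0x0002, "UI", .str_payload(UID_CT_STORAGE, "nul")),
    .dcm_element(0x0002, 0x0003, "UI", .str_payload(sop_uid, "nul")),
    .dcm_element(0x0002, 0x0010, "UI", .str_payload(UID_EXPLICIT_LE, "nul")),
    .dcm_element(0x0002, 0x0012, "UI", .str_payload("2.25.1", "nul")))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .raw32(length(meta))), meta)

  ps <- paste(format(image$spacing_mm, digits = 10, trim = TRUE), collapse = "\\")
  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", .str_payload(UID_CT_STORAGE, "nul")),
    .dcm_element(0x0008, 0x0018, "UI", .str_payload(sop_uid, "nul")),
    .dcm_element(0x0008, 0x0060, "CS", .str_payload("CT")),
    .dcm_element(0x0020, 0x000D, "UI", .str_payload(study_uid, "nul")),
    .dcm_element(0x0020, 0x000E, "UI", .str_payload(series_uid, "nul")),
    .dcm_element(0x0020, 0x0013, "IS", .str_payload(as.integer(instance_number))),
    .dcm_element(0x0028, 0x0002, "US", .raw16(1L)),
    .dcm_element(0x0028, 0x0004, "CS", .str_payload("MONOCHROME2")),
    .dcm_element(0x0028, 0x0010, "US", .raw16(image$rows)),
    .dcm_element(0x0028, 0x0011, "US", .raw16(image$cols)),
    .dcm_element(0x0028, 0x0030, "DS", .str_payload(ps)),
    .dcm_element(0x0028, 0x0100, "US", .raw16(16L)),
    .dcm_element(0x0028, 0x0101, "US", .raw16(16L)),
    .dcm_element(0x0028, 0x0102, "US", .raw16(15L)),
    .dcm_element(0x0028, 0x0103, "US", .raw16(0L)),
    .dcm_element(0x0028, 0x1052, "DS", .str_payload(format(intercept))),
    .dcm_element(0x0028, 0x1053, "DS", .str_payload("1")),
    .dcm_element(0x7FE0, 0x0010, "OW", px))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

.u16 <- function(bytes, i) {
  as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
}
.u32 <- function(bytes, i) {
  as.integer(bytes[i]) + 256 * as.integer(bytes[i + 1L]) +
    65536 * as.integer(bytes[i + 2L]) + 16777216 * as.integer(bytes[i + 3L])
}

# parse little-endian data elements from `pos` until `stop_group` changes or
# pixel data is consumed; returns list(tags = named list of raw payloads, pos)
.parse_elements <- function(bytes, pos, explicit, only_group = NULL) {
  tags <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- .u16(bytes, pos); element <- .u16(bytes, pos + 2L)
    if (!is.null(only_group) && group != only_group) break
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- .u32(bytes, pos + 8L); dstart <- pos + 12L
      } else {
        len <- .u16(bytes, pos + 6L); dstart <- pos + 8L
      }
    } else {
      len <- .u32(bytes, pos + 4L); dstart <- pos + 8L
    }
    if (len == 4294967295) stop("DICOM parse error: undefined-length element (sequences unsupported)")
    if (dstart + len - 1L > n) stop("DICOM parse error: element overruns file")
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- if (len > 0L) bytes[dstart:(dstart + len - 1L)] else raw(0L)
    pos <- dstart + len
    if (key == "7FE0,0010") break
  }
  list(tags = tags, pos = pos)
}

.tag_str <- function(tags, key) {
  if (is.null(tags[[key]])) return(NULL)
  r <- tags[[key]]
  trimws(rawToChar(r[r != as.raw(0L)]))  # UI values are NUL-padded
}
.tag_us <- function(tags, key) {
  if (is.null(tags[[key]])) return(NULL)
  readBin(tags[[key]], integer(), n = 1L, size = 2, signed = FALSE,
          endian = "little")
}
.tag_ds <- function(tags, key) {
  s <- .tag_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

#' Read a single-frame CT DICOM slice as a calibrated HU image
#'
#' Supports uncompressed explicit- and implicit-VR little-endian files with
#' monochrome integer pixel data and a linear rescale. Returned values are
#' `stored * RescaleSlope + RescaleIntercept`, i.e. Hounsfield units; pixel
#' spacing is taken from the PixelSpacing attribute (mm).
#'
#' @param path Path to a DICOM file.
#' @return An [hu_image]; the InstanceNumber (if present) is attached as
#'   attribute `"instance_number"`.
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("DICOM I/O error: file not found: ", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("DICOM parse error: missing DICM marker (not a part-10 DICOM file)")

  meta <- .parse_elements(bytes, 133L, explicit = TRUE, only_group = 0x0002)
  ts <- .tag_str(meta$tags, "0002,0010")
  if (is.null(ts)) stop("DICOM parse error: missing transfer syntax UID")
  explicit <- ts == UID_EXPLICIT_LE
  if (!explicit && ts != UID_IMPLICIT_LE)
    stop("DICOM parse error: unsupported transfer syntax ", ts,
         " (compressed data not supported)")

  ds <- .parse_elements(bytes, meta$pos, explicit = explicit)$tags

  need <- function(key, what) {
    if (is.null(ds[[key]]))
      stop("DICOM calibration error: missing ", what, " (", key, ")")
  }
  need("7FE0,0010", "PixelData")
  need("0028,0030", "PixelSpacing")
  need("0028,0010", "Rows"); need("0028,0011", "Columns")
  need("0028,1052", "RescaleIntercept"); need("0028,1053", "RescaleSlope")

  photometric <- .tag_str(ds, "0028,0004")
  if (!is.null(photometric) && !startsWith(photometric, "MONOCHROME"))
    stop("DICOM calibration error: non-monochrome photometric interpretation ",
         photometric)
  spp <- .tag_us(ds, "0028,0002")
  if (!is.null(spp) && spp != 1L)
    stop("DICOM calibration error: SamplesPerPixel must be 1")
  bits <- .tag_us(ds, "0028,0100")
  if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("DICOM parse error: only 16-bit pixel data supported")

  rows <- .tag_us(ds, "0028,0010"); cols <- .tag_us(ds, "0028,0011")
  signed <- identical(.tag_us(ds, "0028,0103"), 1L)
  slope <- .tag_ds(ds, "0028,1053")[1]
  intercept <- .tag_ds(ds, "0028,1052")[1]
  spacing <- .tag_ds(ds, "0028,0030")  # (row, col) mm

  npx <- rows * cols
  if (length(ds[["7FE0,0010"]]) < 2L * npx)
    stop("DICOM parse error: PixelData shorter than Rows x Columns")
  stored <- readBin(ds[["7FE0,0010"]], integer(), n = npx, size = 2,
                    signed = signed, endian = "little")
  values <- matrix(stored * slope + intercept, nrow = rows, byrow = TRUE)

  img <- hu_image(values, spacing_mm = spacing)
  inst <- .tag_str(ds, "0020,0013")
  if (!is.null(inst)) attr(img, "instance_number") <- as.integer(inst)
  img
}

#' Read a directory of DICOM slices as an ordered stack
#'
#' Reads every `.dcm` file (or every file, if none match) in `dir` and orders
#' the slices by InstanceNumber.
#'
#' @param dir Directory containing one DICOM file per slice.
#' @return List of [hu_image] objects in instance order.
#' @export
read_dicom_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0L) stop("DICOM I/O error: no files in ", dir)
  slices <- lapply(files, read_dicom_slice)
  inst <- vapply(slices, function(s) {
    i <- attr(s, "instance_number")
    if (is.null(i)) NA_integer_ else i
  }, integer(1))
  if (!anyNA(inst)) slices <- slices[order(inst)]
  slices
}

#' Dump HU values as delimited text
#'
#' Plain tab-separated dump of the HU grid for external inspection; the first
#' line is a comment with the pixel spacing.
#'
#' @param image An [hu_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hu_tsv <- function(image, path) {
  stopifnot(is_hu_image(image))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_mm\t%.10g\t%.10g",
                     image$spacing_mm[1], image$spacing_mm[2]), con)
  utils::write.table(image$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
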