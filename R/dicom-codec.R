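# Minimal single-frame DICOM codec: Explicit VR Little Endian only.
# Covers the tag set a CT slice-geometry audit needs (position, orientation,
# spacing, acquisition/instance numbers, pixel grid); no sequences, no
# compressed transfer syntaxes.

DCM_UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
DCM_UID_IMPL <- "1.2.826.0.1.3680043.10.1447.1"

# VRs whose element header carries a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

.dcm_pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.dcm_str_raw <- function(x, pad = as.raw(0x20)) {
  .dcm_pad_even(charToRaw(x), pad)
}

.dcm_uint16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

.dcm_uint32 <- function(x) {
  # element lengths fit in a signed int here; writeBin handles it
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# Decimal String: DICOM caps DS at 16 bytes; 10 significant digits keeps
# round-trip error ~1e-9 mm, well under the 1e-3 mm gap tolerance.
.dcm_ds <- function(x) {
  paste(vapply(x, function(v) formatC(v, digits = 10L, format = "g"),
               character(1L)), collapse = "\\")
}

.dcm_element <- function(group, element, vr, value_raw) {
  header <- c(.dcm_uint16(group), .dcm_uint16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(header, as.raw(c(0, 0)), .dcm_uint32(length(value_raw)), value_raw)
  } else {
    stopifnot(length(value_raw) <= 65534L)
    c(header, .dcm_uint16(length(value_raw)), value_raw)
  }
}

.dcm_el_str <- function(group, element, vr, x) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  .dcm_element(group, element, vr, .dcm_str_raw(x, pad))
}

.dcm_el_us <- function(group, element, x) {
  .dcm_element(group, element, "US", .dcm_uint16(x))
}

#' @noRd
#' @param tags named list: specimen_id, instance_number, acquisition_number,
#'   position (3), orientation (6), pixel_spacing (2), slice_thickness,
#'   spacing_between_slices (or NA), n_rows, n_cols, pixels (matrix or NULL),
#'   series_uid, sop_uid
dcm_write_file <- function(path, tags) {
  n_rows <- as.integer(tags$n_rows)
  n_cols <- as.integer(tags$n_cols)
  pixels <- tags$pixels
  if (is.null(pixels)) {
    pix_raw <- raw(2L * n_rows * n_cols)
  } else {
    stopifnot(nrow(pixels) == n_rows, ncol(pixels) == n_cols)
    # row-major pixel order (row by row), 16-bit unsigned little endian
    pix_raw <- writeBin(as.integer(t(pixels)), raw(), size = 2L,
                        endian = "little")
  }

  meta_body <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcm_el_str(0x0002, 0x0002, "UI", DCM_UID_CT_STORAGE),
    .dcm_el_str(0x0002, 0x0003, "UI", tags$sop_uid),
    .dcm_el_str(0x0002, 0x0010, "UI", DCM_UID_EXPLICIT_LE),
    .dcm_el_str(0x0002, 0x0012, "UI", DCM_UID_IMPL)
  )
  meta <- c(
    .dcm_element(0x0002, 0x0000, "UL", .dcm_uint32(length(meta_body))),
    meta_body
  )

  ds <- c(
    .dcm_el_str(0x0008, 0x0016, "UI", DCM_UID_CT_STORAGE),
    .dcm_el_str(0x0008, 0x0018, "UI", tags$sop_uid),
    .dcm_el_str(0x0008, 0x0060, "CS", "CT"),
    .dcm_el_str(0x0010, 0x0010, "PN", tags$specimen_id),
    .dcm_el_str(0x0010, 0x0020, "LO", tags$specimen_id),
    .dcm_el_str(0x0018, 0x0050, "DS", .dcm_ds(tags$slice_thickness))
  )
  if (!is.null(tags$spacing_between_slices) &&
      is.finite(tags$spacing_between_slices)) {
    ds <- c(ds, .dcm_el_str(0x0018, 0x0088, "DS",
                            .dcm_ds(tags$spacing_between_slices)))
  }
  ds <- c(
    ds,
    .dcm_el_str(0x0020, 0x000D, "UI", paste0(tags$series_uid, ".1")),
    .dcm_el_str(0x0020, 0x000E, "UI", tags$series_uid),
    .dcm_el_str(0x0020, 0x0012, "IS", as.character(tags$acquisition_number)),
    .dcm_el_str(0x0020, 0x0013, "IS", as.character(tags$instance_number)),
    .dcm_el_str(0x0020, 0x0032, "DS", .dcm_ds(tags$position)),
    .dcm_el_str(0x0020, 0x0037, "DS", .dcm_ds(tags$orientation)),
    .dcm_el_us(0x0028, 0x0002, 1L),
    .dcm_el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_el_us(0x0028, 0x0010, n_rows),
    .dcm_el_us(0x0028, 0x0011, n_cols),
    .dcm_el_str(0x0028, 0x0030, "DS", .dcm_ds(tags$pixel_spacing)),
    .dcm_el_us(0x0028, 0x0100, 16L),
    .dcm_el_us(0x0028, 0x0101, 16L),
    .dcm_el_us(0x0028, 0x0102, 15L),
    .dcm_el_us(0x0028, 0x0103, 0L),
    .dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

.dcm_parse_elements <- function(buf, offset) {
  out <- list()
  n <- length(buf)
  pos <- offset
  while (pos + 8L <= n + 1L) {
    group <- readBin(buf[pos:(pos + 1L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
    element <- readBin(buf[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                       signed = FALSE, endian = "little")
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported transfer syntax: implicit VR or corrupt element at byte ",
           pos, call. = FALSE)
    }
    if (vr %in% .dcm_long_vrs) {
      len <- readBin(buf[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      val_start <- pos + 12L
    } else {
      len <- readBin(buf[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      val_start <- pos + 8L
    }
    if (len < 0L || val_start + len - 1L > n) {
      stop("truncated DICOM element at byte ", pos, call. = FALSE)
    }
    value <- if (len > 0L) buf[val_start:(val_start + len - 1L)] else raw(0L)
    out[[.dcm_tag_key(group, element)]] <- list(vr = vr, value = value)
    pos <- val_start + len
  }
  out
}

.dcm_get_str <- function(els, key) {
  el <- els[[key]]
  if (is.null(el)) return(NULL)
  v <- el$value[el$value != as.raw(0x00)]  # UI padding
  trimws(rawToChar(v))
}

.dcm_get_ds <- function(els, key) {
  s <- .dcm_get_str(els, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

.dcm_get_is <- function(els, key) {
  s <- .dcm_get_str(els, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.integer(s)
}

.dcm_get_us <- function(els, key) {
  el <- els[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' @noRd
dcm_read_file <- function(path, read_pixels = TRUE) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 132L || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  els <- .dcm_parse_elements(buf, 133L)
  ts <- .dcm_get_str(els, "0002,0010")
  if (!is.null(ts) && ts != DCM_UID_EXPLICIT_LE) {
    stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
  }

  n_rows <- .dcm_get_us(els, "0028,0010")
  n_cols <- .dcm_get_us(els, "0028,0011")
  pixels <- NULL
  if (read_pixels && !is.null(els[["7FE0,0010"]]) &&
      !is.null(n_rows) && !is.null(n_cols)) {
    v <- readBin(els[["7FE0,0010"]]$value, "integer",
                 n = n_rows * n_cols, size = 2L, signed = FALSE,
                 endian = "little")
    pixels <- matrix(v, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  }

  list(
    specimen_id = .dcm_get_str(els, "0010,0020"),
    instance_number = .dcm_get_is(els, "0020,0013"),
    acquisition_number = .dcm_get_is(els, "0020,0012"),
    position = .dcm_get_ds(els, "0020,0032"),
    orientation = .dcm_get_ds(els, "0020,0037"),
    pixel_spacing = .dcm_get_ds(els, "0028,0030"),
    slice_thickness = .dcm_get_ds(els, "0018,0050"),
    spacing_between_slices = .dcm_get_ds(els, "0018,0088"),
    n_rows = n_rows,
    n_cols = n_cols,
    pixels = pixels
  )
}
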