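# Minimal single-series CT DICOM reading.
#
# Scope: DICOM Part 10 files, explicit or implicit VR little endian, one
# single-frame image per file, uncompressed 16-bit pixel data. That covers
# standard axial CT series; anything else (compressed transfer syntaxes,
# multiframe, big endian) is rejected with a clear error.

# Tags we care about, keyed "group,element" in lower-case hex.
.dcm_tags <- c(
  sop_class        = "0008,0016",
  series_uid       = "0020,000e",
  instance_number  = "0020,0013",
  position         = "0020,0032",
  orientation      = "0020,0037",
  rows             = "0028,0010",
  cols             = "0028,0011",
  pixel_spacing    = "0028,0030",
  bits_allocated   = "0028,0100",
  pixel_repr       = "0028,0103",
  intercept        = "0028,1052",
  slope            = "0028,1053",
  pixel_data       = "7fe0,0010"
)

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

.tag_key <- function(group, element) {
  sprintf("%04x,%04x", group, element)
}

# VRs that use the 4-byte length form in explicit VR little endian.
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one DICOM file into a named list of raw payloads for the tags above.
.dcm_parse <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file (missing DICM magic): ", path)
  }
  pos <- 133L  # 1-based offset just past preamble + magic
  n <- length(raw)
  out <- list()
  transfer_syntax <- NULL
  explicit <- TRUE  # file meta group is always explicit VR LE

  while (pos + 7L <= n) {
    group <- .u16(raw[pos:(pos + 1L)])
    element <- .u16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (!is.null(transfer_syntax) && group != 0x0002) {
      # switch VR mode once past the file meta group
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .long_vrs) {
        len <- .u32(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .u16(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
      if (vr == "SQ" || len == 4294967295) {
        stop("unsupported DICOM element (sequence/undefined length) in ", path)
      }
    } else {
      len <- .u32(raw[pos:(pos + 3L)])
      pos <- pos + 4L
      if (len == 4294967295) {
        stop("unsupported DICOM element (undefined length) in ", path)
      }
    }
    payload <- if (len > 0L) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- .tag_key(group, element)
    if (key == "0002,0010") {
      transfer_syntax <- sub("\\s+$", "", rawToChar(payload))
      transfer_syntax <- gsub("\\x00", "", transfer_syntax, useBytes = TRUE)
      if (!transfer_syntax %in%
          c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        stop("unsupported transfer syntax '", transfer_syntax, "' in ", path)
      }
    }
    hit <- names(.dcm_tags)[match(key, .dcm_tags)]
    if (!is.na(hit)) out[[hit]] <- payload
  }
  out
}

.dcm_str <- function(payload) {
  s <- rawToChar(payload[payload != as.raw(0)])
  trimws(s)
}

.dcm_ds <- function(payload) {
  as.numeric(strsplit(.dcm_str(payload), "\\\\")[[1]])
}

.dcm_us <- function(payload) .u16(payload[1:2])

# Read one slice; returns list(pixels HU matrix [row, col], position,
# orientation, spacing_rc, series_uid).
.dcm_read_slice <- function(path) {
  el <- .dcm_parse(path)
  need <- c("rows", "cols", "pixel_data")
  miss <- setdiff(need, names(el))
  if (length(miss)) {
    stop("DICOM file ", path, " missing required element(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(el$slope) || is.null(el$intercept)) {
    stop("DICOM file ", path, " has no rescale slope/intercept; ",
         "refusing to assume values are Hounsfield Units")
  }
  rows <- .dcm_us(el$rows)
  cols <- .dcm_us(el$cols)
  bits <- if (!is.null(el$bits_allocated)) .dcm_us(el$bits_allocated) else 16L
  if (bits != 16L) stop("only 16-bit pixel data supported (", path, ")")
  signed <- !is.null(el$pixel_repr) && .dcm_us(el$pixel_repr) == 1L
  npx <- rows * cols
  if (length(el$pixel_data) < 2L * npx) {
    stop("pixel data truncated in ", path)
  }
  con <- rawConnection(el$pixel_data)
  stored <- readBin(con, "integer", n = npx, size = 2L,
                    signed = signed, endian = "little")
  close(con)
  slope <- .dcm_ds(el$slope)[1]
  intercept <- .dcm_ds(el$intercept)[1]
  # pixel data is row-major (row by row of columns)
  px <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + intercept
  orient <- if (!is.null(el$orientation)) .dcm_ds(el$orientation) else
    c(1, 0, 0, 0, 1, 0)
  list(
    pixels = px,
    position = if (!is.null(el$position)) .dcm_ds(el$position) else c(0, 0, 0),
    orientation = orient,
    spacing_rc = if (!is.null(el$pixel_spacing)) .dcm_ds(el$pixel_spacing)
      else c(1, 1),
    series_uid = if (!is.null(el$series_uid)) .dcm_str(el$series_uid) else ""
  )
}

# Assemble a directory of DICOM slices into a ct_volume. Slices are sorted by
# physical position along the slice normal, never by filename.
.dcm_read_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, .dcm_read_slice)
  uids <- vapply(slices, `[[`, "", "series_uid")
  if (length(unique(uids)) > 1L) {
    bad <- files[uids != uids[1]][1]
    stop("mixed DICOM series in ", dir, "; offending file: ", bad)
  }
  o <- slices[[1]]$orientation
  normal <- c(
    o[2] * o[6] - o[3] * o[5],
    o[3] * o[4] - o[1] * o[6],
    o[1] * o[5] - o[2] * o[4]
  )
  proj <- vapply(slices, function(s) sum(s$position * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]
  rows <- nrow(slices[[1]]$pixels)
  cols <- ncol(slices[[1]]$pixels)
  vox <- array(0, c(length(slices), rows, cols))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$pixels), c(rows, cols))) {
      stop("inconsistent slice dimensions in series")
    }
    vox[i, , ] <- slices[[i]]$pixels
  }
  dz <- if (length(proj) > 1L) stats::median(diff(proj)) else 1
  if (!is.finite(dz) || dz <= 0) dz <- 1
  sp_rc <- slices[[1]]$spacing_rc
  ct_volume(vox, spacing = c(dz, sp_rc[1], sp_rc[2]),
            origin = c(proj[1], slices[[1]]$position[2],
                       slices[[1]]$position[1]))
}

# --- fixture writer (tests, examples) ---------------------------------------

.dcm_pad_even <- function(x) {
  if (length(x) %% 2L == 1L) c(x, as.raw(0x20)) else x
}

.raw_u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
.raw_u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.dcm_element <- function(group, element, vr, payload) {
  payload <- .dcm_pad_even(payload)
  head <- c(.raw_u16(group), .raw_u16(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0, 0)), .raw_u32(length(payload)), payload)
  } else {
    c(head, .raw_u16(length(payload)), payload)
  }
}

.dcm_str_el <- function(group, element, vr, s) {
  .dcm_element(group, element, vr, charToRaw(s))
}

.dcm_us_el <- function(group, element, value) {
  .dcm_element(group, element, "US", .raw_u16(value))
}

# Write a single-slice explicit-VR-little-endian CT DICOM file. Used to build
# synthetic series in tests and examples; stored values are written as
# unsigned 16-bit, so (hu - intercept)/slope must land in [0, 65535].
write_dicom_slice <- function(hu, path, position = c(0, 0, 0),
                              spacing_rc = c(1, 1), slope = 1,
                              intercept = -1024,
                              series_uid = "1.2.826.0.1.999999.1") {
  stored <- round((hu - intercept) / slope)
  if (any(stored < 0 | stored > 65535)) stop("stored values out of uint16")
  rows <- nrow(hu); cols <- ncol(hu)
  # transpose: pixel data is stored row-major (row by row of columns)
  px_raw <- writeBin(as.integer(as.vector(t(stored))), raw(),
                     size = 2L, endian = "little")
  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcm_str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta_len <- length(meta)
  body <- c(
    .dcm_str_el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_str_el(0x0020, 0x000e, "UI", series_uid),
    .dcm_str_el(0x0020, 0x0032, "DS",
                paste(format(position, trim = TRUE), collapse = "\\")),
    .dcm_str_el(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    .dcm_us_el(0x0028, 0x0010, rows),
    .dcm_us_el(0x0028, 0x0011, cols),
    .dcm_str_el(0x0028, 0x0030, "DS",
                paste(format(spacing_rc, trim = TRUE), collapse = "\\")),
    .dcm_us_el(0x0028, 0x0100, 16L),
    .dcm_us_el(0x0028, 0x0103, 0L),
    .dcm_str_el(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    .dcm_str_el(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    .dcm_element(0x7fe0, 0x0010, "OW", px_raw)
  )
  out <- c(
    raw(128), charToRaw("DICM"),
    .dcm_element(0x0002, 0x0000, "UL", .raw_u32(meta_len)),
    meta, body
  )
  writeBin(out, path)
  invisible(path)
}
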