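# Minimal DICOM support for the two RT objects the pipeline consumes:
# RT Dose and RT Structure Set, explicit-VR little-endian transfer syntax
# only (the profile the companion writers emit and typical TPS exports use).
# Axis-aligned geometry (identity ImageOrientationPatient) is assumed; dose
# is converted to cGy at this boundary.

UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPL <- "1.2.826.0.1.3680043.9.9999.1" # this package's implementation UID

# --- byte-level helpers ----------------------------------------------------

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# One explicit-VR element. `value` is raw (binary VRs) or character
# (joined with "\\" and padded to even length).
dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    s <- paste(value, collapse = "\\")
    value <- charToRaw(s)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% long_vrs)
    c(head, as.raw(c(0, 0)), u32le(length(value)), value)
  else
    c(head, u16le(length(value)), value)
}

dcm_us <- function(group, elem, x)
  dcm_elem(group, elem, "US", writeBin(as.integer(x), raw(), size = 2,
                                       endian = "little"))
dcm_ds <- function(group, elem, x)
  dcm_elem(group, elem, "DS", paste(sprintf("%.10g", x), collapse = "\\"))
dcm_is <- function(group, elem, x)
  dcm_elem(group, elem, "IS", paste(sprintf("%d", as.integer(x)), collapse = "\\"))

# Sequence with defined lengths; items is a list of raw vectors.
dcm_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items)
    body <- c(body, u16le(0xFFFE), u16le(0xE000), u32le(length(it)), it)
  c(u16le(group), u16le(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    u32le(length(body)), body)
}

dcm_file <- function(sop_class, sop_instance, dataset) {
  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", sop_class),
    dcm_elem(0x0002, 0x0003, "UI", sop_instance),
    dcm_elem(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_elem(0x0002, 0x0012, "UI", UID_IMPL)
  )
  c(raw(128), charToRaw("DICM"),
    dcm_elem(0x0002, 0x0000, "UL", u32le(length(meta))), meta, dataset)
}

# Monotone instance-UID suffixes without touching the user's RNG state.
.uid_counter <- new.env(parent = emptyenv())
new_uid <- function(kind) {
  n <- (.uid_counter$n %||% 0L) + 1L
  .uid_counter$n <- n
  sprintf("%s.%s.%d.%d", UID_IMPL, kind,
          as.integer(Sys.time()) %% 100000L, n)
}

# --- generic explicit-VR parser -------------------------------------------

# Parses a dataset byte range into a list keyed "GGGG,EEEE"; SQ values are
# lists of item datasets (recursively parsed). Values keep their VR as an
# attribute; binary payloads stay raw, string VRs become character.
parse_dataset <- function(bytes, pos = 1L, end = length(bytes)) {
  out <- list()
  str_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
               "SH", "ST", "TM", "UI", "UT")
  while (pos + 7L <= end + 1L && pos <= end) {
    grp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    ele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    pos <- pos + 4L
    if (grp == 0xFFFE) { # item delimiters inside undefined-length sequences
      pos <- pos + 4L
      if (ele == 0xE0DD || ele == 0xE00D) next
      stop("unexpected item tag outside sequence parsing")
    }
    vr <- rawToChar(bytes[pos:(pos + 1)])
    pos <- pos + 2L
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 2):(pos + 5)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 6L
    } else {
      len <- readBin(bytes[pos:(pos + 1)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      pos <- pos + 2L
    }
    key <- sprintf("%04X,%04X", grp, ele)
    if (vr == "SQ") {
      sq_end <- if (len == -1L) end else pos + len - 1L
      items <- list()
      while (pos <= sq_end) {
        igrp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2,
                        endian = "little", signed = FALSE)
        iele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                        endian = "little", signed = FALSE)
        ilen <- readBin(bytes[(pos + 4):(pos + 7)], "integer", size = 4,
                        endian = "little")
        pos <- pos + 8L
        if (igrp == 0xFFFE && iele == 0xE0DD) break # sequence delimiter
        if (!(igrp == 0xFFFE && iele == 0xE000))
          stop("malformed sequence item")
        if (ilen == -1L) { # undefined-length item: scan to its delimiter
          depth <- 0L; p <- pos
          repeat {
            if (p + 7L > end + 1L) stop("truncated sequence item")
            g2 <- readBin(bytes[p:(p + 1)], "integer", size = 2,
                          endian = "little", signed = FALSE)
            e2 <- readBin(bytes[(p + 2):(p + 3)], "integer", size = 2,
                          endian = "little", signed = FALSE)
            if (g2 == 0xFFFE && e2 == 0xE00D && depth == 0L) break
            # advance over one element (only defined lengths inside)
            v2 <- rawToChar(bytes[(p + 4):(p + 5)])
            if (v2 %in% long_vrs) {
              l2 <- readBin(bytes[(p + 10):(p + 13)], "integer", size = 4,
                            endian = "little")
              p <- p + 12L + l2
            } else {
              l2 <- readBin(bytes[(p + 6):(p + 7)], "integer", size = 2,
                            endian = "little", signed = FALSE)
              p <- p + 8L + l2
            }
          }
          items[[length(items) + 1L]] <- parse_dataset(bytes, pos, p - 1L)
          pos <- p + 8L
        } else {
          items[[length(items) + 1L]] <-
            parse_dataset(bytes, pos, pos + ilen - 1L)
          pos <- pos + ilen
        }
      }
      out[[key]] <- structure(items, vr = "SQ")
    } else {
      if (len < 0) stop("undefined length outside a sequence")
      val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      if (vr %in% str_vrs) {
        s <- rawToChar(val[val != as.raw(0)])
        val <- sub("\\s+$", "", s)
      }
      out[[key]] <- structure(val, vr = vr)
    }
  }
  out
}

read_dicom_file <- function(file) {
  bytes <- readBin(file, raw(), n = file.info(file)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM file (missing DICM marker)", file))
  meta_len_ds <- parse_dataset(bytes, 133L, 144L) # (0002,0000) UL
  glen <- readBin(meta_len_ds[["0002,0000"]], "integer", size = 4,
                  endian = "little")
  meta <- parse_dataset(bytes, 145L, 144L + glen)
  ts <- meta[["0002,0010"]]
  if (is.null(ts) || ts != UID_EXPLICIT_LE)
    stop(sprintf("%s: unsupported transfer syntax \"%s\"", file,
                 if (is.null(ts)) "?" else ts))
  ds <- parse_dataset(bytes, 145L + glen)
  list(meta = meta, ds = ds)
}

ds_numeric <- function(ds, key, name) {
  v <- ds[[key]]
  if (is.null(v))
    stop(sprintf("missing required tag (%s) %s", key, name))
  as.double(strsplit(v, "\\\\")[[1]])
}

# --- RT Dose ---------------------------------------------------------------

#' Write / read a DICOM RT Dose object
#'
#' `write_rtdose` serialises a [dose_grid()] as an explicit-VR
#' little-endian RT Dose with 32-bit pixels, axis-aligned orientation and
#' the package's voxel-center geometry convention (ImagePositionPatient is
#' the first voxel center; frames run along z via GridFrameOffsetVector).
#' `read_rtdose` reads such an object back, scales the pixel data by
#' DoseGridScaling, and converts Gy to the package's canonical cGy; missing
#' geometry or scaling tags are reported by tag.
#'
#' @param dose a [dose_grid()] (cGy).
#' @param file path to write / read.
#' @param units dose units to write, `"CGY"` (native) or `"GY"`.
#' @return `read_rtdose` returns a [dose_grid()] in cGy; the writer returns
#'   `file` invisibly.
#' @export
write_rtdose <- function(dose, file, units = c("CGY", "GY")) {
  stopifnot(inherits(dose, "dose_grid"))
  units <- match.arg(units)
  d <- dim(dose$values)
  v <- dose$values
  if (units == "GY") v <- v / 100
  mx <- max(v)
  scaling <- if (mx > 0) mx / (2^31 - 2) else 1
  pix <- as.integer(round(as.vector(v) / scaling))
  sop <- new_uid("2")
  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_elem(0x0008, 0x0018, "UI", sop),
    dcm_elem(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_elem(0x0020, 0x0032, "DS",
             paste(sprintf("%.10g", dose$origin), collapse = "\\")),
    dcm_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_elem(0x0020, 0x0052, "UI", dose$frame),
    dcm_us(0x0028, 0x0002, 1), # SamplesPerPixel
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_is(0x0028, 0x0008, d[3]), # NumberOfFrames
    dcm_us(0x0028, 0x0010, d[2]), # Rows (along y)
    dcm_us(0x0028, 0x0011, d[1]), # Columns (along x)
    dcm_ds(0x0028, 0x0030, c(dose$spacing[2], dose$spacing[1])), # row\col
    dcm_us(0x0028, 0x0100, 32), dcm_us(0x0028, 0x0101, 32),
    dcm_us(0x0028, 0x0102, 31), dcm_us(0x0028, 0x0103, 0),
    dcm_elem(0x3004, 0x0002, "CS", units),
    dcm_elem(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_elem(0x3004, 0x000A, "CS", "PLAN"),
    dcm_ds(0x3004, 0x000C, (seq_len(d[3]) - 1) * dose$spacing[3]),
    dcm_elem(0x3004, 0x000E, "DS", sprintf("%.12g", scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(pix, raw(), size = 4, endian = "little"))
  )
  writeBin(dcm_file(UID_RTDOSE, sop, ds), file)
  invisible(file)
}

#' @rdname write_rtdose
#' @export
read_rtdose <- function(file) {
  f <- read_dicom_file(file)
  ds <- f$ds
  sop <- ds[["0008,0016"]]
  if (is.null(sop) || sop != UID_RTDOSE)
    stop(sprintf("%s: not an RT Dose object", file))
  orient <- ds_numeric(ds, "0020,0037", "ImageOrientationPatient")
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("unsupported ImageOrientationPatient (axis-aligned required)")
  rows <- readBin(ds[["0028,0010"]], "integer", size = 2, endian = "little",
                  signed = FALSE)
  cols <- readBin(ds[["0028,0011"]], "integer", size = 2, endian = "little",
                  signed = FALSE)
  nframes <- if (!is.null(ds[["0028,0008"]]))
    as.integer(ds[["0028,0008"]]) else 1L
  ps <- ds_numeric(ds, "0028,0030", "PixelSpacing")
  ipp <- ds_numeric(ds, "0020,0032", "ImagePositionPatient")
  gfo <- ds_numeric(ds, "3004,000C", "GridFrameOffsetVector")
  scaling <- ds_numeric(ds, "3004,000E", "DoseGridScaling")
  if (nframes > 1) {
    dz <- diff(gfo)
    if (max(abs(dz - dz[1])) > 1e-6)
      stop("non-uniform GridFrameOffsetVector is not supported")
    dz <- dz[1]
  } else dz <- 1
  bits <- readBin(ds[["0028,0100"]], "integer", size = 2, endian = "little",
                  signed = FALSE)
  if (bits != 32) stop("only 32-bit RT Dose pixel data is supported")
  pd <- ds[["7FE0,0010"]]
  if (is.null(pd)) stop("missing required tag (7FE0,0010) PixelData")
  n <- as.integer(rows) * as.integer(cols) * nframes
  if (length(pd) < 4L * n) stop(sprintf("%s: truncated PixelData", file))
  pix <- readBin(pd, "integer", n = n, size = 4, endian = "little")
  pix <- ifelse(pix < 0, pix + 2^32, as.double(pix))
  vals <- array(pix * scaling, c(cols, rows, nframes))
  units <- ds[["3004,0002"]]
  if (!is.null(units) && toupper(units) == "GY") vals <- vals * 100
  frame <- ds[["0020,0052"]] %||% "unknown"
  dose_grid(vals, c(ps[2], ps[1], dz), ipp, frame)
}

# --- RT Structure Set ------------------------------------------------------

#' Write / read a DICOM RT Structure Set
#'
#' `write_rtstruct` serialises per-slice closed-planar contours (the
#' `contours` argument of [rasterize_contours()]) as an RT Structure Set;
#' `read_rtstruct` reads one back and rasterises it onto a grid. DICOM
#' contours do not repeat the first vertex, so the reader closes each
#' polygon before rasterisation.
#'
#' @param contours named list of per-structure contour stacks (see
#'   [rasterize_contours()]).
#' @param file path to write / read.
#' @param frame Frame of Reference identifier written with the contours.
#' @param grid the [dose_grid()] to rasterise onto; its `frame` must match
#'   the file's unless `check_frame = FALSE`.
#' @param keep optional character vector of structure names to keep.
#' @param check_frame verify the Frame of Reference matches the grid's.
#' @return `read_rtstruct` returns a [structure_set()]; the writer returns
#'   `file` invisibly.
#' @export
write_rtstruct <- function(contours, file, frame = "phantom") {
  sop <- new_uid("3")
  nms <- names(contours)
  roi_items <- lapply(seq_along(nms), function(i) c(
    dcm_is(0x3006, 0x0022, i),
    dcm_elem(0x3006, 0x0024, "UI", frame),
    dcm_elem(0x3006, 0x0026, "LO", nms[i])
  ))
  contour_items <- lapply(seq_along(nms), function(i) {
    slices <- contours[[nms[i]]]
    citems <- lapply(slices, function(sl) {
      xy <- sl$xy
      # drop the closing vertex: DICOM closed-planar contours are implicit
      if (max(abs(xy[1, ] - xy[nrow(xy), ])) <= 1e-9)
        xy <- xy[-nrow(xy), , drop = FALSE]
      pts <- rbind(t(xy), sl$z)
      c(dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_is(0x3006, 0x0046, ncol(pts)),
        dcm_elem(0x3006, 0x0050, "DS",
                 paste(sprintf("%.10g", as.vector(pts)), collapse = "\\")))
    })
    c(dcm_sq(0x3006, 0x0040, citems), dcm_is(0x3006, 0x0084, i))
  })
  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_elem(0x0008, 0x0018, "UI", sop),
    dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_elem(0x0020, 0x0052, "UI", frame),
    dcm_elem(0x3006, 0x0002, "SH", "rtverify"),
    dcm_sq(0x3006, 0x0020, roi_items),
    dcm_sq(0x3006, 0x0039, contour_items)
  )
  writeBin(dcm_file(UID_RTSTRUCT, sop, ds), file)
  invisible(file)
}

#' @rdname write_rtstruct
#' @export
read_rtstruct <- function(file, grid, keep = NULL, check_frame = TRUE) {
  stopifnot(inherits(grid, "dose_grid"))
  f <- read_dicom_file(file)
  ds <- f$ds
  sop <- ds[["0008,0016"]]
  if (is.null(sop) || sop != UID_RTSTRUCT)
    stop(sprintf("%s: not an RT Structure Set", file))
  frame <- ds[["0020,0052"]]
  if (check_frame && !is.null(frame) && frame != grid$frame)
    stop(sprintf("frame of reference mismatch: file \"%s\" vs grid \"%s\"",
                 frame, grid$frame))
  rois <- ds[["3006,0020"]]
  if (is.null(rois)) stop("missing required tag (3006,0020) StructureSetROISequence")
  names_by_number <- list()
  for (it in rois)
    names_by_number[[it[["3006,0022"]]]] <- it[["3006,0026"]]
  contours <- list()
  for (it in ds[["3006,0039"]] %||% list()) {
    num <- it[["3006,0084"]]
    nm <- names_by_number[[num]] %||% sprintf("ROI_%s", num)
    if (!is.null(keep) && !(nm %in% keep)) next
    slices <- list()
    for (cit in it[["3006,0040"]] %||% list()) {
      cd <- as.double(strsplit(cit[["3006,0050"]], "\\\\")[[1]])
      pts <- matrix(cd, nrow = 3)
      xy <- t(pts[1:2, , drop = FALSE])
      xy <- rbind(xy, xy[1, ]) # close the polygon
      slices[[length(slices) + 1L]] <- list(z = pts[3, 1], xy = xy)
    }
    if (!length(slices)) {
      warning(sprintf("structure \"%s\" has no contours: empty mask", nm))
      contours[[nm]] <- list()
    } else contours[[nm]] <- slices
  }
  if (!is.null(keep)) contours <- contours[intersect(keep, names(contours))]
  rasterize_contours(contours, grid)
}
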