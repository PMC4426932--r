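# Minimal DICOM RT Dose I/O: explicit-VR little-endian, standard tags only.
# Covers exactly the subset this pipeline needs (grid geometry, dose scaling,
# integer pixel data); it is not a general DICOM toolkit.

UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPL <- "1.2.826.0.1.3680043.10.1472.1"

# VRs whose value length is a 4-byte field after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")

dcm_elem <- function(group, element, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2L == 1L) {  # DICOM values are even-length
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    n <- n + 1L
  }
  head <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    len <- c(as.raw(c(0L, 0L)), uint32le(n))
  } else {
    if (n > 65534L) stop("dcm_elem: value too long for short VR", call. = FALSE)
    len <- uint16le(n)
  }
  c(head, len, value_raw)
}

dcm_str <- function(group, element, vr, s) {
  dcm_elem(group, element, vr, charToRaw(s))
}

dcm_us <- function(group, element, x) {
  dcm_elem(group, element, "US", uint16le(x))
}

dcm_ds <- function(group, element, x) {
  dcm_str(group, element, "DS", paste(sprintf("%.10g", x), collapse = "\\"))
}

# Counter-based instance UIDs: unique within a session without touching
# the RNG stream (generators elsewhere must stay seed-reproducible).
.uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

new_uid <- function() {
  paste0(UID_IMPL, ".", as.integer(Sys.time()) %% 1000000L, ".",
         .uid_counter())
}

#' Write a 3D dose grid as a DICOM RT Dose file
#'
#' Writes an explicit-VR little-endian RT Dose object with the standard grid
#' tags (image position/orientation, pixel spacing, grid frame offset vector,
#' dose grid scaling, 32-bit unsigned pixel data). Dose is stored as
#' `round(values / scaling)`; the quantization error is at most one scaling
#' quantum.
#'
#' @param grid A [dose_grid()] with finite, non-negative values.
#' @param path Output path.
#' @param scaling Dose-grid scaling in Gy per stored unit; default chooses
#'   `max(values) / (2^31 - 1)` so the maximum fits the stored range.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  if (!inherits(grid, "dose_grid")) stop("write_rtdose: need a dose_grid",
                                         call. = FALSE)
  vals <- grid$values
  if (length(vals) == 0L) stop("write_rtdose: empty grid", call. = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("write_rtdose: dose must be finite and non-negative", call. = FALSE)
  }
  d <- dim(vals)
  if (is.null(scaling)) {
    scaling <- if (max(vals) > 0) max(vals) / (2^31 - 1) else 1
  }
  stored <- round(as.vector(vals) / scaling)
  if (any(stored > 2^31 - 1)) {
    stop("write_rtdose: scaling too small for stored range", call. = FALSE)
  }
  sop_uid <- new_uid()
  offsets <- (seq_len(d[3]) - 1) * grid$spacing[3]
  summation <- if (identical(grid$scope, "per-beam")) "BEAM" else "PLAN"

  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_ds(0x0020, 0x0032, grid$origin),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_us(0x0028, 0x0010, d[2]),          # Rows = y
    dcm_us(0x0028, 0x0011, d[1]),          # Columns = x
    dcm_ds(0x0028, 0x0030, c(grid$spacing[2], grid$spacing[1])),  # row\col
    dcm_us(0x0028, 0x0100, 32L),
    dcm_us(0x0028, 0x0101, 32L),
    dcm_us(0x0028, 0x0102, 31L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_str(0x3004, 0x0002, "CS", "GY"),
    dcm_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_str(0x3004, 0x000A, "CS", summation),
    dcm_ds(0x3004, 0x000C, offsets),
    dcm_str(0x3004, 0x000E, "DS", sprintf("%.16e", scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(as.integer(stored), raw(), size = 4L, endian = "little"))
  )

  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", UID_RTDOSE),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", UID_IMPL)
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", uint32le(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

read_u16 <- function(bytes, at) {
  sum(as.integer(bytes[at + 0:1]) * c(1, 256))
}

read_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at + 0:3]) * c(1, 256, 65536, 16777216))
}

#' Read a DICOM RT Dose file into a 3D dose grid
#'
#' Parses explicit-VR little-endian RT Dose objects (as produced by
#' [write_rtdose()] or any writer using standard tags). Stored integers are
#' multiplied by the dose-grid scaling to give Gy.
#'
#' @param path Path to the RT Dose file.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) > 132L &&
      rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  tags <- new.env(parent = emptyenv())
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- read_u16(bytes, pos)
    element <- read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("read_rtdose: not explicit-VR little endian", call. = FALSE)
    }
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      val_at <- pos + 8L
    }
    if (len == 4294967295) {
      stop("read_rtdose: undefined-length elements unsupported", call. = FALSE)
    }
    key <- sprintf("%04X,%04X", group, element)
    raw_val <- bytes[seq.int(val_at, length.out = len)]
    assign(key, list(vr = vr, raw = raw_val), envir = tags)
    pos <- val_at + len
  }
  get_tag <- function(key, required = TRUE) {
    if (!exists(key, envir = tags)) {
      if (required) stop(sprintf("read_rtdose: missing tag (%s)", key),
                         call. = FALSE)
      return(NULL)
    }
    get(key, envir = tags)
  }
  as_str <- function(tag) {
    trimws(rawToChar(tag$raw[tag$raw != as.raw(0L)]))  # strip NUL/space pad
  }
  as_ds <- function(tag) as.numeric(strsplit(as_str(tag), "\\\\")[[1]])
  as_us <- function(tag) read_u16(tag$raw, 1L)

  ts <- get_tag("0002,0010", required = FALSE)
  if (!is.null(ts) && as_str(ts) != UID_EXPLICIT_LE) {
    stop("read_rtdose: unsupported transfer syntax", call. = FALSE)
  }
  scaling_tag <- get_tag("3004,000E", required = FALSE)
  if (is.null(scaling_tag)) {
    stop("read_rtdose: missing dose-grid scaling", call. = FALSE)
  }
  scaling <- as.numeric(as_str(scaling_tag))
  rows <- as_us(get_tag("0028,0010"))
  cols <- as_us(get_tag("0028,0011"))
  nframes_tag <- get_tag("0028,0008", required = FALSE)
  nframes <- if (is.null(nframes_tag)) 1L else as.integer(as_str(nframes_tag))
  origin <- as_ds(get_tag("0020,0032"))
  spacing_rc <- as_ds(get_tag("0028,0030"))
  offsets <- as_ds(get_tag("3004,000C"))
  if (length(offsets) != nframes) {
    stop("read_rtdose: frame offset vector length mismatch", call. = FALSE)
  }
  dz <- if (nframes > 1L) diff(offsets) else 1
  if (nframes > 1L && diff(range(dz)) > 1e-6 * max(abs(dz))) {
    stop("read_rtdose: non-uniform frame offsets", call. = FALSE)
  }
  dz <- if (nframes > 1L) dz[1] else 1
  bits <- as_us(get_tag("0028,0100"))
  px <- get_tag("7FE0,0010")
  nvox <- as.integer(rows) * as.integer(cols) * nframes
  if (bits == 32L) {
    stored <- readBin(px$raw, "integer", n = nvox, size = 4L,
                      endian = "little")
    stored <- as.numeric(stored)
    stored[stored < 0] <- stored[stored < 0] + 2^32
  } else if (bits == 16L) {
    stored <- as.numeric(readBin(px$raw, "integer", n = nvox, size = 2L,
                                 signed = FALSE, endian = "little"))
  } else {
    stop("read_rtdose: unsupported bits allocated", call. = FALSE)
  }
  summation <- get_tag("3004,000A", required = FALSE)
  scope <- if (!is.null(summation) && as_str(summation) == "BEAM") {
    "per-beam"
  } else {
    "total"
  }
  vals <- array(stored * scaling, dim = c(cols, rows, nframes))
  dose_grid(vals, origin = origin,
            spacing = c(spacing_rc[2], spacing_rc[1], dz), scope = scope)
}
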