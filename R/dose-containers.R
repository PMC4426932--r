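#' 2D dose plane on a regular isocenter-plane grid
#'
#' A planar dose (or relative-intensity) distribution in the beam's-eye-view
#' isocenter plane. `values[iv, iu]` sits at crossplane
#' `u = origin[1] + (iu - 1) * spacing[1]` and inplane
#' `v = origin[2] + (iv - 1) * spacing[2]` (mm, pixel centers).
#'
#' @param values Numeric matrix, rows indexing inplane v, columns crossplane u.
#' @param origin Length-2 numeric, mm coordinate (u, v) of `values[1, 1]`.
#' @param spacing Length-2 numeric, mm grid step (du, dv); both > 0.
#' @return Object of class `dose_plane`.
#' @export
dose_plane <- function(values, origin, spacing) {
  values <- as.matrix(values)
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 2L, length(spacing) == 2L)
  if (any(spacing <= 0)) stop("dose_plane: spacing must be > 0", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("dose_plane: values must be finite", call. = FALSE)
  }
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %d x %d (v x u), origin (%.1f, %.1f) mm, spacing (%.2f, %.2f) mm\n",
              nrow(x$values), ncol(x$values), x$origin[1], x$origin[2],
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

plane_u <- function(p) p$origin[1] + (seq_len(ncol(p$values)) - 1) * p$spacing[1]
plane_v <- function(p) p$origin[2] + (seq_len(nrow(p$values)) - 1) * p$spacing[2]

#' Bilinear lookup in a dose plane
#'
#' Samples a [dose_plane()] at arbitrary (u, v) by bilinear interpolation.
#' Points outside the plane's extent return `outside` (default `NA`).
#'
#' @param plane A [dose_plane()].
#' @param u,v Numeric vectors of query coordinates in mm (recycled together).
#' @param outside Value returned outside the plane extent.
#' @return Numeric vector of interpolated values.
#' @export
plane_lookup <- function(plane, u, v, outside = NA_real_) {
  vals <- plane$values
  nu <- ncol(vals); nv <- nrow(vals)
  fu <- (u - plane$origin[1]) / plane$spacing[1] + 1
  fv <- (v - plane$origin[2]) / plane$spacing[2] + 1
  ok <- fu >= 1 & fu <= nu & fv >= 1 & fv <= nv
  out <- rep(outside, length(fu))
  if (!any(ok)) return(out)
  fu <- fu[ok]; fv <- fv[ok]
  iu <- pmin(floor(fu), nu - 1L); iv <- pmin(floor(fv), nv - 1L)
  iu <- pmax(iu, 1L); iv <- pmax(iv, 1L)
  du <- fu - iu; dv <- fv - iv
  v00 <- vals[cbind(iv, iu)]
  v01 <- vals[cbind(iv, iu + 1L)]
  v10 <- vals[cbind(iv + 1L, iu)]
  v11 <- vals[cbind(iv + 1L, iu + 1L)]
  out[ok] <- v00 * (1 - du) * (1 - dv) + v01 * du * (1 - dv) +
    v10 * (1 - du) * dv + v11 * du * dv
  out
}

#' 3D dose grid
#'
#' A regular 3D dose grid in patient coordinates (mm, isocenter origin).
#' `values[i, j, k]` sits at
#' `origin + (c(i, j, k) - 1) * spacing` along (x, y, z); doses are Gy.
#'
#' @param values Numeric 3D array of doses in Gy (non-negative).
#' @param origin Length-3 numeric, mm coordinate of voxel center `[1, 1, 1]`.
#' @param spacing Length-3 numeric, mm voxel size; all > 0.
#' @param scope `"per-beam"` or `"total"`.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing, scope = c("per-beam", "total")) {
  scope <- match.arg(scope)
  stopifnot(length(dim(values)) == 3L, length(origin) == 3L,
            length(spacing) == 3L)
  if (any(spacing <= 0)) stop("dose_grid: spacing must be > 0", call. = FALSE)
  if (any(values < 0)) stop("dose_grid: negative dose", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), scope = scope),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels (%s), spacing (%.1f, %.1f, %.1f) mm, max %.2f Gy\n",
              d[1], d[2], d[3], x$scope, x$spacing[1], x$spacing[2],
              x$spacing[3], max(x$values)))
  invisible(x)
}

#' Voxel-center coordinates of a dose grid
#'
#' @param grid A [dose_grid()].
#' @return An n x 3 matrix of (x, y, z) voxel-center coordinates in mm, in
#'   the storage order of `grid$values` (first index fastest).
#' @export
grid_voxel_centers <- function(grid) {
  d <- dim(grid$values)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  cbind(x = rep(xs, times = d[2] * d[3]),
        y = rep(rep(ys, each = d[1]), times = d[3]),
        z = rep(zs, each = d[1] * d[2]))
}

#' Read a plain-text dose plane
#'
#' The text dialect is two header lines -- `origin <u> <v>` then
#' `spacing <du> <dv>` (mm) -- followed by the value matrix, one inplane row
#' per line (crossplane u across columns), whitespace- or comma-delimited.
#'
#' @param path Path to the text file.
#' @return A [dose_plane()].
#' @export
read_text_plane <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("read_text_plane: truncated file", call. = FALSE)
  hdr_num <- function(line, what) {
    toks <- strsplit(trimws(gsub(",", " ", line)), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    vals <- vals[!is.na(vals)]
    if (length(vals) != 2L) {
      stop(sprintf("read_text_plane: bad %s header", what), call. = FALSE)
    }
    vals
  }
  origin <- hdr_num(lines[1], "origin")
  spacing <- hdr_num(lines[2], "spacing")
  rows <- lapply(lines[-(1:2)], function(l) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(gsub(",", " ", l)),
                                                 "\\s+")[[1]]))
    if (anyNA(vals)) stop("read_text_plane: non-numeric entry", call. = FALSE)
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("read_text_plane: ragged rows", call. = FALSE)
  }
  dose_plane(do.call(rbind, rows), origin, spacing)
}

#' Write a dose plane in the plain-text dialect
#'
#' @param plane A [dose_plane()].
#' @param path Output path.
#' @param digits Significant digits written (default 17, lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_text_plane <- function(plane, path, digits = 17) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "g")
  writeLines(c(paste("origin", sprintf(fmt, plane$origin[1]),
                     sprintf(fmt, plane$origin[2])),
               paste("spacing", sprintf(fmt, plane$spacing[1]),
                     sprintf(fmt, plane$spacing[2]))), con)
  writeLines(apply(plane$values, 1L,
                   function(r) paste(sprintf(fmt, r), collapse = " ")), con)
  invisible(path)
}
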