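#' EPID portal image
#'
#' A single portal-imager exposure. `pixels[row, col]` has detector-plane
#' coordinates `u_det = (col - center) * pitch` (crossplane, MLC leaf
#' travel) and `v_det = (row - center) * pitch` (inplane, leaf width), with
#' the physical panel center at row = col = `(npix / 2)` (1-based; 512 for
#' the 1024-pixel panel). Isocenter-scale positions are `u_det * sad / sid`.
#'
#' @param pixels Non-negative numeric matrix of pixel intensities
#'   (arbitrary linear units).
#' @param pitch Pixel pitch in mm at the detector plane (> 0).
#' @param sid Source-imager distance in mm.
#' @param gantry_angle Gantry angle in degrees at acquisition.
#' @param reticle_offset List with `rotation` (degrees) and `translation`
#'   (length-2, pixels, (row, col)) of the reticule cross relative to the
#'   panel center.
#' @return Object of class `epid_image`.
#' @export
epid_image <- function(pixels, pitch = 0.40, sid = 1500, gantry_angle = 0,
                       reticle_offset = list(rotation = 0,
                                             translation = c(0, 0))) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("epid_image: negative pixels", call. = FALSE)
  if (pitch <= 0) stop("epid_image: pitch must be > 0", call. = FALSE)
  structure(list(pixels = pixels, pitch = pitch, sid = sid,
                 gantry_angle = gantry_angle,
                 reticle_offset = reticle_offset),
            class = "epid_image")
}

epid_center <- function(img) dim(img$pixels) / 2

#' Sum exposures into a composite non-gap image
#'
#' Per-pixel arithmetic sum of a list of exposures sharing pitch, SID,
#' gantry angle and shape (linear detector response assumed, so summing
#' strip exposures reproduces the dose of the composed open field).
#'
#' @param exposures List of [epid_image()] objects.
#' @return Object of class `composite_image` (fields as `epid_image` plus
#'   `n_exposures`).
#' @export
build_composite <- function(exposures) {
  if (length(exposures) < 1L) {
    stop("build_composite: empty exposure list", call. = FALSE)
  }
  ref <- exposures[[1]]
  for (e in exposures[-1]) {
    if (!identical(dim(e$pixels), dim(ref$pixels)) ||
        e$pitch != ref$pitch || e$sid != ref$sid ||
        e$gantry_angle != ref$gantry_angle) {
      stop("build_composite: exposures disagree in shape or metadata",
           call. = FALSE)
    }
  }
  px <- Reduce(`+`, lapply(exposures, function(e) e$pixels))
  structure(list(pixels = px, pitch = ref$pitch, sid = ref$sid,
                 gantry_angle = ref$gantry_angle,
                 n_exposures = length(exposures)),
            class = c("composite_image", "epid_image"))
}

#' Correct the reticule offset of a portal image
#'
#' The reticule (two orthogonal tungsten wires marking the beam axis) does
#' not project exactly onto the physical panel center; the measured offset
#' is a rotation about the center plus a pixel translation. This resamples
#' the image (bilinear) so the reticule cross-point lands on the center
#' pixel, and zeroes the stored offset.
#'
#' @param image An [epid_image()] with its `reticle_offset` filled in.
#' @return The corrected [epid_image()].
#' @export
correct_reticle_offset <- function(image) {
  off <- image$reticle_offset
  rot <- off$rotation
  tr <- off$translation
  if (sqrt(sum(tr^2)) > 50) {
    warning("correct_reticle_offset: offset larger than 50 px; applying anyway")
  }
  if (rot == 0 && all(tr == 0)) {
    image$reticle_offset <- list(rotation = 0, translation = c(0, 0))
    return(image)
  }
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  ctr <- epid_center(image)
  # observed = rotate(ideal about center) then translate; invert by sampling
  # the observed image at rotate(p - center) + center + translation
  ct <- cospi(rot / 180); st <- sinpi(rot / 180)  # exact at right angles
  rowg <- rep(seq_len(nr), times = nc) - ctr[1]
  colg <- rep(seq_len(nc), each = nr) - ctr[2]
  src_r <- ct * rowg - st * colg + ctr[1] + tr[1]
  src_c <- st * rowg + ct * colg + ctr[2] + tr[2]
  image$pixels <- matrix(bilinear_sample(px, src_r, src_c), nr, nc)
  image$reticle_offset <- list(rotation = 0, translation = c(0, 0))
  image
}

# Bilinear sample of a matrix at fractional (row, col); 0 outside.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  i <- pmax(pmin(floor(r), nr - 1L), 1L)
  j <- pmax(pmin(floor(c), nc - 1L), 1L)
  dr <- r - i; dc <- c - j
  out[ok] <- m[cbind(i, j)] * (1 - dr) * (1 - dc) +
    m[cbind(i, j + 1L)] * (1 - dr) * dc +
    m[cbind(i + 1L, j)] * dr * (1 - dc) +
    m[cbind(i + 1L, j + 1L)] * dr * dc
  out
}

#' Measure radiation field size by full width at half maximum
#'
#' Takes the crossplane intensity profile at a leaf pair's center (averaged
#' over the central 5 mm of the leaf width), references the half-maximum to
#' the plateau mean over the central 50 % of the nominal field, and finds
#' each field edge as the 50 % crossing by linear sub-pixel interpolation,
#' scanning from outside the field inward. Edge positions are reported at
#' isocenter scale (multiplied by sad/sid).
#'
#' @param image A reticule-corrected [epid_image()] or composite.
#' @param nominal_half_sizes Length-2 numeric `(X1, X2)`: nominal half field
#'   sizes in mm at isocenter on the negative-u and positive-u sides.
#' @param leaf_index Integer vector of leaf pairs to analyse (1-based).
#' @param n_leaves,leaf_width MLC bank layout (defaults 19 leaves of 10 mm).
#' @param geometry An [rt_geometry()]; its `sad` and the image `sid` set the
#'   isocenter magnification.
#' @return A data.frame of class `field_size_result` with columns `leaf`,
#'   `x1_edge`, `x2_edge` (mm), `x1_error`, `x2_error` (mm; positive means
#'   the opening is larger than nominal) and `size` (mm).
#' @export
measure_field_size <- function(image, nominal_half_sizes, leaf_index,
                               n_leaves = 19, leaf_width = 10,
                               geometry = rt_geometry()) {
  mag <- image$sid / geometry$sad
  ctr <- epid_center(image)
  u_iso <- (seq_len(ncol(image$pixels)) - ctr[2]) * image$pitch / mag
  v_iso <- (seq_len(nrow(image$pixels)) - ctr[1]) * image$pitch / mag
  x1 <- nominal_half_sizes[1]; x2 <- nominal_half_sizes[2]
  res <- lapply(leaf_index, function(li) {
    v_leaf <- (li - (n_leaves + 1) / 2) * leaf_width
    rows <- which(abs(v_iso - v_leaf) <= 2.5)
    if (length(rows) == 0L) {
      stop("measure_field_size: leaf row outside image", call. = FALSE)
    }
    prof <- colMeans(image$pixels[rows, , drop = FALSE])
    plateau_cols <- which(u_iso >= -x1 / 2 & u_iso <= x2 / 2)
    half <- mean(prof[plateau_cols]) / 2
    cross_in <- function(idx) {
      below <- prof[idx] < half
      hit <- which(below[-length(idx)] & !below[-1])
      if (length(hit) == 0L) {
        stop("measure_field_size: no half-maximum crossing", call. = FALSE)
      }
      i <- idx[hit[1]]; j <- idx[hit[1] + 1L]
      frac <- (half - prof[i]) / (prof[j] - prof[i])
      u_iso[i] + frac * (u_iso[j] - u_iso[i])
    }
    left <- cross_in(seq_along(prof))              # scan left -> right
    right <- cross_in(rev(seq_along(prof)))        # scan right -> left
    data.frame(leaf = li, x1_edge = left, x2_edge = right,
               x1_error = abs(left) - x1, x2_error = abs(right) - x2,
               size = right - left)
  })
  out <- do.call(rbind, res)
  class(out) <- c("field_size_result", "data.frame")
  out
}
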