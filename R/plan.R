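#' Beam specification for step-and-shoot delivery
#'
#' One treatment beam: gantry angle, total monitor units (MU) and the list
#' of static MLC segments. Each segment carries its MU and the left/right
#' leaf-end positions per leaf pair, in mm at the isocenter plane.
#'
#' @param gantry_angle Gantry angle in degrees, IEC 61217, in `[0, 360)`.
#' @param beam_mu Total beam monitor units.
#' @param segments List of segments; each a list with `mu` (numeric) and
#'   `leaves` (n_leaves x 2 matrix, columns left/right leaf end in mm).
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(gantry_angle, beam_mu, segments) {
  if (gantry_angle < 0 || gantry_angle >= 360) {
    stop("beam_spec: gantry_angle must be in [0, 360)", call. = FALSE)
  }
  mu <- vapply(segments, function(s) s$mu, numeric(1))
  if (any(mu < 0)) stop("beam_spec: segment MU must be >= 0", call. = FALSE)
  if (abs(sum(mu) - beam_mu) > 1e-6) {
    stop("beam_spec: segment MUs must sum to beam_mu", call. = FALSE)
  }
  for (s in segments) {
    lv <- s$leaves
    if (!is.matrix(lv) || ncol(lv) != 2L || any(lv[, 2] < lv[, 1])) {
      stop("beam_spec: leaves must be an n x 2 matrix with right >= left",
           call. = FALSE)
    }
  }
  structure(list(gantry_angle = gantry_angle, beam_mu = beam_mu,
                 segments = segments),
            class = "beam_spec")
}

#' Treatment plan specification
#'
#' @param beams List of [beam_spec()] objects (at least one).
#' @param prescription_dose Prescribed dose in Gy (> 0).
#' @param fractions Number of fractions.
#' @return Object of class `plan_spec`.
#' @export
plan_spec <- function(beams, prescription_dose, fractions) {
  if (length(beams) < 1L) stop("plan_spec: need >= 1 beam", call. = FALSE)
  if (prescription_dose <= 0) {
    stop("plan_spec: prescription_dose must be > 0", call. = FALSE)
  }
  structure(list(beams = beams, prescription_dose = prescription_dose,
                 fractions = as.integer(fractions)),
            class = "plan_spec")
}

#' Structure set: named stacks of closed planar contours
#'
#' Each structure is a list of axial contours; a contour is a list with `z`
#' (slice position, mm) and `xy` (n x 2 matrix of vertices, mm; closed
#' implicitly, the last vertex need not repeat the first).
#'
#' @param structures Named list of structures as described above.
#' @return Object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  nm <- names(structures)
  if (is.null(nm) || anyDuplicated(nm)) {
    stop("structure_set: structures must have unique names", call. = FALSE)
  }
  for (s in structures) {
    for (ctr in s) {
      if (!is.matrix(ctr$xy) || ncol(ctr$xy) != 2L || nrow(ctr$xy) < 3L) {
        stop("structure_set: each contour needs an n x 2 matrix, n >= 3",
             call. = FALSE)
      }
    }
  }
  structure(list(structures = structures), class = "structure_set")
}

#' Rasterize one structure onto a dose grid
#'
#' Voxel-center-in-polygon test (even-odd rule) per axial slice: a voxel
#' belongs to the structure when its center lies inside an odd number of
#' that slice's contours. Contours are matched to the grid slice whose z is
#' nearest within half a slice spacing.
#'
#' @param sset A [structure_set()].
#' @param name Structure name.
#' @param grid A [dose_grid()].
#' @return Logical array with the dimensions of `grid$values`.
#' @export
structure_mask <- function(sset, name, grid) {
  if (!name %in% names(sset$structures)) {
    stop(sprintf("structure_mask: unknown structure '%s'", name),
         call. = FALSE)
  }
  d <- dim(grid$values)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  mask <- array(FALSE, dim = d)
  pts <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]))
  for (ctr in sset$structures[[name]]) {
    k <- which.min(abs(zs - ctr$z))
    if (abs(zs[k] - ctr$z) > grid$spacing[3] / 2 + 1e-9) next
    inside <- point_in_polygon(pts, ctr$xy)
    mask[, , k] <- xor(mask[, , k], matrix(inside, d[1], d[2]))
  }
  mask
}

# Even-odd crossing-number test, vectorized over points.
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
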