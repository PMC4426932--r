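#' Segmented intensity map of one beam
#'
#' Per-beam relative intensity on a 1-mm isocenter-plane grid together with
#' the MLC leaf-row layout, as exported after leaf segmentation. Segment
#' boundaries appear as intensity steps along the leaf-travel direction.
#'
#' @param plane A [dose_plane()] of relative intensities (>= 0).
#' @param n_leaves,leaf_width Leaf-bank layout (defaults 19 rows of 10 mm).
#' @return Object of class `segment_intensity_map`.
#' @export
segment_intensity_map <- function(plane, n_leaves = 19, leaf_width = 10) {
  if (any(plane$values < 0)) {
    stop("segment_intensity_map: intensities must be >= 0", call. = FALSE)
  }
  structure(list(plane = plane, n_leaves = n_leaves, leaf_width = leaf_width),
            class = "segment_intensity_map")
}

leaf_v_span <- function(leaf, n_leaves, leaf_width) {
  center <- (leaf - (n_leaves + 1) / 2) * leaf_width
  c(center - leaf_width / 2, center + leaf_width / 2)
}

#' 2D measured-vs-planned fractional error map
#'
#' Interpolates the measured plane (possibly a sparse diode-array grid)
#' bilinearly onto the planned grid and forms the fractional error
#' `e = (measured - planned) / planned` wherever the planned dose is at
#' least `threshold_frac` of its maximum and a measured value is available;
#' elsewhere `e = 0` with the validity mask false.
#'
#' @param planned A [dose_plane()] on the analysis (1-mm) grid.
#' @param measured A [dose_plane()]; may be coarser (e.g. 7-mm diode pitch).
#' @param threshold_frac Low-dose cutoff as a fraction of the planned
#'   maximum (default 0.10).
#' @return Object of class `error_map`: list with `e` (matrix), `mask`
#'   (logical matrix), `origin`, `spacing` matching the planned grid.
#' @export
compute_error_map <- function(planned, measured, threshold_frac = 0.10) {
  u <- plane_u(planned); v <- plane_v(planned)
  uu <- rep(u, each = length(v))
  vv <- rep(v, times = length(u))
  m <- matrix(plane_lookup(measured, uu, vv, outside = NA_real_),
              nrow = length(v), ncol = length(u))
  if (all(is.na(m))) {
    stop("compute_error_map: planned and measured planes do not overlap",
         call. = FALSE)
  }
  p <- planned$values
  mask <- !is.na(m) & p >= threshold_frac * max(p) & p > 0
  e <- matrix(0, nrow(p), ncol(p))
  e[mask] <- (m[mask] - p[mask]) / p[mask]
  structure(list(e = e, mask = mask, origin = planned$origin,
                 spacing = planned$spacing),
            class = "error_map")
}

#' Detect MLC abutment positions on a segmented intensity map
#'
#' Scans each leaf row's intensity profile at the map resolution along the
#' leaf-travel direction; adjacent-sample differences of at least
#' `threshold_frac` of the beam's maximum intensity mark an abutment at the
#' step midpoint. Steps closer than `merge_mm` are merged
#' (magnitude-weighted). Each abutment is annotated with the MU fraction of
#' the segment whose leaf end lies within `match_mm` of it.
#'
#' @param simap A [segment_intensity_map()].
#' @param beam A [beam_spec()] providing segment MUs and leaf ends.
#' @param threshold_frac Step threshold as a fraction of the beam maximum
#'   intensity (default 0.01).
#' @param merge_mm Steps within this distance are merged (default 1).
#' @param match_mm Leaf-end matching tolerance in mm (default 1.5).
#' @return Object of class `abutment_set`: data.frame with columns `leaf`,
#'   `x_mm`, `mu_fraction`, `segment` (NA when unmatched). May be empty.
#' @export
detect_abutments <- function(simap, beam, threshold_frac = 0.01,
                             merge_mm = 1, match_mm = 1.5) {
  plane <- simap$plane
  u <- plane_u(plane); v <- plane_v(plane)
  imax <- max(plane$values)
  rows_out <- list()
  for (leaf in seq_len(simap$n_leaves)) {
    span <- leaf_v_span(leaf, simap$n_leaves, simap$leaf_width)
    rows <- which(v >= span[1] & v < span[2])
    if (length(rows) == 0L) next
    prof <- colMeans(plane$values[rows, , drop = FALSE])
    d <- diff(prof)
    cand <- which(abs(d) >= threshold_frac * imax)
    if (length(cand) == 0L) next
    mid <- (u[cand] + u[cand + 1L]) / 2
    w <- abs(d[cand])
    # merge runs of candidates closer than merge_mm
    grp <- cumsum(c(TRUE, diff(mid) > merge_mm))
    pos <- vapply(split(seq_along(mid), grp), function(ii) {
      sum(mid[ii] * w[ii]) / sum(w[ii])
    }, numeric(1))
    for (p0 in pos) {
      seg_id <- NA_integer_; best <- match_mm
      for (si in seq_along(beam$segments)) {
        lv <- beam$segments[[si]]$leaves
        if (leaf > nrow(lv)) next
        dmin <- min(abs(lv[leaf, ] - p0))
        if (dmin <= best) {
          best <- dmin
          seg_id <- si
        }
      }
      muf <- if (is.na(seg_id)) NA_real_ else {
        beam$segments[[seg_id]]$mu / beam$beam_mu
      }
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(leaf = leaf, x_mm = p0, mu_fraction = muf,
                   segment = seg_id)
    }
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else {
    data.frame(leaf = integer(), x_mm = numeric(),
               mu_fraction = numeric(), segment = integer())
  }
  rownames(out) <- NULL
  structure(out, class = c("abutment_set", "data.frame"))
}

#' Inject gantry-angle corrections into an error map
#'
#' For each detected abutment at (leaf, x) the table delta
#' `gac_at(table, angle, leaf, x)`, weighted by the abutment's segment MU
#' fraction, is added to the fractional error over a band of width
#' `band_width` centered on the abutment column, restricted to that leaf's
#' row span and to the valid mask. Everything else is unchanged.
#'
#' @param emap A [compute_error_map()] result.
#' @param abutments A [detect_abutments()] result.
#' @param table A [build_gac_table()] result.
#' @param gantry_angle Beam gantry angle in degrees.
#' @param band_width Correction band width in mm (default 2).
#' @param n_leaves,leaf_width Leaf layout used to bound the band rows.
#' @return The corrected `error_map`.
#' @export
apply_gac <- function(emap, abutments, table, gantry_angle, band_width = 2,
                      n_leaves = 19, leaf_width = 10) {
  if (nrow(abutments) == 0L) return(emap)
  nu <- ncol(emap$e); nv <- nrow(emap$e)
  u <- emap$origin[1] + (seq_len(nu) - 1) * emap$spacing[1]
  v <- emap$origin[2] + (seq_len(nv) - 1) * emap$spacing[2]
  for (i in seq_len(nrow(abutments))) {
    muf <- abutments$mu_fraction[i]
    if (is.na(muf)) {
      warning("apply_gac: abutment without a matched segment skipped")
      next
    }
    g <- gac_at(table, gantry_angle, abutments$leaf[i], abutments$x_mm[i]) *
      muf
    if (g == 0) next
    cols <- which(abs(u - abutments$x_mm[i]) <= band_width / 2)
    span <- leaf_v_span(abutments$leaf[i], n_leaves, leaf_width)
    rows <- which(v >= span[1] & v < span[2])
    if (length(cols) == 0L || length(rows) == 0L) next
    sel <- emap$mask[rows, cols, drop = FALSE]
    emap$e[rows, cols][sel] <- emap$e[rows, cols][sel] + g
  }
  emap
}

#' Back-project a 2D error map onto a per-beam 3D dose grid
#'
#' Every voxel center is projected into the beam's-eye-view isocenter plane
#' ([project_voxel_to_bev()]); the corrected dose is the planned dose
#' multiplied by `1 + e(u, v)` with bilinear lookup of the error map
#' (`e = 0` outside the map or off its mask). The single-plane error is
#' applied along the whole diverging ray: depth dependence of the
#' measurement is deliberately not modeled.
#'
#' @param emap A (possibly GAC-corrected) `error_map`.
#' @param beam_dose Per-beam planned [dose_grid()].
#' @param gantry_angle Beam gantry angle in degrees.
#' @param geometry An [rt_geometry()].
#' @return The corrected per-beam [dose_grid()].
#' @export
backproject <- function(emap, beam_dose, gantry_angle,
                        geometry = rt_geometry()) {
  centers <- grid_voxel_centers(beam_dose)
  uv <- project_voxel_to_bev(centers, gantry_angle, geometry)
  eplane <- dose_plane(emap$e, emap$origin, emap$spacing)
  ev <- plane_lookup(eplane, uv[, 1], uv[, 2], outside = 0)
  vals <- beam_dose$values * array(1 + ev, dim = dim(beam_dose$values))
  dose_grid(vals, beam_dose$origin, beam_dose$spacing, scope = "per-beam")
}

#' Predict the delivered 3D dose with or without gantry-angle correction
#'
#' Runs the whole chain per beam -- fractional error map from planned vs
#' measured planes, optional GAC injection at the abutments detected on the
#' segmented intensity map, back-projection onto the per-beam planned 3D
#' grid -- and sums the corrected per-beam grids into the predicted total.
#'
#' @param plan A [plan_spec()].
#' @param planned_planes,measured_planes,simaps,beam_grids Per-beam lists,
#'   aligned with `plan$beams`: planned [dose_plane()]s, measured planes,
#'   [segment_intensity_map()]s, and planned per-beam [dose_grid()]s.
#' @param table A [build_gac_table()] result (ignored when `use_gac` is
#'   FALSE).
#' @param use_gac Logical: inject gantry-angle corrections?
#' @param band_width Correction band width in mm, see [apply_gac()].
#' @param threshold_frac Low-dose cutoff for the error maps.
#' @param geometry An [rt_geometry()].
#' @return The predicted total [dose_grid()] (`scope = "total"`).
#' @export
predict_dose <- function(plan, planned_planes, measured_planes, simaps,
                         beam_grids, table = NULL, use_gac = TRUE,
                         band_width = 2, threshold_frac = 0.10,
                         geometry = rt_geometry()) {
  nb <- length(plan$beams)
  if (length(planned_planes) != nb || length(measured_planes) != nb ||
      length(beam_grids) != nb || (use_gac && length(simaps) != nb)) {
    stop("predict_dose: per-beam inputs do not match the plan's beam count",
         call. = FALSE)
  }
  if (use_gac && is.null(table)) {
    stop("predict_dose: use_gac = TRUE requires a gac_table", call. = FALSE)
  }
  total <- NULL
  for (i in seq_len(nb)) {
    beam <- plan$beams[[i]]
    emap <- compute_error_map(planned_planes[[i]], measured_planes[[i]],
                              threshold_frac = threshold_frac)
    if (use_gac) {
      ab <- detect_abutments(simaps[[i]], beam)
      emap <- apply_gac(emap, ab, table, beam$gantry_angle,
                        band_width = band_width)
    }
    corrected <- backproject(emap, beam_grids[[i]], beam$gantry_angle,
                             geometry)
    if (is.null(total)) {
      total <- corrected$values
      origin <- corrected$origin; spacing <- corrected$spacing
    } else {
      if (!isTRUE(all.equal(origin, corrected$origin)) ||
          !isTRUE(all.equal(spacing, corrected$spacing))) {
        stop("predict_dose: per-beam grids are not co-registered",
             call. = FALSE)
      }
      total <- total + corrected$values
    }
  }
  dose_grid(total, origin, spacing, scope = "total")
}
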