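eval_points <- function(x) {
  if (inherits(x, "dose_plane")) {
    u <- plane_u(x); v <- plane_v(x)
    list(coords = cbind(rep(u, each = nrow(x$values)),
                        rep(v, times = ncol(x$values))),
         values = as.vector(x$values), dim = dim(x$values), ndim = 2L)
  } else if (inherits(x, "dose_grid")) {
    list(coords = grid_voxel_centers(x), values = as.vector(x$values),
         dim = dim(x$values), ndim = 3L)
  } else {
    stop("expected a dose_plane or dose_grid", call. = FALSE)
  }
}

# Trilinear lookup in a dose grid; NA outside.
grid_lookup <- function(grid, pts) {
  d <- dim(grid$values)
  f <- sweep(sweep(pts, 2L, grid$origin), 2L, grid$spacing, `/`) + 1
  ok <- f[, 1] >= 1 & f[, 1] <= d[1] & f[, 2] >= 1 & f[, 2] <= d[2] &
    f[, 3] >= 1 & f[, 3] <= d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmax(pmin(floor(f), rep(d - 1L, each = nrow(f))), 1L)
  fr <- f - i0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
      (if (cy) fr[, 2] else 1 - fr[, 2]) *
      (if (cz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * grid$values[cbind(i0[, 1] + cx, i0[, 2] + cy,
                                       i0[, 3] + cz)]
  }
  out[ok] <- acc
  out
}

dist_lookup <- function(x, pts) {
  if (inherits(x, "dose_plane")) {
    plane_lookup(x, pts[, 1], pts[, 2], outside = NA_real_)
  } else {
    grid_lookup(x, pts)
  }
}

offset_lattice <- function(ndim, step, radius) {
  ax <- seq(-floor(radius / step), floor(radius / step)) * step
  offs <- as.matrix(do.call(expand.grid, rep(list(ax), ndim)))
  d2 <- rowSums(offs^2)
  keep <- d2 <= radius^2 + 1e-12
  offs <- offs[keep, , drop = FALSE]
  offs[order(d2[keep]), , drop = FALSE]
}

#' Gamma-index comparison of two dose distributions
#'
#' Computes the gamma index of `evaluated` against `reference` (2D planes
#' or 3D grids) with global normalization: the dose tolerance is
#' `dose_pct` % of the reference maximum, the spatial tolerance is `dta_mm`
#' mm. For every reference point at or above the low-dose threshold,
#' `gamma = min over search offsets of sqrt((dd/delta)^2 + (dr/dta)^2)`
#' where the evaluated distribution is interpolated (bi-/trilinear) on a
#' search lattice of step `step` out to `radius`. Offsets are visited in
#' order of increasing distance with early termination, which is exactly
#' equivalent to the exhaustive search over the same lattice.
#'
#' @param reference,evaluated Two [dose_plane()]s or two [dose_grid()]s on
#'   overlapping extents. Gamma is not symmetric: `reference` supplies the
#'   evaluation points and the normalization.
#' @param dose_pct Dose-difference criterion in % of the reference maximum.
#' @param dta_mm Distance-to-agreement criterion in mm.
#' @param threshold_pct Low-dose threshold in % of the reference maximum;
#'   points below it get `NA` gamma and are excluded from the pass rate.
#' @param step Search lattice step in mm (default `dta_mm / 10`).
#' @param radius Search radius in mm (default `3 * dta_mm`).
#' @return Object of class `gamma_result`: list with `gamma` (array shaped
#'   like the reference values, `NA` below threshold), `pass_rate` (% of
#'   evaluated points with gamma <= 1) and the criteria used.
#' @export
gamma_map <- function(reference, evaluated, dose_pct, dta_mm,
                      threshold_pct = 10, step = dta_mm / 10,
                      radius = 3 * dta_mm) {
  ref <- eval_points(reference)
  refmax <- max(ref$values)
  if (refmax <= 0) stop("gamma_map: reference maximum must be > 0",
                        call. = FALSE)
  delta <- dose_pct / 100 * refmax
  sel <- which(ref$values >= threshold_pct / 100 * refmax)
  if (length(sel) == 0L) stop("gamma_map: no points above threshold",
                              call. = FALSE)
  pts <- ref$coords[sel, , drop = FALSE]
  dref <- ref$values[sel]
  offs <- offset_lattice(ref$ndim, step, radius)
  g2 <- rep(Inf, length(sel))
  active <- seq_along(sel)
  any_eval <- FALSE
  for (k in seq_len(nrow(offs))) {
    r2 <- sum(offs[k, ]^2) / dta_mm^2
    active <- active[g2[active] > r2]
    if (length(active) == 0L) break
    q <- sweep(pts[active, , drop = FALSE], 2L, offs[k, ], `+`)
    ev <- dist_lookup(evaluated, q)
    okk <- !is.na(ev)
    if (any(okk)) {
      any_eval <- TRUE
      idx <- active[okk]
      cand <- r2 + ((ev[okk] - dref[idx]) / delta)^2
      g2[idx] <- pmin(g2[idx], cand)
    }
  }
  if (!any_eval && all(!is.finite(g2))) {
    stop("gamma_map: reference and evaluated distributions do not overlap",
         call. = FALSE)
  }
  gam <- rep(NA_real_, length(ref$values))
  gam[sel] <- sqrt(g2)
  dim(gam) <- ref$dim
  finite <- is.finite(g2)
  pass <- 100 * mean(sqrt(g2[finite]) <= 1 + 1e-9)
  structure(list(gamma = gam, pass_rate = pass,
                 criteria = list(dose_pct = dose_pct, dta_mm = dta_mm,
                                 threshold_pct = threshold_pct,
                                 step = step, radius = radius)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (threshold %g%%): pass rate %.1f%%\n",
              x$criteria$dose_pct, x$criteria$dta_mm,
              x$criteria$threshold_pct, x$pass_rate))
  invisible(x)
}

#' Signed relative dose-difference map
#'
#' `(evaluated - reference) / max(reference) * 100` (global normalization),
#' with `NA` below the low-dose threshold. The evaluated distribution is
#' interpolated onto the reference geometry.
#'
#' @inheritParams gamma_map
#' @return List of class `dose_diff_map` with `values` (% difference, shaped
#'   like the reference), and the reference `origin`/`spacing` when planar.
#' @export
dose_difference_map <- function(reference, evaluated, threshold_pct = 10) {
  ref <- eval_points(reference)
  refmax <- max(ref$values)
  ev <- dist_lookup(evaluated, ref$coords)
  out <- (ev - ref$values) / refmax * 100
  out[ref$values < threshold_pct / 100 * refmax] <- NA_real_
  dim(out) <- ref$dim
  structure(list(values = out,
                 origin = if (ref$ndim == 2L) reference$origin else NULL,
                 spacing = if (ref$ndim == 2L) reference$spacing else NULL),
            class = "dose_diff_map")
}

#' Distance-to-agreement map
#'
#' For each reference point, the distance to the nearest location where the
#' evaluated distribution takes the same dose value, found on a search
#' lattice of step `step`: agreement holds where the interpolated evaluated
#' dose is within `tol_frac` of the reference maximum of the point's dose,
#' or where it brackets that dose between adjacent lattice samples (a level
#' crossing inside a lattice cell). Distances are capped at
#' `search_radius`.
#'
#' @param reference,evaluated Two [dose_plane()]s on overlapping extents.
#' @param search_radius Cap and search extent in mm.
#' @param step Search lattice step in mm (default 0.5).
#' @param tol_frac Dose-agreement tolerance as a fraction of the reference
#'   maximum (default 0.001).
#' @return Matrix of DTA values (mm) shaped like the reference values.
#' @export
dta_map <- function(reference, evaluated, search_radius = 10, step = 0.5,
                    tol_frac = 0.001) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"))
  tol <- tol_frac * max(reference$values)
  ru <- plane_u(reference); rv <- plane_v(reference)
  lu <- seq(min(ru) - search_radius, max(ru) + search_radius, by = step)
  lv <- seq(min(rv) - search_radius, max(rv) + search_radius, by = step)
  lat <- matrix(plane_lookup(evaluated, rep(lu, each = length(lv)),
                             rep(lv, times = length(lu)), outside = NA_real_),
                nrow = length(lv), ncol = length(lu))
  # bracketing ranges between horizontally / vertically adjacent samples
  hmin <- pmin(lat[, -ncol(lat)], lat[, -1])
  hmax <- pmax(lat[, -ncol(lat)], lat[, -1])
  vmin <- pmin(lat[-nrow(lat), ], lat[-1, ])
  vmax <- pmax(lat[-nrow(lat), ], lat[-1, ])
  out <- matrix(search_radius, nrow(reference$values), ncol(reference$values))
  for (iv in seq_along(rv)) for (iu in seq_along(ru)) {
    d0 <- reference$values[iv, iu]
    ju <- which(abs(lu - ru[iu]) <= search_radius)
    jv <- which(abs(lv - rv[iv]) <= search_radius)
    sub <- lat[jv, ju, drop = FALSE]
    agree <- !is.na(sub) & abs(sub - d0) <= tol
    jh <- ju[ju < length(lu)]
    agree_h <- !is.na(hmin[jv, jh, drop = FALSE]) &
      hmin[jv, jh, drop = FALSE] <= d0 & d0 <= hmax[jv, jh, drop = FALSE]
    jw <- jv[jv < length(lv)]
    agree_v <- !is.na(vmin[jw, ju, drop = FALSE]) &
      vmin[jw, ju, drop = FALSE] <= d0 & d0 <= vmax[jw, ju, drop = FALSE]
    du <- lu[ju] - ru[iu]; dv <- lv[jv] - rv[iv]
    d2 <- outer(dv^2, du^2, `+`)
    cands <- c(d2[agree],
               (outer(dv^2, (lu[jh] + step / 2 - ru[iu])^2, `+`))[agree_h],
               (outer((lv[jw] + step / 2 - rv[iv])^2, du^2, `+`))[agree_v])
    if (length(cands)) {
      out[iv, iu] <- min(sqrt(min(cands)), search_radius)
    }
  }
  out
}

#' Dose-volume histogram indices of a structure
#'
#' `Dx` is the dose received by at least x % of the structure volume
#' (linear interpolation of the cumulative DVH of voxel doses); `VxGy` is
#' the percentage of structure voxels receiving at least x Gy.
#'
#' @param dose A [dose_grid()].
#' @param mask Logical array matching `dose$values` (e.g. from
#'   [structure_mask()]); must select at least one voxel.
#' @param d_pct Volume percentages for the Dx indices (default 98, 2, 95).
#' @param v_gy Dose levels in Gy for the VxGy indices (default 65, 40).
#' @return Object of class `dvh_indices`: named list with `D<x>` (Gy),
#'   `Dmean` (Gy) and `V<x>Gy` (%).
#' @export
dvh_indices <- function(dose, mask, d_pct = c(98, 2, 95), v_gy = c(65, 40)) {
  if (!any(mask)) stop("dvh_indices: empty structure mask", call. = FALSE)
  doses <- dose$values[mask]
  out <- list()
  for (x in d_pct) {
    out[[paste0("D", x)]] <- unname(stats::quantile(doses, 1 - x / 100,
                                                    type = 7))
  }
  out$Dmean <- mean(doses)
  for (x in v_gy) {
    out[[paste0("V", x, "Gy")]] <- 100 * mean(doses >= x)
  }
  structure(out, class = "dvh_indices")
}

#' Paired two-tailed Student's t comparison
#'
#' @param a,b Equal-length numeric vectors (paired observations, n >= 2).
#' @return Object of class `paired_comparison`: per-group means and sample
#'   SDs, the paired t statistic and the two-tailed p value.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired_comparison: length mismatch", call. = FALSE)
  }
  if (length(a) < 2L) stop("paired_comparison: need n >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    # constant differences: t.test refuses; the limit is well defined
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    tt <- list(statistic = tval, parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %.2f +/- %.2f vs %.2f +/- %.2f; t(%g) = %.3f, p = %.4g\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$df, x$t, x$p))
  invisible(x)
}
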