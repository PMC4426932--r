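#' Abutment sampling grid for the non-gap test
#'
#' Lays out the analysis geometry of the non-gap test: `n_strips` abutting
#' strips of `strip_width` mm tile the crossplane direction, so the MLC
#' abutment lines (A positions) sit at the internal strip junctions and the
#' open-field reference positions (B) at the strip centers; one row per MLC
#' leaf pair. The default (10 strips of 20 mm, 19 leaves of 10 mm) gives
#' 9 x 19 = 171 abutment positions, A at x in {-80, -60, ..., +80} mm and
#' B at x in {-90, -70, ..., +90} mm at isocenter.
#'
#' @param n_strips Number of abutting strips (>= 2).
#' @param strip_width Strip width in mm at isocenter (> 0).
#' @param n_leaves Number of MLC leaf pairs.
#' @param leaf_width Leaf width in mm at isocenter (> 0).
#' @param roi_u,roi_v Analysis ROI size in mm at isocenter: `roi_u` along
#'   leaf travel, `roi_v` along leaf width (defaults 10 x 5 mm).
#' @return Object of class `abutment_grid`.
#' @export
make_abutment_grid <- function(n_strips = 10, strip_width = 20,
                               n_leaves = 19, leaf_width = 10,
                               roi_u = 10, roi_v = 5) {
  if (n_strips < 2) stop("make_abutment_grid: need >= 2 strips", call. = FALSE)
  if (strip_width <= 0 || leaf_width <= 0) {
    stop("make_abutment_grid: widths must be > 0", call. = FALSE)
  }
  x_min <- -n_strips * strip_width / 2
  abutment_x <- x_min + seq_len(n_strips - 1) * strip_width
  b_x <- x_min + (seq_len(n_strips) - 0.5) * strip_width
  leaf_center_v <- (seq_len(n_leaves) - (n_leaves + 1) / 2) * leaf_width
  structure(list(abutment_x = abutment_x, b_x = b_x,
                 leaf_index = seq_len(n_leaves),
                 leaf_center_v = leaf_center_v,
                 strip_width = strip_width, leaf_width = leaf_width,
                 roi_u = roi_u, roi_v = roi_v),
            class = "abutment_grid")
}

roi_mean <- function(composite, u0, v0, roi_u, roi_v, geometry) {
  mag <- composite$sid / geometry$sad
  ctr <- epid_center(composite)
  u_iso <- (seq_len(ncol(composite$pixels)) - ctr[2]) * composite$pitch / mag
  v_iso <- (seq_len(nrow(composite$pixels)) - ctr[1]) * composite$pitch / mag
  cols <- which(abs(u_iso - u0) <= roi_u / 2)
  rows <- which(abs(v_iso - v0) <= roi_v / 2)
  if (length(cols) == 0L || length(rows) == 0L) {
    stop("compute_abutment_ratios: ROI outside composite", call. = FALSE)
  }
  mean(composite$pixels[rows, cols])
}

#' Per-abutment pixel-value ratios (A/B x 100) of a composite image
#'
#' For every (leaf, abutment) node, A is the mean pixel value in the ROI
#' centered on the abutment line at that leaf's center, and B is the mean
#' of the two flanking open-field (strip-center) ROI means; the reported
#' quantity is A/B x 100. Ratios above 100 indicate an overdose line at the
#' abutment, below 100 an underdose.
#'
#' @param composite A [build_composite()] result covering all ROIs.
#' @param grid An [make_abutment_grid()] layout.
#' @param geometry An [rt_geometry()].
#' @return Object of class `nongap_result`: a data.frame with columns
#'   `leaf`, `x_mm`, `ratio`, plus attributes `gantry_angle` and `grid`.
#' @export
compute_abutment_ratios <- function(composite, grid,
                                    geometry = rt_geometry()) {
  out <- expand.grid(leaf = grid$leaf_index, x_mm = grid$abutment_x,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$leaf, out$x_mm), , drop = FALSE]
  rownames(out) <- NULL
  ratio <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    v0 <- grid$leaf_center_v[out$leaf[i]]
    x0 <- out$x_mm[i]
    a <- roi_mean(composite, x0, v0, grid$roi_u, grid$roi_v, geometry)
    flank <- grid$b_x[order(abs(grid$b_x - x0))[1:2]]
    b <- mean(vapply(flank, function(bx) {
      roi_mean(composite, bx, v0, grid$roi_u, grid$roi_v, geometry)
    }, numeric(1)))
    if (b <= 0) {
      stop("compute_abutment_ratios: non-positive open-field reference",
           call. = FALSE)
    }
    ratio[i] <- a / b * 100
  }
  out$ratio <- ratio
  structure(out, gantry_angle = composite$gantry_angle, grid = grid,
            class = c("nongap_result", "data.frame"))
}

same_nongap_layout <- function(a, b) {
  isTRUE(all.equal(a$leaf, b$leaf)) && isTRUE(all.equal(a$x_mm, b$x_mm))
}

#' Reproducibility of the non-gap test: per-abutment coefficient of variation
#'
#' @param results List of >= 2 [compute_abutment_ratios()] results with
#'   identical grids and gantry angle (repeat acquisitions).
#' @return Data.frame with columns `leaf`, `x_mm`, `cov_percent`
#'   (sample SD / mean x 100).
#' @export
reproducibility_cov <- function(results) {
  if (length(results) < 2L) {
    stop("reproducibility_cov: need >= 2 replicates", call. = FALSE)
  }
  ref <- results[[1]]
  for (r in results[-1]) {
    if (!same_nongap_layout(ref, r) ||
        !identical(attr(ref, "gantry_angle"), attr(r, "gantry_angle"))) {
      stop("reproducibility_cov: replicates disagree in grid or angle",
           call. = FALSE)
    }
  }
  mat <- vapply(results, function(r) r$ratio, numeric(nrow(ref)))
  data.frame(leaf = ref$leaf, x_mm = ref$x_mm,
             cov_percent = apply(mat, 1L, stats::sd) /
               rowMeans(mat) * 100)
}
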