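#' Build a gantry-angle-correction (GAC) lookup table
#'
#' For every abutment node (leaf, x) and every measured gantry angle, the
#' pixel-ratio change relative to gantry 0 is mapped through the calibration
#' slope to a fractional dose delta:
#' `delta(theta) = slope * (ratio(theta) - ratio(0))`. The delta at the 0
#' degree reference is identically zero.
#'
#' @param nongap_by_angle Named list of [compute_abutment_ratios()] results;
#'   names are gantry angles in degrees and must include `"0"`.
#' @param conv A [fit_conversion()] result supplying the slope.
#' @return Object of class `gac_table`: list with `angles` (sorted degrees),
#'   `leaves`, `x_nodes` (mm) and `delta`, an `angles x leaves x x_nodes`
#'   array of fractional dose deltas.
#' @export
build_gac_table <- function(nongap_by_angle, conv) {
  angles <- as.numeric(names(nongap_by_angle))
  if (anyNA(angles)) {
    stop("build_gac_table: list names must be gantry angles", call. = FALSE)
  }
  if (anyDuplicated(angles)) {
    stop("build_gac_table: duplicate angles", call. = FALSE)
  }
  if (!any(angles == 0)) {
    stop("build_gac_table: missing the 0-degree reference result",
         call. = FALSE)
  }
  ord <- order(angles)
  angles <- angles[ord]
  results <- nongap_by_angle[ord]
  ref <- results[[which(angles == 0)]]
  for (r in results) {
    if (!same_nongap_layout(ref, r)) {
      stop("build_gac_table: abutment grids differ across angles",
           call. = FALSE)
    }
  }
  leaves <- sort(unique(ref$leaf))
  x_nodes <- sort(unique(ref$x_mm))
  delta <- array(0, dim = c(length(angles), length(leaves), length(x_nodes)),
                 dimnames = list(angle = angles, leaf = leaves, x = x_nodes))
  for (ai in seq_along(angles)) {
    dr <- results[[ai]]$ratio - ref$ratio
    dd <- ratio_delta_to_dose_delta(conv, dr)
    li <- match(results[[ai]]$leaf, leaves)
    xi <- match(results[[ai]]$x_mm, x_nodes)
    delta[cbind(ai, li, xi)] <- dd
  }
  delta[which(angles == 0), , ] <- 0  # exact reference identity
  structure(list(angles = angles, leaves = leaves, x_nodes = x_nodes,
                 delta = delta, reference_angle = 0),
            class = "gac_table")
}

#' @export
print.gac_table <- function(x, ...) {
  cat(sprintf("<gac_table> %d angles x %d leaves x %d abutment nodes; |delta| up to %.3f\n",
              length(x$angles), length(x$leaves), length(x$x_nodes),
              max(abs(x$delta))))
  invisible(x)
}

#' Query the GAC table at an arbitrary (angle, leaf, position)
#'
#' Linear interpolation in crossplane position between the two neighboring
#' abutment nodes of the same leaf (constant extrapolation beyond the
#' outermost nodes) and, for unmeasured gantry angles, linear interpolation
#' on the circle between the two adjacent measured angles (wrapping across
#' 360 degrees). Leaf rows are physically independent: no interpolation
#' across leaves.
#'
#' @param table A [build_gac_table()] result.
#' @param angle Gantry angle in degrees (any real; reduced mod 360).
#' @param leaf_index Leaf pair number present in the table.
#' @param x Crossplane position(s) in mm at isocenter.
#' @return Fractional dose delta(s), same length as `x`.
#' @export
gac_at <- function(table, angle, leaf_index, x) {
  li <- match(leaf_index, table$leaves)
  if (is.na(li)) stop("gac_at: unknown leaf", call. = FALSE)
  angle <- angle %% 360
  angs <- table$angles
  interp_x <- function(ai) {
    vals <- table$delta[ai, li, ]
    nodes <- table$x_nodes
    if (length(nodes) == 1L) return(rep(vals[1], length(x)))
    stats::approx(nodes, vals, xout = pmin(pmax(x, nodes[1]),
                                           nodes[length(nodes)]),
                  method = "linear", rule = 2)$y
  }
  hit <- which(abs(angs - angle) < 1e-9)
  if (length(hit) == 1L) return(interp_x(hit))
  if (length(angs) == 1L) return(interp_x(1L))
  lo <- max(which(angs <= angle), 0L)
  if (lo == 0L) {  # below the smallest measured angle: wrap backwards
    a_lo <- angs[length(angs)] - 360
    i_lo <- length(angs); i_hi <- 1L
    a_hi <- angs[1]
  } else if (lo == length(angs)) {  # above the largest: wrap forwards
    a_lo <- angs[lo]; i_lo <- lo
    i_hi <- 1L; a_hi <- angs[1] + 360
  } else {
    a_lo <- angs[lo]; i_lo <- lo
    i_hi <- lo + 1L; a_hi <- angs[i_hi]
  }
  w <- (angle - a_lo) / (a_hi - a_lo)
  (1 - w) * interp_x(i_lo) + w * interp_x(i_hi)
}

#' Serialize a GAC table to JSON
#'
#' @param table A [build_gac_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gac_table <- function(table, path) {
  obj <- list(angles = table$angles, leaves = table$leaves,
              x_nodes = table$x_nodes,
              delta = as.vector(table$delta),   # angle-major flattening
              delta_dim = dim(table$delta),
              reference_angle = table$reference_angle)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a GAC table from JSON
#'
#' @param path Path written by [write_gac_table()].
#' @return A `gac_table`.
#' @export
read_gac_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  angles <- as.numeric(obj$angles)
  leaves <- as.numeric(obj$leaves)
  x_nodes <- as.numeric(obj$x_nodes)
  delta <- array(as.numeric(obj$delta), dim = as.integer(obj$delta_dim),
                 dimnames = list(angle = angles, leaf = leaves, x = x_nodes))
  structure(list(angles = angles, leaves = leaves, x_nodes = x_nodes,
                 delta = delta,
                 reference_angle = as.numeric(obj$reference_angle)),
            class = "gac_table")
}
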