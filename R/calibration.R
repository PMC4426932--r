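#' Fit the pixel-ratio to dose-ratio conversion line
#'
#' Ordinary least-squares fit of film-derived relative dose ratios on EPID
#' pixel-value ratios (A/B x 100) across abutment positions, the linear
#' conversion that anchors the portal-imager non-gap test to absolute dose.
#' The fitted slope is the change in relative dose ratio per unit change in
#' pixel ratio; downstream corrections use only the slope, never the
#' intercept, because they work with pixel-ratio *differences* between
#' gantry angles.
#'
#' @param pairs Data.frame (or list coercible to one) with columns
#'   `pixel_ratio` (~100 scale) and `dose_ratio` (~1 scale); >= 3 rows.
#' @return Object of class `dose_conversion`: list with `slope`,
#'   `intercept`, `r` (Pearson correlation) and `n`.
#' @export
#' @examples
#' x <- c(90, 95, 100, 105, 110)
#' fit_conversion(data.frame(pixel_ratio = x,
#'                           dose_ratio = 0.0203 * x - 1.0153))
fit_conversion <- function(pairs) {
  pairs <- as.data.frame(pairs)
  x <- pairs$pixel_ratio
  y <- pairs$dose_ratio
  if (length(x) < 3L) stop("fit_conversion: need >= 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("fit_conversion: pairs must be finite and positive", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("fit_conversion: pixel ratios are all equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y),
                 n = length(x)),
            class = "dose_conversion")
}

#' @export
print.dose_conversion <- function(x, ...) {
  cat(sprintf("<dose_conversion> dose_ratio = %.4f * pixel_ratio %+.4f  (r = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Convert a pixel-ratio difference to a fractional dose change
#'
#' Applies only the slope of the fitted conversion: a pixel-ratio change of
#' `delta_ratio` units corresponds to a fractional relative-dose change of
#' `slope * delta_ratio` (multiply by 100 for percent). The intercept is
#' deliberately not used -- it cancels when differencing ratios between
#' gantry angles.
#'
#' @param conv A [fit_conversion()] result.
#' @param delta_ratio Numeric vector of pixel-ratio differences.
#' @return Fractional dose change(s).
#' @export
ratio_delta_to_dose_delta <- function(conv, delta_ratio) {
  if (!inherits(conv, "dose_conversion")) {
    stop("ratio_delta_to_dose_delta: need a dose_conversion", call. = FALSE)
  }
  conv$slope * delta_ratio
}
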