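# Independent oracles and small fixture builders shared across tests.

# Exhaustive gamma search: per reference point, scan ALL lattice offsets.
# Deliberately structured differently from gamma_map (point-major full scan
# vs offset-major pruned scan) while using the same search geometry.
oracle_gamma <- function(reference, evaluated, dose_pct, dta_mm,
                         threshold_pct = 10, step = dta_mm / 10,
                         radius = 3 * dta_mm) {
  vals <- reference$values
  refmax <- max(vals)
  delta <- dose_pct / 100 * refmax
  ax <- seq(-floor(radius / step), floor(radius / step)) * step
  offs <- expand.grid(du = ax, dv = ax)
  offs <- offs[offs$du^2 + offs$dv^2 <= radius^2 + 1e-12, ]
  us <- reference$origin[1] + (seq_len(ncol(vals)) - 1) * reference$spacing[1]
  vs <- reference$origin[2] + (seq_len(nrow(vals)) - 1) * reference$spacing[2]
  gam <- matrix(NA_real_, nrow(vals), ncol(vals))
  npass <- 0L; ntot <- 0L
  for (iv in seq_along(vs)) {
    for (iu in seq_along(us)) {
      d0 <- vals[iv, iu]
      if (d0 < threshold_pct / 100 * refmax) next
      evv <- plane_lookup(evaluated, us[iu] + offs$du, vs[iv] + offs$dv)
      gg <- sqrt((offs$du^2 + offs$dv^2) / dta_mm^2 + ((evv - d0) / delta)^2)
      gam[iv, iu] <- min(gg, na.rm = TRUE)
      ntot <- ntot + 1L
      if (gam[iv, iu] <= 1 + 1e-9) npass <- npass + 1L
    }
  }
  list(gamma = gam, pass_rate = 100 * npass / ntot)
}

# DVH quantile by direct sorting of the cumulative curve, no stats::quantile.
oracle_dx <- function(doses, x_pct) {
  s <- sort(doses)
  n <- length(s)
  # dose received by at least x% of volume == (1 - x/100) quantile of the
  # order statistics with linear interpolation
  h <- (n - 1) * (1 - x_pct / 100) + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Smooth random dose plane: low-order separable surface, positive.
random_smooth_plane <- function(n = 30, spacing = 1) {
  cu <- stats::runif(3, -1, 1)
  cv <- stats::runif(3, -1, 1)
  x <- seq(-1, 1, length.out = n)
  fu <- 1.5 + cu[1] * x + cu[2] * x^2 + cu[3] * sin(2 * x)
  fv <- 1.5 + cv[1] * x + cv[2] * x^2 + cv[3] * cos(2 * x)
  vals <- outer(abs(fv) + 0.2, abs(fu) + 0.2)
  dose_plane(vals / max(vals) * 2, c(0, 0), c(spacing, spacing))
}

# Per-case gamma pass rates (%) of the 15 step-and-shoot prostate cases,
# with / without gantry-angle correction at both criteria.
load_case_pass_rates <- function() {
  utils::read.csv(system.file("extdata", "passrates_15cases.csv",
                              package = "gacqa"))
}

eq1_pairs <- function() {
  x <- c(90, 95, 100, 105, 110)
  data.frame(pixel_ratio = x, dose_ratio = 0.0203 * x - 1.0153)
}
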