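# Seeded synthetic generators. Every generator is a pure function of its
# arguments: the RNG state is saved and restored, so the same seed always
# yields identical output and callers' RNG streams are untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Rising-falling edge profile: ~1 inside [lo, hi], error-function penumbra
# of width sigma, exactly 0.5 at the nominal edges.
edge_profile <- function(x, lo, hi, sigma) {
  0.5 * (erf((x - lo) / (sqrt(2) * sigma)) +
           erf((hi - x) / (sqrt(2) * sigma)))
}

#' Generate a synthetic open-field EPID image
#'
#' An error-function-penumbra rectangular field on the portal imager,
#' used both directly (field-size analysis) and as the building block of
#' the non-gap strips. Edge positions are specified at isocenter scale;
#' the half-maximum of the profile falls exactly on them.
#'
#' @param u_edges,v_edges Length-2 mm at isocenter: field edges along leaf
#'   travel (crossplane) and leaf width (inplane).
#' @param shift_u Rigid crossplane shift of the port in mm at isocenter.
#' @param penumbra_sigma Penumbra width (Gaussian sigma, mm at isocenter).
#' @param npix Panel size in pixels (square; default 1024).
#' @param pitch Detector pixel pitch in mm (default 0.40).
#' @param sid,sad Source-imager and source-axis distances in mm.
#' @param gantry_angle Stored gantry angle.
#' @param noise_sigma Per-pixel multiplicative Gaussian sigma (fraction,
#'   e.g. 0.01); 0 disables noise.
#' @param seed RNG seed (only used when `noise_sigma > 0`).
#' @return An [epid_image()].
#' @export
gen_open_field <- function(u_edges = c(-100, 100), v_edges = c(-100, 100),
                           shift_u = 0, penumbra_sigma = 1.5, npix = 1024,
                           pitch = 0.40, sid = 1500, sad = 1000,
                           gantry_angle = 0, noise_sigma = 0, seed = 1) {
  mag <- sid / sad
  ctr <- npix / 2
  u_iso <- (seq_len(npix) - ctr) * pitch / mag
  pu <- edge_profile(u_iso, u_edges[1] + shift_u, u_edges[2] + shift_u,
                     penumbra_sigma)
  pv <- edge_profile(u_iso, v_edges[1], v_edges[2], penumbra_sigma)
  px <- outer(pv, pu)
  if (noise_sigma > 0) {
    px <- with_seed(seed, px * matrix(stats::rnorm(npix * npix, 1,
                                                   noise_sigma),
                                      npix, npix))
    px[px < 0] <- 0
  }
  epid_image(px, pitch = pitch, sid = sid, gantry_angle = gantry_angle)
}

#' Generate the strip exposures of a non-gap test
#'
#' Emulates the acquisition of the non-gap test: abutting strips (default
#' ten of 2 cm x 20 cm, one per exposure) whose junction regions are
#' perturbed so that the downstream A/B pixel ratio at abutment
#' `(leaf, x)` equals `100 + delta_r[leaf, x]`. Two noise components can
#' be added per acquisition: per-pixel multiplicative Gaussian noise
#' (detector quantum noise) and a per-junction, per-leaf multiplicative
#' fluctuation (delivery/leaf-position reproducibility), which is what
#' dominates the observed ratio reproducibility after ROI averaging.
#'
#' @param gantry_angles Numeric vector of gantry angles to generate.
#' @param delta_r Either a single n_leaves x n_abutments matrix applied to
#'   every non-zero angle, or a named list (names = angles) of such
#'   matrices; the 0-degree acquisition is always unperturbed unless a
#'   matrix for `"0"` is supplied. `NULL` means no perturbation anywhere.
#' @param grid An [make_abutment_grid()]; fixes strip and leaf layout.
#' @param penumbra_sigma Penumbra width in mm at isocenter.
#' @param noise_sigma Per-pixel multiplicative sigma (fraction).
#' @param junction_sigma Per-junction multiplicative sigma (fraction).
#' @param npix,pitch,sid,sad Panel geometry, see [gen_open_field()].
#' @param seed RNG seed.
#' @return Named list (by angle) of lists of [epid_image()] strips.
#' @export
gen_nongap_images <- function(gantry_angles = 0, delta_r = NULL,
                              grid = make_abutment_grid(),
                              penumbra_sigma = 1.5, noise_sigma = 0,
                              junction_sigma = 0, npix = 1024, pitch = 0.40,
                              sid = 1500, sad = 1000, seed = 1) {
  mag <- sid / sad
  ctr <- npix / 2
  u_iso <- (seq_len(npix) - ctr) * pitch / mag
  v_iso <- u_iso
  n_strips <- length(grid$b_x)
  x_min <- grid$b_x[1] - grid$strip_width / 2
  v_lo <- min(grid$leaf_center_v) - grid$leaf_width / 2
  v_hi <- max(grid$leaf_center_v) + grid$leaf_width / 2
  v_field <- c(min(v_lo, -n_strips * grid$strip_width / 2),
               max(v_hi, n_strips * grid$strip_width / 2))
  pv <- edge_profile(v_iso, v_field[1], v_field[2], penumbra_sigma)
  dr_for <- function(angle) {
    if (is.null(delta_r)) return(NULL)
    if (is.list(delta_r)) {
      m <- delta_r[[as.character(angle)]]
      return(m)
    }
    if (angle == 0) NULL else delta_r
  }
  with_seed(seed, {
    out <- lapply(gantry_angles, function(angle) {
      dr <- dr_for(angle)
      strips <- lapply(seq_len(n_strips), function(k) {
        lo <- x_min + (k - 1) * grid$strip_width
        hi <- lo + grid$strip_width
        pu <- edge_profile(u_iso, lo, hi, penumbra_sigma)
        px <- outer(pv, pu)
        # junction-band factors: abutments bounding this strip
        for (ja in seq_along(grid$abutment_x)) {
          xj <- grid$abutment_x[ja]
          if (abs(xj - lo) > 1e-9 && abs(xj - hi) > 1e-9) next
          cols <- which(abs(u_iso - xj) <= grid$roi_u / 2)
          for (li in grid$leaf_index) {
            fac <- 1
            if (!is.null(dr)) fac <- fac * (1 + dr[li, ja] / 100)
            if (junction_sigma > 0) {
              fac <- fac * stats::rnorm(1, 1, junction_sigma)
            }
            if (fac == 1) next
            vr <- grid$leaf_center_v[li]
            rows <- which(abs(v_iso - vr) <= grid$leaf_width / 2)
            px[rows, cols] <- px[rows, cols] * fac
          }
        }
        if (noise_sigma > 0) {
          px <- px * matrix(stats::rnorm(npix * npix, 1, noise_sigma),
                            npix, npix)
          px[px < 0] <- 0
        }
        epid_image(px, pitch = pitch, sid = sid, gantry_angle = angle)
      })
      strips
    })
    names(out) <- as.character(gantry_angles)
    out
  })
}

#' Generate calibration pairs around a target conversion line
#'
#' Pixel ratios uniform on `[90, 110]`; dose ratios on the target line plus
#' additive Gaussian noise. The default noise level (0.075) reproduces the
#' strength of correlation seen between film-derived dose ratios and EPID
#' pixel ratios (r around 0.84) given the uniform-x spread used here.
#'
#' @param slope,intercept Target line (defaults: the fitted film/EPID
#'   conversion, 0.0203 and -1.0153).
#' @param sigma Additive Gaussian noise SD on the dose ratio.
#' @param n Number of pairs (default 171, one per abutment node).
#' @param seed RNG seed.
#' @return Data.frame with columns `pixel_ratio`, `dose_ratio`.
#' @export
gen_calibration_pairs <- function(slope = 0.0203, intercept = -1.0153,
                                  sigma = 0.075, n = 171, seed = 1) {
  if (n < 3) stop("gen_calibration_pairs: need n >= 3", call. = FALSE)
  with_seed(seed, {
    x <- stats::runif(n, 90, 110)
    y <- slope * x + intercept + stats::rnorm(n, 0, sigma)
    data.frame(pixel_ratio = x, dose_ratio = y)
  })
}

ellipsoid_contours <- function(center, semi, zs, n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  out <- list()
  for (z in zs) {
    t <- (z - center[3]) / semi[3]
    if (abs(t) >= 1) next
    s <- sqrt(1 - t^2)
    out[[length(out) + 1L]] <- list(
      z = z,
      xy = cbind(center[1] + semi[1] * s * cos(th),
                 center[2] + semi[2] * s * sin(th)))
  }
  out
}

default_error_blobs <- function() {
  list(list(u = 15, v = 10, amp = 0.03, sigma = 15),
       list(u = -20, v = -15, amp = -0.02, sigma = 18))
}

blob_field <- function(u, v, blobs) {
  # u, v vectors of equal length -> error fraction at each point
  e <- numeric(length(u))
  for (b in blobs) {
    e <- e + b$amp * exp(-((u - b$u)^2 + (v - b$v)^2) / (2 * b$sigma^2))
  }
  e
}

#' Generate a five-beam step-and-shoot plan fixture
#'
#' A complete, internally consistent synthetic data set for the prediction
#' pipeline: five beams at the treatment gantry angles 45, 105, 180, 255
#' and 315 degrees, each with three abutting MLC segments of known leaf
#' ends (hence known abutment positions), the per-beam segmented intensity
#' maps and planned isocenter-plane dose (1-mm grid), per-beam planned 3D
#' grids on a 2-mm phantom grid (toy fluence-times-attenuation model, not
#' a dose engine), diode-array "measurements" (planned plane times one plus
#' an injected smooth error field, sampled on a 7-mm lattice), and
#' ellipsoidal CTV/PTV/rectum/bladder structures.
#'
#' @param seed RNG seed (reserved for future noisy variants; the default
#'   fixture is deterministic).
#' @param gantry_angles Beam angles in degrees.
#' @param beam_mu Monitor units per beam.
#' @param segment_weights MU fractions of the three segments per beam.
#' @param boundaries Function(beam index) -> length-2 crossplane segment
#'   boundaries in mm, or NULL for the built-in stagger.
#' @param error_blobs List of blob lists (one per beam, recycled): each
#'   blob has `u`, `v` (mm), `amp` (fraction), `sigma` (mm). NULL injects
#'   zero error.
#' @param grid_spacing 3D grid voxel size in mm (default 2, the planning
#'   grid of the study conditions).
#' @param grid_halfsize Half-extent of the cubic phantom grid in mm.
#' @param dose_per_mu Output calibration of the toy model, Gy per MU.
#' @param mu_att Effective linear attenuation per mm of the toy
#'   depth factor (default 0.004, a 10-MV-like value).
#' @param diode_pitch Diode-array sampling pitch in mm (default 7).
#' @param n_leaves,leaf_width Leaf-bank layout.
#' @return List with `plan`, `planned_planes`, `measured_planes`, `simaps`,
#'   `beam_grids`, `total_grid`, `structures`, `error_blobs` (as used,
#'   per beam), `abutments` (data.frame of the generator's ground truth).
#' @export
gen_plan_fixture <- function(seed = 1,
                             gantry_angles = c(45, 105, 180, 255, 315),
                             beam_mu = 100,
                             segment_weights = c(0.5, 0.3, 0.2),
                             boundaries = NULL,
                             error_blobs = default_error_blobs(),
                             grid_spacing = 2, grid_halfsize = 60,
                             dose_per_mu = 0.01, mu_att = 0.004,
                             diode_pitch = 7,
                             n_leaves = 19, leaf_width = 10) {
  nb <- length(gantry_angles)
  if (is.null(boundaries)) {
    boundaries <- function(i) c(-24 + 3 * i, 12 + 2 * i)
  }
  if (!is.null(error_blobs) && !is.null(error_blobs[[1]]$amp)) {
    error_blobs <- list(error_blobs)   # single blob set -> recycle
  }
  aperture <- c(-60, 60)
  u1 <- seq(-100, 100, by = 1)
  v1 <- seq(-n_leaves * leaf_width / 2, n_leaves * leaf_width / 2, by = 1)

  beams <- list()
  simaps <- list()
  planned_planes <- list()
  measured_planes <- list()
  beam_grids <- list()
  blobs_used <- list()
  abutments <- list()

  vox <- NULL
  geometry <- rt_geometry()
  for (i in seq_len(nb)) {
    bnd <- sort(boundaries(i))
    edges <- c(aperture[1], bnd, aperture[2])
    leaves <- lapply(seq_len(3), function(s) {
      matrix(rep(c(edges[s], edges[s + 1]), each = n_leaves),
             ncol = 2, dimnames = NULL)
    })
    segs <- lapply(seq_len(3), function(s) {
      list(mu = beam_mu * segment_weights[s], leaves = leaves[[s]])
    })
    beam <- beam_spec(gantry_angles[i], beam_mu, segs)
    beams[[i]] <- beam
    abutments[[i]] <- data.frame(beam = i, leaf = rep(seq_len(n_leaves), 2),
                                 x_mm = rep(bnd, each = n_leaves))

    # segmented intensity: cumulative MU fraction crossing each boundary
    intens <- numeric(length(u1))
    for (s in seq_len(3)) {
      intens <- intens + segment_weights[s] *
        (u1 >= edges[s] & u1 < edges[s + 1])
    }
    iv <- as.numeric(v1 >= -n_leaves * leaf_width / 2 &
                       v1 < n_leaves * leaf_width / 2)
    imap <- outer(iv, intens)
    plane_i <- dose_plane(imap, origin = c(u1[1], v1[1]), spacing = c(1, 1))
    simaps[[i]] <- segment_intensity_map(plane_i, n_leaves, leaf_width)

    planned <- dose_plane(imap * beam_mu * dose_per_mu,
                          origin = c(u1[1], v1[1]), spacing = c(1, 1))
    planned_planes[[i]] <- planned

    blobs <- if (is.null(error_blobs)) list() else {
      error_blobs[[(i - 1) %% length(error_blobs) + 1]]
    }
    blobs_used[[i]] <- blobs
    ud <- seq(-98, 98, by = diode_pitch)
    vd <- seq(-91, 91, by = diode_pitch)
    uu <- rep(ud, each = length(vd)); vv <- rep(vd, times = length(ud))
    pd <- plane_lookup(planned, uu, vv, outside = 0)
    md <- pd * (1 + blob_field(uu, vv, blobs))
    measured_planes[[i]] <- dose_plane(matrix(md, length(vd), length(ud)),
                                       origin = c(ud[1], vd[1]),
                                       spacing = c(diode_pitch, diode_pitch))

    if (is.null(vox)) {
      ax <- seq(-grid_halfsize, grid_halfsize, by = grid_spacing)
      shape <- c(length(ax), length(ax), length(ax))
      origin3 <- rep(-grid_halfsize, 3)
      centers <- grid_voxel_centers(dose_grid(array(0, shape), origin3,
                                              rep(grid_spacing, 3)))
      vox <- list(ax = ax, shape = shape, origin3 = origin3,
                  centers = centers)
    }
    th <- gantry_angles[i] * pi / 180
    zb <- vox$centers[, 1] * sin(th) + vox$centers[, 3] * cos(th)
    uvp <- project_voxel_to_bev(vox$centers, gantry_angles[i], geometry)
    fl <- plane_lookup(planned, uvp[, 1], uvp[, 2], outside = 0)
    depth <- grid_halfsize - zb          # mm from the upstream phantom face
    dosev <- fl * exp(-mu_att * depth)
    beam_grids[[i]] <- dose_grid(array(dosev, vox$shape), vox$origin3,
                                 rep(grid_spacing, 3), scope = "per-beam")
  }

  zs <- vox$ax
  structures <- structure_set(list(
    CTV = ellipsoid_contours(c(0, 0, 0), c(24, 22, 24), zs),
    PTV = ellipsoid_contours(c(0, 0, 0), c(31, 29, 31), zs),
    Rectum = ellipsoid_contours(c(0, 38, 0), c(13, 13, 50), zs),
    Bladder = ellipsoid_contours(c(0, -38, 4), c(20, 18, 26), zs)
  ))

  # normalize the 3D grids to the prescription: mean PTV dose = 78 Gy over
  # the full course (the planes stay at per-fraction QA scale; error maps
  # are fractional, so the scale difference is immaterial downstream)
  total <- Reduce(`+`, lapply(beam_grids, function(g) g$values))
  total_grid <- dose_grid(total, vox$origin3, rep(grid_spacing, 3),
                          scope = "total")
  ptv <- structure_mask(structures, "PTV", total_grid)
  scale <- 78 / mean(total[ptv])
  beam_grids <- lapply(beam_grids, function(g) {
    dose_grid(g$values * scale, g$origin, g$spacing, scope = "per-beam")
  })
  # total is re-summed from the scaled grids so the per-beam decomposition
  # is exact to the last bit
  total <- Reduce(`+`, lapply(beam_grids, function(g) g$values))
  total_grid <- dose_grid(total, vox$origin3, rep(grid_spacing, 3),
                          scope = "total")

  list(plan = plan_spec(beams, prescription_dose = 78, fractions = 39),
       planned_planes = planned_planes, measured_planes = measured_planes,
       simaps = simaps, beam_grids = beam_grids, total_grid = total_grid,
       structures = structures, error_blobs = blobs_used,
       abutments = do.call(rbind, abutments))
}
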