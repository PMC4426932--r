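zero_table <- function() {
  conv <- fit_conversion(eq1_pairs())
  base <- matrix(100, 19, 9)
  mk <- function(angle) {
    grid <- make_abutment_grid()
    df <- expand.grid(leaf = grid$leaf_index, x_mm = grid$abutment_x,
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(df$leaf, df$x_mm), , drop = FALSE]
    rownames(df) <- NULL
    df$ratio <- 100
    structure(df, gantry_angle = angle, grid = grid,
              class = c("nongap_result", "data.frame"))
  }
  build_gac_table(list("0" = mk(0), "45" = mk(45), "105" = mk(105),
                       "180" = mk(180), "255" = mk(255), "315" = mk(315)),
                  conv)
}

test_that("error map is zero for matching planes and uniform for scaled ones", {
  set.seed(41)
  planned <- random_smooth_plane(40)
  em <- compute_error_map(planned, planned)
  expect_true(all(em$e == 0))
  expect_true(all(em$mask[planned$values >= 0.1 * max(planned$values)]))

  up <- dose_plane(planned$values * 1.05, planned$origin, planned$spacing)
  em2 <- compute_error_map(planned, up)
  expect_equal(range(em2$e[em2$mask]), c(0.05, 0.05), tolerance = 1e-12)
  expect_true(all(em2$e[!em2$mask] == 0))

  far <- dose_plane(planned$values, planned$origin + 1000, planned$spacing)
  expect_error(compute_error_map(planned, far), "overlap")
})

test_that("sparse diode sampling of a smooth field recovers the error field", {
  # smooth quadratic dose with a smooth relative error, diodes on a 7-mm grid
  u <- seq(-40, 40); v <- seq(-40, 40)
  dose <- outer(1 - (v / 90)^2, 1 - (u / 90)^2) * 2
  planned <- dose_plane(dose, c(-40, -40), c(1, 1))
  errf <- function(uu, vv) 0.03 * exp(-((uu - 5)^2 + (vv + 8)^2) / 800)
  ud <- seq(-42, 42, by = 7)
  md <- outer(1 - (ud / 90)^2, 1 - (ud / 90)^2) * 2 *
    (1 + outer(ud, ud, function(a, b) errf(b, a)))
  measured <- dose_plane(md, c(-42, -42), c(7, 7))
  em <- compute_error_map(planned, measured)
  truth <- outer(v, u, function(a, b) errf(b, a))
  expect_lt(max(abs(em$e[em$mask] - truth[em$mask])), 0.005)
})

test_that("abutments are detected at intensity steps and matched to segments", {
  # single step at x = 12 on one leaf row
  u <- seq(-40, 40); v <- seq(-95, 95)
  vals <- matrix(0.5, length(v), length(u))
  vals[, u > 12] <- 1
  simap <- segment_intensity_map(dose_plane(vals, c(-40, -95), c(1, 1)))
  leaves <- matrix(rep(c(-40, 12), each = 19), ncol = 2)
  leaves2 <- matrix(rep(c(12, 40), each = 19), ncol = 2)
  beam <- beam_spec(0, 100, list(list(mu = 50, leaves = leaves),
                                 list(mu = 50, leaves = leaves2)))
  ab <- detect_abutments(simap, beam)
  hit <- ab[ab$leaf == 10, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$x_mm - 12), 0.5 + 1e-9)
  expect_equal(hit$mu_fraction, 0.5)

  # uniform map: nothing to detect
  uni <- segment_intensity_map(dose_plane(matrix(1, length(v), length(u)),
                                          c(-40, -95), c(1, 1)))
  expect_identical(nrow(detect_abutments(uni, beam)), 0L)
})

test_that("fixture abutments are all detected within 1 mm with correct MU fractions", {
  fx <- gen_plan_fixture()
  for (i in seq_along(fx$plan$beams)) {
    ab <- detect_abutments(fx$simaps[[i]], fx$plan$beams[[i]])
    truth <- fx$abutments[fx$abutments$beam == i, ]
    for (j in seq_len(nrow(truth))) {
      cand <- ab[ab$leaf == truth$leaf[j], ]
      dmin <- min(abs(cand$x_mm - truth$x_mm[j]))
      expect_lt(dmin, 1 + 1e-9)
      k <- which.min(abs(cand$x_mm - truth$x_mm[j]))
      expect_true(cand$mu_fraction[k] %in% c(0.5, 0.3, 0.2))
    }
  }
})

test_that("GAC injection adds the MU-weighted delta over the abutment band only", {
  emap <- structure(list(e = matrix(0, 190, 201),
                        mask = matrix(TRUE, 190, 201),
                        origin = c(-100, -95), spacing = c(1, 1)),
                   class = "error_map")
  abut <- structure(data.frame(leaf = 10, x_mm = -80, mu_fraction = 1,
                               segment = 1L),
                    class = c("abutment_set", "data.frame"))
  tab <- zero_table()
  same <- apply_gac(emap, abut, tab, 45)
  expect_identical(same$e, emap$e)

  tab$delta[tab$angles == 45, 10, 1] <- 0.05   # leaf 10, x = -80
  g1 <- apply_gac(emap, abut, tab, 45)
  u <- -100:100; v <- -95:94
  band_cols <- which(abs(u - (-80)) <= 1)
  band_rows <- which(v >= -5 & v < 5)
  expect_equal(unique(as.vector(g1$e[band_rows, band_cols])), 0.05)
  g1$e[band_rows, band_cols] <- 0
  expect_true(all(g1$e == 0))

  abut$mu_fraction <- 0.4
  g2 <- apply_gac(emap, abut, tab, 45)
  expect_equal(max(g2$e), 0.02, tolerance = 1e-12)
})

test_that("back-projection scales voxels by one plus the looked-up error", {
  fx <- gen_plan_fixture()
  bg <- fx$beam_grids[[1]]
  emap0 <- structure(list(e = matrix(0, 191, 201),
                          mask = matrix(TRUE, 191, 201),
                          origin = c(-100, -95), spacing = c(1, 1)),
                     class = "error_map")
  out <- backproject(emap0, bg, 45)
  expect_identical(out$values, bg$values)

  emap3 <- emap0; emap3$e[] <- 0.03
  # widen the map so every projected voxel lands inside it
  big <- matrix(0.03, 401, 401)
  emapb <- structure(list(e = big, mask = matrix(TRUE, 401, 401),
                          origin = c(-200, -200), spacing = c(1, 1)),
                     class = "error_map")
  out3 <- backproject(emapb, bg, 45)
  expect_equal(out3$values, bg$values * 1.03, tolerance = 1e-12)
})

test_that("an off-axis error blob scales doses along its diverging ray", {
  fx <- gen_plan_fixture(gantry_angles = 0, error_blobs = NULL)
  bg <- fx$beam_grids[[1]]
  u <- -100:100; v <- -95:95
  blob <- 0.04 * exp(-(outer((v - 10)^2, (u - 15)^2, `+`)) / (2 * 12^2))
  emap <- structure(list(e = blob, mask = matrix(TRUE, 191, 201),
                         origin = c(-100, -95), spacing = c(1, 1)),
                    class = "error_map")
  out <- backproject(emap, bg, 0)
  centers <- grid_voxel_centers(bg)
  uv <- project_voxel_to_bev(centers, 0)
  expected <- 1 + 0.04 * exp(-((uv[, 1] - 15)^2 + (uv[, 2] - 10)^2) /
                               (2 * 12^2))
  nz <- bg$values > 0.01 * max(bg$values)
  ratio <- out$values[nz] / bg$values[nz]
  expect_lt(max(abs(ratio - expected[nz])), 0.01)
})

test_that("back-projection is linear in the error field", {
  fx <- gen_plan_fixture(gantry_angles = 45, error_blobs = NULL)
  bg <- fx$beam_grids[[1]]
  set.seed(44)
  mk <- function() {
    e <- matrix(rnorm(191 * 201, 0, 0.02), 191, 201)
    structure(list(e = e, mask = matrix(TRUE, 191, 201),
                   origin = c(-100, -95), spacing = c(1, 1)),
              class = "error_map")
  }
  e1 <- mk(); e2 <- mk()
  e12 <- e1; e12$e <- e1$e + e2$e
  lhs <- backproject(e12, bg, 45)$values
  rhs <- backproject(e1, bg, 45)$values + backproject(e2, bg, 45)$values -
    bg$values
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("prediction closes on the plan under zero error and zero GAC", {
  fx <- gen_plan_fixture()
  pred <- predict_dose(fx$plan, fx$planned_planes, fx$planned_planes,
                       fx$simaps, fx$beam_grids, use_gac = FALSE)
  expect_equal(pred$values, fx$total_grid$values, tolerance = 1e-9)

  tab <- zero_table()
  with_tab <- predict_dose(fx$plan, fx$planned_planes, fx$measured_planes,
                           fx$simaps, fx$beam_grids, table = tab,
                           use_gac = TRUE)
  without <- predict_dose(fx$plan, fx$planned_planes, fx$measured_planes,
                          fx$simaps, fx$beam_grids, use_gac = FALSE)
  expect_identical(with_tab$values, without$values)

  expect_error(predict_dose(fx$plan, fx$planned_planes[1:3],
                            fx$measured_planes, fx$simaps, fx$beam_grids,
                            use_gac = FALSE), "beam count")
})

test_that("a positive GAC delta never decreases any predicted voxel dose", {
  fx <- gen_plan_fixture()
  tab <- zero_table()
  base <- predict_dose(fx$plan, fx$planned_planes, fx$measured_planes,
                       fx$simaps, fx$beam_grids, table = tab, use_gac = TRUE)
  tab$delta[tab$angles == 45, , ] <- 0.05
  up <- predict_dose(fx$plan, fx$planned_planes, fx$measured_planes,
                     fx$simaps, fx$beam_grids, table = tab, use_gac = TRUE)
  expect_true(all(up$values - base$values >= -1e-12))
  expect_gt(max(up$values - base$values), 0)
})

test_that("five-beam prediction matches an independently composed oracle", {
  fx <- gen_plan_fixture()
  pred <- predict_dose(fx$plan, fx$planned_planes, fx$measured_planes,
                       fx$simaps, fx$beam_grids, use_gac = FALSE)
  # oracle: straightforward per-beam composition with its own lookup code
  set.seed(46)
  total_ref <- max(fx$total_grid$values)
  idx <- sample(length(fx$total_grid$values), 4000)
  centers <- grid_voxel_centers(fx$total_grid)[idx, , drop = FALSE]
  oracle <- numeric(length(idx))
  for (b in seq_along(fx$plan$beams)) {
    ang <- fx$plan$beams[[b]]$gantry_angle
    em <- compute_error_map(fx$planned_planes[[b]], fx$measured_planes[[b]])
    th <- ang * pi / 180
    xb <- centers[, 1] * cos(th) - centers[, 3] * sin(th)
    zb <- centers[, 1] * sin(th) + centers[, 3] * cos(th)
    f <- 1000 / (1000 - zb)
    uu <- xb * f; vv <- centers[, 2] * f
    ev <- numeric(length(uu))
    for (k in seq_along(uu)) {
      iu <- (uu[k] - em$origin[1]) / em$spacing[1] + 1
      iv <- (vv[k] - em$origin[2]) / em$spacing[2] + 1
      if (iu < 1 || iu > ncol(em$e) || iv < 1 || iv > nrow(em$e)) next
      i0 <- min(max(floor(iu), 1), ncol(em$e) - 1)
      j0 <- min(max(floor(iv), 1), nrow(em$e) - 1)
      du <- iu - i0; dv <- iv - j0
      ev[k] <- em$e[j0, i0] * (1 - du) * (1 - dv) +
        em$e[j0, i0 + 1] * du * (1 - dv) +
        em$e[j0 + 1, i0] * (1 - du) * dv +
        em$e[j0 + 1, i0 + 1] * du * dv
    }
    oracle <- oracle + fx$beam_grids[[b]]$values[idx] * (1 + ev)
  }
  expect_lt(max(abs(pred$values[idx] - oracle)) / total_ref, 0.005)
})
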