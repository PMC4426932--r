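test_that("composite of abutting strips reproduces the open field by superposition", {
  strips <- gen_nongap_images(0)[["0"]]
  comp <- build_composite(strips)
  open <- gen_open_field()
  # rising/falling error-function edges cancel at every junction, so the
  # unperturbed composite equals the open field everywhere
  expect_lt(max(abs(comp$pixels - open$pixels)) / max(open$pixels), 1e-12)
  expect_identical(comp$n_exposures, 10L)
})

test_that("composite is the identity for one exposure and permutation-invariant", {
  strips <- gen_nongap_images(0)[["0"]]
  one <- build_composite(strips[1])
  expect_identical(one$pixels, strips[[1]]$pixels)
  set.seed(3)
  perm <- sample(length(strips))
  expect_equal(build_composite(strips[perm])$pixels,
               build_composite(strips)$pixels, tolerance = 1e-12)
  bad <- strips
  bad[[2]]$pitch <- 0.5
  expect_error(build_composite(bad), "disagree")
})

test_that("reticle correction recenters a translated cross and is a 180-degree involution", {
  px <- matrix(0, 256, 256)
  px[131, 126] <- 1                         # cross displaced (+3, -2) from (128, 128)
  img <- epid_image(px, reticle_offset = list(rotation = 0,
                                              translation = c(3, -2)))
  fixed <- correct_reticle_offset(img)
  peak <- which(fixed$pixels == max(fixed$pixels), arr.ind = TRUE)
  expect_lt(max(abs(peak - c(128, 128))), 0.5 + 1e-9)
  expect_equal(fixed$reticle_offset$translation, c(0, 0))

  # zero offset: exact identity
  img0 <- epid_image(px)
  expect_identical(correct_reticle_offset(img0)$pixels, px)

  # 180-degree rotation applied twice returns the original smooth image
  sm <- epid_image(outer(dnorm(seq(-3, 3, length.out = 256)),
                         dnorm(seq(-2, 4, length.out = 256))),
                   reticle_offset = list(rotation = 180,
                                         translation = c(0, 0)))
  once <- correct_reticle_offset(sm)
  once$reticle_offset <- list(rotation = 180, translation = c(0, 0))
  twice <- correct_reticle_offset(once)
  inner <- 2:255
  expect_lt(max(abs(twice$pixels[inner, inner] - sm$pixels[inner, inner])),
            1e-6 * diff(range(sm$pixels)))
})

test_that("FWHM field size is exact on ideal fields and tracks shifts", {
  comp <- build_composite(gen_nongap_images(0)[["0"]])
  fs <- measure_field_size(comp, c(100, 100), leaf_index = c(1, 10, 19))
  expect_true(all(abs(fs$x1_error) < 0.05))
  expect_true(all(abs(fs$x2_error) < 0.05))

  for (s in c(1.2, 2.5, -3.1)) {
    sh <- measure_field_size(gen_open_field(shift_u = s), c(100, 100), 10)
    expect_equal(sh$x1_error, -s, tolerance = 0.05)
    expect_equal(sh$x2_error, s, tolerance = 0.05)
    expect_equal(sh$size, 200, tolerance = 0.05)
  }

  # closed form: generator edges at +-25 mm give a 50-mm field
  small <- gen_open_field(u_edges = c(-25, 25))
  fs50 <- measure_field_size(small, c(25, 25), 10)
  expect_equal(fs50$size, 50, tolerance = 0.05)
})

test_that("field-size analysis is invariant to global intensity scaling", {
  img <- gen_open_field(u_edges = c(-50, 50))
  a <- measure_field_size(img, c(50, 50), 10)
  img$pixels <- img$pixels * 731.5
  b <- measure_field_size(img, c(50, 50), 10)
  expect_equal(b$x1_edge, a$x1_edge, tolerance = 1e-9)
  expect_equal(b$x2_edge, a$x2_edge, tolerance = 1e-9)
})

test_that("abutment grid layout matches the strip geometry", {
  g <- make_abutment_grid()
  expect_identical(length(g$abutment_x) * length(g$leaf_index), 171L)
  expect_identical(length(g$abutment_x), 9L)
  expect_identical(length(g$leaf_index), 19L)
  expect_equal(g$abutment_x, seq(-80, 80, by = 20))
  expect_equal(g$b_x, seq(-90, 90, by = 20))

  small <- make_abutment_grid(n_strips = 3, strip_width = 20, n_leaves = 5)
  expect_identical(length(small$abutment_x) * length(small$leaf_index), 10L)
  expect_error(make_abutment_grid(strip_width = 0), "widths")
  expect_error(make_abutment_grid(n_strips = 1), "strips")
})

test_that("pixel ratios are 100 on uniform composites and track local scaling", {
  grid <- make_abutment_grid()
  uni <- structure(list(pixels = matrix(2.5, 1024, 1024), pitch = 0.4,
                        sid = 1500, gantry_angle = 0, n_exposures = 1L),
                   class = c("composite_image", "epid_image"))
  r <- compute_abutment_ratios(uni, grid)
  expect_identical(nrow(r), 171L)
  expect_true(all(r$ratio == 100))

  # scale one A-ROI region by 1.05 -> that abutment reads 105
  u_iso <- (seq_len(1024) - 512) * 0.4 / 1.5
  v_iso <- u_iso
  cols <- which(abs(u_iso - (-80)) <= 5)
  rows <- which(abs(v_iso - grid$leaf_center_v[7]) <= 2.5)
  uni$pixels[rows, cols] <- uni$pixels[rows, cols] * 1.05
  r2 <- compute_abutment_ratios(uni, grid)
  hit <- r2$leaf == 7 & r2$x_mm == -80
  expect_equal(r2$ratio[hit], 105, tolerance = 1e-9)
  expect_true(all(r2$ratio[!hit] == 100))
})

test_that("injected per-abutment ratio patterns are recovered after ROI averaging", {
  grid <- make_abutment_grid()
  set.seed(17)
  dr <- matrix(rnorm(19 * 9, 0, 3), 19, 9)
  imgs <- gen_nongap_images(c(0, 180), delta_r = dr)
  r0 <- compute_abutment_ratios(build_composite(imgs[["0"]]), grid)
  r180 <- compute_abutment_ratios(build_composite(imgs[["180"]]), grid)
  expect_true(all(abs(r0$ratio - 100) < 0.05))
  injected <- dr[cbind(r180$leaf, match(r180$x_mm, grid$abutment_x))]
  expect_lt(max(abs(r180$ratio - 100 - injected)), 0.1)
})

test_that("coefficient of variation reproduces hand-computed and null cases", {
  grid <- make_abutment_grid(n_strips = 3, n_leaves = 2)
  base <- compute_abutment_ratios(
    structure(list(pixels = matrix(1, 1024, 1024), pitch = 0.4, sid = 1500,
                   gantry_angle = 0, n_exposures = 1L),
              class = c("composite_image", "epid_image")), grid)
  expect_true(all(reproducibility_cov(list(base, base, base))$cov_percent == 0))

  r1 <- base; r2 <- base
  r1$ratio[1] <- 99; r2$ratio[1] <- 101
  cv <- reproducibility_cov(list(r1, r2))
  expect_equal(cv$cov_percent[1], sqrt(2), tolerance = 1e-12)

  # CoV is invariant to a common scale factor
  r1s <- r1; r2s <- r2
  r1s$ratio <- r1s$ratio * 7.3; r2s$ratio <- r2s$ratio * 7.3
  expect_equal(reproducibility_cov(list(r1s, r2s))$cov_percent,
               cv$cov_percent, tolerance = 1e-12)
})

test_that("CoV of noisy replicates matches the generating noise level", {
  grid <- make_abutment_grid()
  base <- compute_abutment_ratios(
    structure(list(pixels = matrix(1, 1024, 1024), pitch = 0.4, sid = 1500,
                   gantry_angle = 0, n_exposures = 1L),
              class = c("composite_image", "epid_image")), grid)
  set.seed(55)
  reps <- lapply(1:10, function(i) {
    r <- base
    r$ratio <- r$ratio * rnorm(nrow(r), 1, 0.0055)
    r
  })
  cv <- reproducibility_cov(reps)
  expect_gt(mean(cv$cov_percent), 0.40)
  expect_lt(mean(cv$cov_percent), 0.70)
})
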