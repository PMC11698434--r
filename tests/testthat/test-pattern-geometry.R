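test_that("maximum projection handles single planes, full stacks and blocks", {
  m <- matrix(1:6, 2, 3)
  expect_equal(project_stack(m), m)
  st <- array(0, c(2, 3, 2))
  st[, , 1] <- 3; st[, , 2] <- 7
  expect_equal(project_stack(st), matrix(7, 2, 3))
  st12 <- array(rep(1:12, each = 4), c(2, 2, 12))
  blocks <- project_stack(st12, group_size = 5)
  expect_length(blocks, 3)             # planes 1-5, 6-10, 11-12
  expect_equal(blocks[[1]], matrix(5, 2, 2))
  expect_equal(blocks[[3]], matrix(12, 2, 2))
  expect_error(project_stack(array(0, c(2, 2, 0))), "non-empty")
})

test_that("background subtraction averages the ROI and clamps at zero", {
  img <- matrix(10, 60, 60)
  expect_equal(subtract_background(img, c(1, 1)), matrix(0, 60, 60))
  img2 <- matrix(40, 60, 60)
  img2[50, 50] <- 100
  img2[40, 40] <- 30
  out <- subtract_background(img2, c(1, 1))   # ROI mean 40
  expect_equal(out[50, 50], 60)
  expect_equal(out[40, 40], 0)                # clamped
  expect_error(subtract_background(img, c(40, 40)), "outside")
})

test_that("binarization thresholds strictly at the stated fraction of the maximum", {
  img <- matrix(0, 4, 4)
  img[1, 1] <- 250; img[2, 2] <- 51; img[3, 3] <- 49; img[4, 4] <- 50
  m <- binarize_pattern(img, 0.20)             # threshold 50, strict
  expect_equal(m[1, 1], 1L)
  expect_equal(m[2, 2], 1L)
  expect_equal(m[3, 3], 0L)
  expect_equal(m[4, 4], 0L)
  # relative threshold: intensity scaling leaves the mask unchanged
  expect_equal(binarize_pattern(img * 7.3, 0.20), m)
  # fraction 0 selects every positive pixel; constant images fully on
  expect_equal(sum(binarize_pattern(img, 0)), 4)
  expect_true(all(binarize_pattern(matrix(5, 3, 3), 0.2) == 1L))
  expect_error(binarize_pattern(matrix(0, 3, 3)), "positive")
  # inverse binarization is the complement
  expect_equal(binarize_pattern(img, 0.2, invert = TRUE), 1L - m)
})

test_that("mask cleanup removes specks, honors identity parameters and breaks ties deterministically", {
  m <- matrix(0L, 100, 100)
  m[10:41, 10:41] <- 1L                        # 1024-px blob
  m[60, 60] <- 1L; m[70, 5] <- 1L; m[5, 80] <- 1L   # specks
  out <- preprocess_mask(m, min_component_px = 64, blur_kernel = 1)
  expect_equal(sum(out), 1024)
  expect_equal(out[60, 60], 0L)
  # identity settings
  expect_equal(preprocess_mask(m, min_component_px = 0, blur_kernel = 1), m)
  # two equal blobs with keep_largest: the first in label scan order stays
  m2 <- matrix(0L, 50, 50)
  m2[5:14, 5:14] <- 1L
  m2[30:39, 30:39] <- 1L
  out2 <- preprocess_mask(m2, min_component_px = 0, blur_kernel = 1,
                          keep_largest = TRUE)
  expect_equal(sum(out2), 100)
  expect_equal(out2[5, 5], 1L)
  expect_equal(out2[30, 30], 0L)
  expect_error(preprocess_mask(matrix(0L, 5, 5) , min_component_px = 0,
                               blur_kernel = 1), "empty")
})

test_that("convex hull of a filled rectangle is its corners and ignores interior", {
  m <- matrix(0L, 40, 40)
  m[10:20, 5:25] <- 1L
  h <- hull_points(m)
  expect_equal(nrow(h), 4)
  expect_setequal(apply(h, 1, paste, collapse = ","),
                  c("5,10", "25,10", "25,20", "5,20"))
  expect_gt(signed_loop_area(h), 0)            # counterclockwise
  m2 <- m
  m2[15, 15] <- 0L                              # interior hole
  expect_equal(hull_points(m2), h)
  single <- matrix(0L, 10, 10); single[3, 3] <- 1L
  expect_error(hull_points(single), "at least 3")
  collin <- matrix(0L, 10, 10); collin[5, 2:8] <- 1L
  expect_error(hull_points(collin), "collinear")
})

test_that("direct least-squares ellipse fit recovers exact generators", {
  # circle
  circ <- fit_ellipse(ellipse_points(1, 1, n = 200))
  expect_equal(circ$a, 1, tolerance = 1e-6)
  expect_equal(circ$b, 1, tolerance = 1e-6)
  expect_equal(circ$e, 0, tolerance = 1e-3)
  # a=2, b=1 at 30 degrees, offset center
  p <- ellipse_points(2, 1, theta = pi / 6, center = c(3, -2), n = 200)
  f <- fit_ellipse(p)
  expect_equal(f$e, 0.8660254, tolerance = 1e-6)
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 1, tolerance = 1e-6)
  expect_equal(f$theta, pi / 6, tolerance = 1e-6)
  expect_equal(unname(f$center), c(3, -2), tolerance = 1e-6)
  # zero algebraic residual on exact points
  co <- f$conic
  resid <- co[1] * p[, 1]^2 + co[2] * p[, 1] * p[, 2] + co[3] * p[, 2]^2 +
    co[4] * p[, 1] + co[5] * p[, 2] + co[6]
  expect_lt(max(abs(resid)) / max(abs(co)), 1e-9)
  # five points determine the conic exactly
  p5 <- ellipse_points(5, 2, theta = 0.4, center = c(1, 1), n = 5)
  f5 <- fit_ellipse(p5)
  expect_equal(f5$a, 5, tolerance = 1e-6)
  expect_equal(f5$b, 2, tolerance = 1e-6)
  # degenerate inputs
  expect_error(fit_ellipse(p5[1:4, ]), "at least 5")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "collinear|ellip")
})

test_that("hinge-pouch fold clicks recover their generating ellipse", {
  clicks <- ellipse_points(140, 90, theta = 1.1, center = c(250, 260), n = 8)
  f <- fit_hp_ellipse(clicks)
  expect_equal(f$a, 140, tolerance = 1e-6)
  expect_equal(f$b, 90, tolerance = 1e-6)
  expect_equal(unname(f$center), c(250, 260), tolerance = 1e-5)
})

test_that("pattern eccentricity recovers phantom ground truth within pixelation tolerance", {
  disc <- raster_ellipse(150, 150)
  expect_lte(pattern_eccentricity(disc)$e, 0.1)
  ell <- raster_ellipse(200, 120)
  e0 <- pattern_eccentricity(ell)$e
  expect_equal(e0, 0.8, tolerance = 0.02)
  # rotation invariance
  e45 <- pattern_eccentricity(raster_ellipse(200, 120, theta = pi / 4))$e
  expect_equal(e45, e0, tolerance = 0.01)
  # translation and moderate scaling
  esh <- pattern_eccentricity(raster_ellipse(200, 120,
                                             center = c(220, 300)))$e
  expect_equal(esh, e0, tolerance = 0.01)
  ehalf <- pattern_eccentricity(raster_ellipse(100, 60))$e
  expect_equal(ehalf, 0.8, tolerance = 0.02)
})

test_that("overlap/nuclei estimate is fractional, symmetric and monotone", {
  a <- matrix(0L, 50, 50); b <- matrix(0L, 50, 50)
  a[1:40, 1:25] <- 1L                  # 1000 px
  b[1:40, 1:25] <- 1L
  expect_equal(overlap_nuclei_estimate(a, b), 5.0)
  expect_equal(overlap_nuclei_estimate(a, matrix(0L, 50, 50)), 0)
  b199 <- matrix(0L, 50, 50)
  b199[1:40, 1:4] <- 1L; b199[1:39, 5] <- 1L   # 199 px, all inside a
  expect_equal(overlap_nuclei_estimate(a, b199), 0.995)
  expect_equal(overlap_nuclei_estimate(a, b), overlap_nuclei_estimate(b, a))
  bigger <- b; bigger[1:40, 26] <- 1L
  expect_gte(overlap_nuclei_estimate(a, bigger),
             overlap_nuclei_estimate(a, b))
  expect_error(overlap_nuclei_estimate(a, matrix(0L, 10, 10)), "shape")
})
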