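test_that("extract_instances handles empty, single and multi-label masks", {
  shape <- c(40, 40)
  expect_length(extract_instances(matrix(0L, 40, 40), 0)$instances, 0)

  m <- matrix(0L, 40, 40)
  m[11:20, 16:25] <- 3L
  fs <- extract_instances(m, 2)
  expect_length(fs$instances, 1)
  ci <- fs$instances[[1]]
  expect_equal(ci$instance_id, 3L)
  expect_equal(ci$area, 100)
  expect_equal(ci$centroid, c(19.5, 14.5))  # (x, y), 0-based
  expect_equal(ci$frame, 2L)

  m2 <- matrix(0L, 40, 40)
  m2[2:5, 2:5] <- 1L; m2[10:13, 10:13] <- 2L; m2[20:23, 20:23] <- 5L
  fs2 <- extract_instances(m2, 0)
  expect_equal(vapply(fs2$instances, function(x) x$instance_id, integer(1)),
               c(1L, 2L, 5L))
})

test_that("extract_instances rejects malformed input and keeps the largest component", {
  expect_error(extract_instances(array(0L, c(2, 2, 2)), 0), "2D")
  expect_error(extract_instances(matrix(-1L, 4, 4), 0), "negative")
  expect_error(extract_instances(matrix(0.5, 4, 4), 0), "non-integer")
  expect_error(extract_instances(matrix(0L, 4, 4), 0,
                                 intensity_image = matrix(0, 3, 3)),
               "shape mismatch")
  # fragmented label: keep largest 8-connected component
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 7L      # 100 px
  m[20:22, 20:22] <- 7L    # 9 px
  expect_warning(fs <- extract_instances(m, 0), "components")
  expect_equal(fs$instances[[1]]$area, 100)
  # labels above 255 accepted
  m16 <- matrix(0L, 10, 10); m16[3:6, 3:6] <- 70000L
  expect_equal(extract_instances(m16, 0)$instances[[1]]$instance_id, 70000L)
})

test_that("intensity statistics are computed over labelled pixels", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  img <- matrix(0, 10, 10); img[3:6, 3:6] <- c(rep(2, 8), rep(6, 8))
  ci <- extract_instances(m, 0, intensity_image = img)$instances[[1]]
  expect_equal(ci$intensity_mean, 4)
  expect_equal(ci$intensity_var, stats::var(c(rep(2, 8), rep(6, 8))))
})

test_that("shoelace area matches the closed-form cases", {
  expect_equal(shoelace_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(shoelace_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_warning(a <- shoelace_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "degenerate")
  expect_equal(a, 0)
  expect_error(shoelace_area(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("traced contours of rectangles have exact shoelace area w*h", {
  for (wh in list(c(1, 1), c(3, 7), c(10, 10), c(12, 4))) {
    ci <- rect_cell(0, 1, 5, 5, w = wh[1], h = wh[2])
    expect_equal(shoelace_area(ci$contour), wh[1] * wh[2])
  }
  # and of rasterized ellipses: shoelace equals pixel count exactly
  ci <- ell_cell(0, 1, 30, 30, a = 9, b = 6, theta = 0.7)
  expect_equal(shoelace_area(ci$contour), ci$area)
})

test_that("mask_iou obeys identity, disjointness and the shifted-square case", {
  a <- rect_cell(0, 1, 10, 10, 2, 2)
  b <- rect_cell(0, 2, 11, 10, 2, 2)
  c <- rect_cell(0, 3, 40, 40, 2, 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, c), 0)
  expect_equal(mask_iou(a, b), 1 / 3)  # inter 2, union 6
  expect_equal(mask_iou(a, b), mask_iou(b, a))
})

test_that("expand_bbox follows the printed formula, identity and clipping", {
  e <- expand_bbox(bbox(10, 20, 10, 20), 1.5)
  expect_equal(unclass(e)[c("x1", "x2", "y1", "y2")],
               list(x1 = -5, x2 = 35, y1 = -5, y2 = 35))
  b0 <- bbox(3, 9, 4, 7)
  expect_equal(unclass(expand_bbox(b0, 0)), unclass(b0))
  ec <- expand_bbox(bbox(10, 20, 10, 20), 1.5, image_shape = c(30, 30))
  expect_equal(unclass(ec)[c("x1", "x2", "y1", "y2")],
               list(x1 = 0, x2 = 29, y1 = 0, y2 = 29))
  # centre preserved, width scaled by (1 + 2*alpha), when unclipped
  for (alpha in c(0.3, 1, 1.5)) {
    e <- expand_bbox(b0, alpha)
    expect_equal((e$x1 + e$x2) / 2, (b0$x1 + b0$x2) / 2)
    expect_equal(e$x2 - e$x1, (1 + 2 * alpha) * (b0$x2 - b0$x1))
  }
  expect_error(bbox(5, 5, 1, 2), "degenerate")
})

test_that("Hu invariants are exact under translation and 90-degree rotation", {
  ras <- getFromNamespace("rasterize_ellipse", "trackforest")
  e1 <- ras(40, 40, 14, 7, 0, c(90, 90))
  e2 <- ras(51, 38, 14, 7, 0, c(90, 90))    # integer translation, same raster
  h1 <- hu_moments(e1$mask)
  expect_equal(hu_moments(e2$mask), h1, tolerance = 1e-6)
  expect_equal(hu_moments(t(e1$mask)), h1, tolerance = 1e-12)  # rot 90
  # uniform scaling: raster moments converge but pixelation leaves a small
  # residual; a doubled shape agrees loosely, not to 1e-6
  e3 <- ras(40, 40, 28, 14, 0, c(90, 90))
  expect_lt(max(abs(hu_moments(e3$mask)[1:4] - h1[1:4])), 0.05)
  expect_error(hu_moments(matrix(FALSE, 3, 3)), "empty")
})

test_that("cell_instance validates its invariants", {
  ok <- rect_cell(0, 1, 5, 5)
  expect_s3_class(ok, "cell_instance")
  expect_length(ok$hu, 7)
  expect_true(point_in <- ok$centroid[1] >= ok$bbox$x1 &&
                ok$centroid[1] <= ok$bbox$x2)
  expect_error(cell_instance(0, 1, ok$contour, c(100, 100), 10, ok$bbox,
                             ok$mask, ok$offset, ok$hu),
               "centroid")
  expect_error(cell_instance(0, 1, ok$contour, ok$centroid, 10, ok$bbox,
                             ok$mask, ok$offset, 1:6), "7")
  expect_error(frame_segmentation(0, list(ok, ok), c(64, 64)), "duplicate")
})
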