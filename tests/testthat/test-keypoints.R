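# Mask -> landmark pipeline: regions, Harris response, NMS, labelling.

test_that("extract_regions counts bodies and filters specks", {
  ph <- quick_phantom(seed = 4)
  regs <- extract_regions(ph$mask)
  expect_length(regs, 6)
  expect_equal(sum(vapply(regs, `[[`, character(1), "class") == "lumbar"), 5)
  # a 3-px speck is removed by the area filter
  m2 <- ph$mask
  m2[2:4, 2] <- 1L
  expect_length(extract_regions(m2), 6)
  # empty mask and missing sacrum raise anatomy-count errors
  expect_error(extract_regions(matrix(0L, 40, 40)),
               class = "lumbometry_anatomy_count")
  m3 <- ph$mask
  m3[m3 == 2L] <- 0L
  expect_error(extract_regions(m3), class = "lumbometry_anatomy_count")
})

test_that("label_vertebrae orders by row and ignores list order", {
  ph <- quick_phantom(seed = 4)
  regs <- extract_regions(ph$mask)
  lab <- label_vertebrae(regs)
  ids <- vapply(lab, `[[`, character(1), "identity")
  expect_equal(ids, c("L1", "L2", "L3", "L4", "L5", "S1"))
  shuf <- label_vertebrae(regs[c(4, 6, 1, 5, 2, 3)])
  expect_equal(vapply(shuf, `[[`, character(1), "identity"), ids)
  # mirroring leaves row order unchanged
  regs_m <- extract_regions(ph$mask[, ncol(ph$mask):1])
  expect_equal(vapply(label_vertebrae(regs_m), `[[`, character(1),
                      "identity"), ids)
})

test_that("harris_response: constant, edge and corner cases", {
  expect_true(all(harris_response(matrix(1, 30, 30)) == 0))
  # straight edge: response non-positive along the edge interior
  e <- matrix(0, 40, 40); e[, 21:40] <- 1
  r <- harris_response(e)
  expect_true(all(r[10:30, 19:22] <= 1e-12))
  # axis-aligned square: top responses within 2 px of the true corners
  sq <- matrix(0, 100, 100); sq[31:61, 41:71] <- 1
  r2 <- harris_response(sq, pre_sigma = 1.5)
  truth <- rbind(c(40, 30), c(70, 30), c(40, 60), c(70, 60))  # (x, y)
  top <- which(r2 >= sort(r2, decreasing = TRUE)[4], arr.ind = TRUE)
  for (k in seq_len(nrow(top))) {
    d <- sqrt((truth[, 1] - (top[k, 2] - 1))^2 +
              (truth[, 2] - (top[k, 1] - 1))^2)
    expect_lt(min(d), 2)
  }
  # response field is symmetric under 90 deg rotation of the patch
  r90 <- harris_response(t(sq)[ncol(sq):1, ], pre_sigma = 1.5)
  expect_equal(max(r90), max(r2), tolerance = 1e-9)
})

test_that("detect_corners finds rectangle corners and rejects disks", {
  reg <- quad_region(rot_rect(60, 60, 20, 10, 0))
  cand <- detect_corners(reg)
  expect_gte(nrow(cand), 4)
  truth <- rot_rect(60, 60, 20, 10, 0)
  for (k in 1:4) {
    d <- sqrt(rowSums(sweep(as.matrix(cand[1:4, c("x", "y")]), 2,
                            truth[k, ])^2))
    expect_lt(min(d), 2)
  }
  disk <- outer(1:120, 1:120, function(i, j) (i - 60)^2 + (j - 60)^2 <= 400)
  expect_error(detect_corners(list(support = disk, class = "lumbar",
                                   identity = "L3")),
               class = "lumbometry_corner_shortage")
})

test_that("corner labelling across rotations and scales", {
  for (ang in c(-30, -15, 0, 15, 30)) {
    for (sc in c(0.5, 1, 2)) {
      quad <- rot_rect(70, 70, 14 * sc, 9 * sc, ang)
      reg <- quad_region(quad)
      lab <- assign_anatomical_labels(detect_corners(reg), reg, "left")
      expect_named(lab, c("L3SA", "L3SP", "L3IA", "L3IP"))
      err <- vapply(lab, function(p) {
        min(sqrt(rowSums(sweep(quad, 2, p)^2)))
      }, numeric(1))
      expect_lt(max(err), 2)
    }
  }
})

test_that("anterior side drives the A/P assignment", {
  reg <- quad_region(rot_rect(60, 60, 20, 10, 0))
  l <- assign_anatomical_labels(detect_corners(reg), reg, "left")
  r <- assign_anatomical_labels(detect_corners(reg), reg, "right")
  expect_lt(l$L3SA[1], l$L3SP[1])
  expect_gt(r$L3SA[1], r$L3SP[1])
  expect_equal(unname(l$L3SA), unname(r$L3SP))
})

test_that("mask_to_keypoints recovers phantom landmarks within 2 px", {
  for (s in c(3, 21)) {
    side <- if (s %% 2) "left" else "right"
    ph <- quick_phantom(seed = s, side = side)
    kp <- mask_to_keypoints(ph$mask, pixel_spacing = c(1, 1))
    expect_equal(kp$anterior_side, side)  # inferred from sacral slope
    expect_setequal(rownames(kp$points), KEYPOINT_VOCABULARY)
    d <- sqrt(rowSums((kp$points[KEYPOINT_VOCABULARY, ] -
                       ph$keypoints$points[KEYPOINT_VOCABULARY, ])^2))
    expect_lt(max(d), 2.5)
  }
})

test_that("mask_to_keypoints is deterministic and mirror-equivariant", {
  ph <- quick_phantom(seed = 6)
  k1 <- mask_to_keypoints(ph$mask)
  k2 <- mask_to_keypoints(ph$mask)
  expect_identical(k1$points, k2$points)
  W <- ncol(ph$mask)
  km <- mask_to_keypoints(ph$mask[, W:1])
  expect_equal(km$anterior_side, "right")
  expect_equal(unname(km$points[KEYPOINT_VOCABULARY, 1]),
               unname(W - 1 - k1$points[KEYPOINT_VOCABULARY, 1]),
               tolerance = 1e-9)
  expect_equal(unname(km$points[KEYPOINT_VOCABULARY, 2]),
               unname(k1$points[KEYPOINT_VOCABULARY, 2]), tolerance = 1e-9)
  # integer translation equivariance
  sh <- matrix(0L, nrow(ph$mask), ncol(ph$mask))
  sh[3:nrow(sh), ] <- ph$mask[1:(nrow(sh) - 2), ]
  kt <- mask_to_keypoints(sh)
  expect_equal(unname(kt$points[KEYPOINT_VOCABULARY, 2]),
               unname(k1$points[KEYPOINT_VOCABULARY, 2] + 2),
               tolerance = 1e-9)
})
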