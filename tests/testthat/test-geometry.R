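# Measurement geometry: endplate lines, the four parameters, invariances.

test_that("endplate_line normalises direction toward the anterior side", {
  l <- endplate_line(c(0, 0), c(10, 0), "left")
  expect_equal(abs(l$direction), c(1, 0))
  expect_lte(l$direction[1], 0)  # anterior (left) x-component
  lv <- endplate_line(c(0, 0), c(0, 5), "left")
  expect_equal(abs(lv$direction), c(0, 1))
  ld <- endplate_line(c(1, 1), c(4, 3), "left")
  expect_equal(abs(sum(ld$direction * c(3, 2) / sqrt(13))), 1,
               tolerance = 1e-12)
  expect_error(endplate_line(c(1, 1), c(1, 1)),
               class = "lumbometry_degenerate_geometry")
})

test_that("angle_between_lines is symmetric, bounded and exact on axes", {
  l1 <- lumbometry:::line2d(c(0, 0), c(1, 0))
  l2 <- lumbometry:::line2d(c(5, 5), c(1, 0))
  l3 <- lumbometry:::line2d(c(0, 0), c(0, 1))
  l4 <- lumbometry:::line2d(c(0, 0), c(1, 1))
  expect_equal(angle_between_lines(l1, l2), 0)
  expect_equal(angle_between_lines(l1, l3), 90)
  expect_equal(angle_between_lines(l1, l4), 45, tolerance = 1e-12)
  for (s in 1:20) {
    a <- lumbometry:::line2d(c(0, 0), stats::rnorm(2))
    b <- lumbometry:::line2d(c(0, 0), stats::rnorm(2))
    ang <- angle_between_lines(a, b)
    expect_equal(ang, angle_between_lines(b, a))
    expect_gte(ang, 0); expect_lte(ang, 90)
  }
})

test_that("LL and SHA on hand-built configurations", {
  kps <- kps_rect_stack()
  expect_equal(lumbar_lordosis(kps), 0)
  expect_equal(sacral_horizontal_angle(kps), 0)
  # S1 endplate at 40 deg, L1 horizontal
  kps$points["S1SA", ] <- kps$points["S1SP", ] +
    40 * c(-cos(40 * pi / 180), sin(40 * pi / 180))
  expect_equal(lumbar_lordosis(kps), 40, tolerance = 1e-9)
  expect_equal(sacral_horizontal_angle(kps), 40, tolerance = 1e-9)
  # horizontal S1 endplate examples
  k2 <- keypoint_set(rbind(S1SA = c(10, 50), S1SP = c(40, 50)))
  expect_equal(sacral_horizontal_angle(k2), 0)
  k3 <- keypoint_set(rbind(S1SA = c(0, 0), S1SP = c(10, 10)))
  expect_equal(sacral_horizontal_angle(k3), 45, tolerance = 1e-12)
  expect_error(lumbar_lordosis(keypoint_set(rbind(L1SA = c(0, 0)))),
               class = "lumbometry_missing_keypoint")
})

test_that("ISA sign convention: positive wedge opens anteriorly", {
  kps <- kps_rect_stack()
  expect_equal(intervertebral_space_angle(kps, "L4L5"), 0)
  expect_equal(intervertebral_space_angle(kps, "L5S1"), 0)
  # tilt L4 inferior endplate +10 deg (anterior up): disc opens anteriorly
  ip <- kps$points["L4IP", ]
  kps$points["L4IA", ] <- ip + 40 * c(-cos(10 * pi / 180),
                                      -sin(10 * pi / 180))
  expect_equal(intervertebral_space_angle(kps, "L4L5"), 10,
               tolerance = 1e-9)
  # mirrored image must preserve the sign
  m <- mirror_kps(kps, 80)
  expect_equal(intervertebral_space_angle(m, "L4L5"), 10, tolerance = 1e-9)
})

test_that("posterior edge construction per vertebra", {
  kps <- kps_rect_stack()
  l5 <- posterior_edge_line(kps, "L5")
  expect_equal(abs(l5$direction), c(0, 1))  # vertical posterior border
  expect_equal(l5$anchor, unname(kps$points["L5SP", ]))
  l4 <- posterior_edge_line(kps, "L4")
  expect_equal(abs(sum(l4$direction * l5$direction)), 1, tolerance = 1e-12)
  s1 <- posterior_edge_line(kps, "S1")  # horizontal endplate -> vertical
  expect_equal(abs(s1$direction), c(0, 1))
})

test_that("PLS evaluates the slip ratio by hand", {
  kps <- kps_rect_stack()
  expect_equal(percent_spondylolisthesis(kps, "L4L5"), 0, tolerance = 1e-9)
  expect_equal(percent_spondylolisthesis(kps, "L5S1"), 0, tolerance = 1e-9)
  # shift L4 anteriorly (left) by 5 px: N = 5, M = 40 -> +12.5 %
  kps$points["L4IA", ] <- kps$points["L4IA", ] - c(5, 0)
  kps$points["L4IP", ] <- kps$points["L4IP", ] - c(5, 0)
  expect_equal(percent_spondylolisthesis(kps, "L4L5"), 12.5,
               tolerance = 1e-9)
  # posterior (retro) slip is negative
  kps$points["L4IP", ] <- kps$points["L4IP", ] + c(12, 0)
  kps$points["L4IA", ] <- kps$points["L4IA", ] + c(12, 0)
  expect_equal(percent_spondylolisthesis(kps, "L4L5"), -17.5,
               tolerance = 1e-9)
})

test_that("degenerate geometry is reported, not silently computed", {
  kps <- kps_rect_stack()
  kps$points["S1SA", ] <- kps$points["S1SP", ]
  expect_error(percent_spondylolisthesis(kps, "L5S1"),
               class = "lumbometry_degenerate_geometry")
})

test_that("phantom closure: generated keypoints reproduce the targets", {
  for (s in c(3, 17, 42)) {
    pk <- phantom_keypoints(sample_spec(seed = s))
    got <- compute_all_parameters(pk$keypoints)
    expect_equal(unclass(got), unclass(pk$truth), tolerance = 1e-9)
  }
  # explicitly targeted values, as printed examples
  pk <- phantom_keypoints(phantom_spec(LL = 49.8, SHA = 38.1,
                                       ISA_L5S1 = 19.2, PLS_L4L5 = 12.3))
  got <- compute_all_parameters(pk$keypoints)
  expect_equal(got[["LL"]], 49.8, tolerance = 1e-6)
  expect_equal(got[["SHA"]], 38.1, tolerance = 1e-6)
  expect_equal(got[["ISA_L5S1"]], 19.2, tolerance = 1e-6)
  expect_equal(got[["PLS_L4L5"]], 12.3, tolerance = 1e-6)
})

test_that("translation, scaling and mirroring leave all parameters fixed", {
  for (s in 1:20) {
    pk <- phantom_keypoints(sample_spec(seed = 1000 + s))
    base <- unclass(compute_all_parameters(pk$keypoints))
    tr <- pk$keypoints
    tr$points <- sweep(tr$points, 2, c(13.7, -41.2), "+")
    expect_equal(unclass(compute_all_parameters(tr)), base,
                 tolerance = 1e-9)
    sc <- pk$keypoints
    sc$points <- sc$points * 2.37
    expect_equal(unclass(compute_all_parameters(sc)), base,
                 tolerance = 1e-9)
    mi <- mirror_kps(pk$keypoints, 128)
    expect_equal(unclass(compute_all_parameters(mi)), base,
                 tolerance = 1e-9)
  }
})

test_that("rotation changes SHA only", {
  for (s in 1:10) {
    pk <- phantom_keypoints(sample_spec(seed = 2000 + s))
    base <- unclass(compute_all_parameters(pk$keypoints))
    rot <- rotate_kps(pk$keypoints, 9.5, centre = c(64, 128))
    got <- unclass(compute_all_parameters(rot))
    keep <- c("LL", "ISA_L4L5", "ISA_L5S1", "PLS_L4L5", "PLS_L5S1")
    expect_equal(got[keep], base[keep], tolerance = 1e-9)
    expect_gt(abs(got[["SHA"]] - base[["SHA"]]), 1)
  }
})
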