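# Evaluation statistics and their independent oracles.

test_that("Dice and accuracy: identities and forced values", {
  a <- matrix(0L, 10, 10); a[3:7, 3:7] <- 1L
  expect_equal(dice_coefficient(a, a, 1L), 1)
  expect_equal(pixel_accuracy(a, a, 1L), 1)
  b <- matrix(0L, 10, 10)  # disjoint
  b[8:10, 8:10] <- 1L
  expect_equal(dice_coefficient(a, b, 1L), 0)
  # two 10x10 squares overlapping half their area
  p <- matrix(0L, 30, 30); p[1:10, 1:10] <- 1L
  q <- matrix(0L, 30, 30); q[1:10, 6:15] <- 1L
  expect_equal(dice_coefficient(p, q, 1L), 0.5)
  # both empty for a class
  expect_equal(dice_coefficient(b * 0L, b * 0L, 2L), 1)
  expect_error(dice_coefficient(a, matrix(0L, 5, 5), 1L),
               class = "lumbometry_data_error")
})

test_that("Dice/accuracy match brute-force recomputation on random masks", {
  set.seed(71)
  for (i in 1:25) {
    a <- matrix(sample(0:2, 100, TRUE), 10, 10)
    b <- matrix(sample(0:2, 100, TRUE), 10, 10)
    for (cls in 0:2) {
      expect_equal(dice_coefficient(a, b, cls), dice_brute(a, b, cls),
                   tolerance = 1e-12)
      expect_equal(pixel_accuracy(a, b, cls), acc_brute(a, b, cls),
                   tolerance = 1e-12)
      expect_equal(dice_coefficient(a, b, cls), dice_coefficient(b, a, cls))
    }
  }
})

test_that("PCK: identity, displacement, monotonicity", {
  ph <- phantom_keypoints(sample_spec(seed = 77))
  ref <- ph$keypoints
  expect_true(all(pck(ref, ref) == 100))
  # one landmark displaced 4 mm at 1 mm/px; threshold 3 -> 90 % overall
  pred <- ref
  pred$points["L3SA", ] <- pred$points["L3SA", ] + c(4, 0)
  tab <- pck(pred, ref, thresholds = 3,
             landmarks = rownames(ref$points)[1:10])
  # displaced landmark is not in the first-10 subset necessarily; use all
  tab <- pck(pred, ref, thresholds = 1:5,
             landmarks = rownames(ref$points))
  expect_equal(unname(tab["overall", "<=3"]),
               100 * (nrow(ref$points) - 1) / nrow(ref$points))
  expect_true(all(diff(tab["overall", ]) >= 0))
  set.seed(4)
  for (i in 1:10) {
    noisy <- ref
    noisy$points <- ref$points + matrix(rnorm(length(ref$points), 0, 2),
                                        nrow(ref$points))
    t2 <- pck(noisy, ref, thresholds = 1:5)
    expect_true(all(apply(t2, 1, function(r) all(diff(r) >= 0))))
  }
  nospc <- ref; nospc$pixel_spacing <- NULL
  expect_error(pck(nospc, nospc), class = "lumbometry_data_error")
})

test_that("observer reliability: identity, constant shift, simulation", {
  ph <- phantom_keypoints(sample_spec(seed = 88))
  ref <- ph$keypoints
  same <- observer_reliability(list(S1 = list(ref), S1b = list(ref)))
  expect_true(all(same == 100))
  shifted <- ref
  shifted$points <- ref$points + matrix(c(2.5, 0), nrow(ref$points), 2,
                                        byrow = TRUE)
  tab <- observer_reliability(list(A = list(ref), B = list(shifted)),
                              thresholds = 1:5)
  expect_equal(unname(unlist(tab[1, ])), c(0, 0, 100, 100, 100))
  # three raters with iid 1-mm-SD noise vs a Monte-Carlo oracle:
  # pairwise distance ~ 1mm * sqrt(2) * chi(2)
  set.seed(12)
  raters <- lapply(1:3, function(r) {
    lapply(1:120, function(i) {
      k <- ref
      k$points <- ref$points + matrix(rnorm(length(ref$points)),
                                      nrow(ref$points))
      k
    })
  })
  names(raters) <- c("S1", "S2", "S3")
  tab3 <- observer_reliability(raters, thresholds = 1:3)
  oracle <- stats::pchisq((1:3)^2 / 2, df = 2) * 100
  for (r in 1:3) {
    expect_lt(max(abs(unlist(tab3[r, ]) - oracle)), 2.5)
  }
})

test_that("reference standard averages raters and reduces noise", {
  expect_equal(reference_standard(list(c(1, 2, 3))), c(1, 2, 3))
  expect_equal(reference_standard(list(c(0, 0), c(2, 0), c(4, 0))), c(2, 0))
  ph <- phantom_keypoints(sample_spec(seed = 99))
  truth <- ph$keypoints
  set.seed(5)
  raters <- lapply(1:3, function(r) {
    k <- truth
    k$points <- truth$points + matrix(rnorm(length(truth$points), 0, 1.5),
                                      nrow(truth$points))
    k
  })
  avg <- reference_standard(raters)
  rms <- function(k) sqrt(mean((k$points - truth$points)^2))
  expect_lt(rms(avg), min(vapply(raters, rms, numeric(1))))
  bad <- raters
  rownames(bad[[2]]$points)[1] <- "XXSA"
  expect_error(reference_standard(bad), class = "lumbometry_data_error")
})

test_that("ICC(2,1) matches the ANOVA oracle and behaves under bias", {
  expect_equal(icc21(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))$icc, 1)
  # 6-pair hand table
  Y <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  expect_equal(icc21(Y)$icc, icc21_oracle(Y), tolerance = 1e-9)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    Y <- matrix(rnorm(n * k, 10, 3), n, k) +
      rnorm(n, 0, 2)  # subject effect
    r <- icc21(Y)
    expect_equal(r$icc, icc21_oracle(Y), tolerance = 1e-9)
    expect_lte(r$icc, 1)
    expect_lte(r$ci[1], r$icc + 1e-9)
    expect_gte(r$ci[2], r$icc - 1e-9)
  }
  # constant bias lowers absolute-agreement ICC but not Pearson r
  x <- rnorm(20, 50, 8)
  y <- x + rnorm(20, 0, 1)
  base <- icc21(x, y)$icc
  biased <- icc21(x, y + 5)$icc
  expect_lt(biased, base)
  expect_equal(cor(x, y), cor(x, y + 5))
  expect_error(icc21(rep(1, 5), rep(1, 5)),
               class = "lumbometry_undefined_icc")
})

test_that("agreement_report identities, shifts and brute-force checks", {
  x <- c(10, 12, 14, 16, 18)
  r0 <- suppressWarnings(agreement_report(x, x))
  expect_equal(r0$md, 0); expect_equal(r0$mae, 0); expect_equal(r0$rmse, 0)
  r2 <- agreement_report(x, x + 2)
  expect_equal(r2$md, 2); expect_equal(r2$sd, 0)
  expect_equal(r2$mae, 2); expect_equal(r2$rmse, 2)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(15, 40, 6); b <- a + rnorm(15, 1, 2)
    rep <- agreement_report(a, b)
    d <- b - a
    expect_equal(rep$md, mean(d), tolerance = 1e-12)
    expect_equal(rep$mae, mean(abs(d)), tolerance = 1e-12)
    expect_equal(rep$rmse, sqrt(mean(d^2)), tolerance = 1e-12)
    expect_lte(rep$mae, rep$rmse)
    expect_equal(rep$quartiles,
                 unname(quantile(d, c(0, .25, .5, .75, 1))),
                 tolerance = 1e-12)
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(rep$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(rep$p, tt$p.value, tolerance = 1e-12)
    # order invariance
    p <- sample(15)
    rp <- agreement_report(a[p], b[p])
    expect_equal(rp$rmse, rep$rmse, tolerance = 1e-12)
    expect_equal(rp$icc, rep$icc, tolerance = 1e-12)
  }
})
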