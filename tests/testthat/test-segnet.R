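# Network blocks, training mechanics and augmentation.

fwd <- lumbometry:::forward_net
bwd <- lumbometry:::backward_net

test_that("configuration contracts are enforced", {
  expect_error(network_config(branch_channels = c(8, 16)),
               class = "lumbometry_config_error")
  expect_error(network_config(input_size = c(30, 16)),
               class = "lumbometry_config_error")
  expect_error(build_network(network_config(
    input_size = c(32, 16), branch_channels = c(6L, 12L, 24L),
    reduction = 5L), quiet = TRUE),
    class = "lumbometry_config_error")
})

test_that("conv-BN-SiLU block: shape contract, SiLU(0) = 0, finiteness", {
  set.seed(1)
  blk <- lumbometry:::cbs_make(3L, 2L, 5L)
  x <- array(rnorm(20 * 12 * 2 * 3), c(20, 12, 2, 3))
  out <- lumbometry:::cbs_f(blk, x, training = TRUE)
  expect_equal(dim(out$y), c(20, 12, 5, 3))
  expect_true(all(is.finite(out$y)))
  expect_equal(lumbometry:::silu_f(array(0, c(2, 2, 1, 1)))$y,
               array(0, c(2, 2, 1, 1)))
  for (s in 1:3) {
    set.seed(100 + s)
    blk2 <- lumbometry:::cbs_make(3L, 1L, 4L)
    x2 <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
    expect_true(all(is.finite(lumbometry:::cbs_f(blk2, x2, TRUE)$y)))
  }
})

test_that("residual attention block: gate identity / annihilation / shape", {
  set.seed(2)
  blk <- lumbometry:::ra_make(4L, 2L)
  x <- array(rnorm(12 * 8 * 4 * 2), c(12, 8, 4, 2))
  base <- lumbometry:::ra_f(blk, x, training = FALSE)
  expect_equal(dim(base$y), dim(x))
  # gate forced to 1: plain residual branch + identity
  g1 <- lumbometry:::ra_f(blk, x, training = FALSE, force_gate = 1)
  c2 <- lumbometry:::conv_f(blk$conv2,
                            lumbometry:::cbs_f(blk$cbs1, x, FALSE)$y)
  b2 <- lumbometry:::bn_f(blk$bn2, c2$y, FALSE)
  expect_equal(g1$y, lumbometry:::silu_f(x + b2$y)$y, tolerance = 1e-12)
  # gate forced to 0: only the identity path (then SiLU)
  g0 <- lumbometry:::ra_f(blk, x, training = FALSE, force_gate = 0)
  expect_equal(g0$y, lumbometry:::silu_f(x)$y, tolerance = 1e-12)
})

test_that("fusion and dilated modules: shape and sensitivity", {
  cfg <- tiny_net_config(seed = 7)
  net <- build_network(cfg, quiet = TRUE)
  x <- array(rnorm(32 * 16), c(32, 16, 1, 1))
  out <- fwd(net, x, training = FALSE)
  expect_equal(dim(out$logits), c(32, 16, 3, 1))
  # ablating the fusion residual add changes the output
  net2 <- build_network(cfg, quiet = TRUE)
  net2$layers$fuse1$b <- net2$layers$fuse1$b + 0.5
  expect_false(isTRUE(all.equal(out$logits,
                                fwd(net2, x, FALSE)$logits)))
  # dilated-branch impulse response: 5x5 kernel at dilation 2 reaches
  # exactly 4 pixels from the centre along each axis
  w <- array(0, c(5, 5, 1, 1)); w[3, 3, 1, 1] <- 0  # build impulse probe
  imp <- array(0, c(17, 17, 1, 1)); imp[9, 9, 1, 1] <- 1
  k <- array(1, c(5, 5, 1, 1))
  resp <- lumbometry:::cpp_conv2d_fwd(imp, k, 0, 2L)
  on <- which(resp[, , 1, 1] != 0, arr.ind = TRUE)
  expect_equal(range(on[, 1]), c(9 - 4, 9 + 4))
  expect_equal(range(on[, 2]), c(9 - 4, 9 + 4))
})

test_that("build determinism and gradient flow", {
  cfg <- tiny_net_config(seed = 3)
  x <- with_seed(5, array(rnorm(32 * 16), c(32, 16, 1, 1)))
  n1 <- build_network(cfg, quiet = TRUE)
  n2 <- build_network(cfg, quiet = TRUE)
  expect_identical(fwd(n1, x, FALSE)$logits, fwd(n2, x, FALSE)$logits)
  # every trainable tensor receives a nonzero gradient on random data
  msk <- with_seed(6, matrix(sample(0:2, 32 * 16, TRUE), 32, 16))
  tgt <- lumbometry:::mask_onehot(list(msk), 3L)
  f <- fwd(n1, x, training = TRUE)
  ls <- lumbometry:::seg_loss(f$logits, tgt)
  lumbometry:::zero_grads(n1)
  bwd(n1, f$cache, ls$gz)
  for (e in n1$params) {
    if (e$kind == "conv") {
      expect_gt(max(abs(e$gw)), 0)
      expect_gt(max(abs(e$gb)), 0)
    } else {
      expect_gt(max(abs(e$ggamma)), 0)
      expect_gt(max(abs(e$gbeta)), 0)
    }
  }
})

test_that("gradients match finite differences on a tiny network", {
  cfg <- tiny_net_config(seed = 9)
  net <- build_network(cfg, quiet = TRUE)
  x <- with_seed(10, array(rnorm(32 * 16 * 2), c(32, 16, 1, 2)))
  msk <- with_seed(11, list(matrix(sample(0:2, 32 * 16, TRUE), 32, 16),
                            matrix(sample(0:2, 32 * 16, TRUE), 32, 16)))
  tgt <- lumbometry:::mask_onehot(msk, 3L)
  lossv <- function() {
    lumbometry:::seg_loss(fwd(net, x, TRUE)$logits, tgt)
  }
  ls <- lossv()
  lumbometry:::zero_grads(net)
  bwd(net, fwd(net, x, TRUE)$cache, ls$gz)
  eps <- 1e-6
  set.seed(12)
  for (trial in 1:10) {
    e <- net$params[[sample(length(net$params), 1)]]
    fld <- if (e$kind == "conv") "w" else sample(c("gamma", "beta"), 1)
    gfld <- paste0("g", fld)
    idx <- sample(length(e[[fld]]), 1)
    orig <- e[[fld]][idx]
    e[[fld]][idx] <- orig + eps
    lp <- lossv()$loss
    e[[fld]][idx] <- orig - eps
    lm_ <- lossv()$loss
    e[[fld]][idx] <- orig
    num <- (lp - lm_) / (2 * eps)
    expect_equal(e[[gfld]][idx], num, tolerance = 1e-3)
  }
})

test_that("training smoke: runs, records history, errors on empty data", {
  cfg <- tiny_net_config(seed = 2)
  net <- build_network(cfg, quiet = TRUE)
  mk <- function(s) {
    with_seed(s, list(image = matrix(runif(32 * 16), 32, 16),
                      mask = {
                        m <- matrix(0L, 32, 16)
                        m[8:16, 4:10] <- 1L
                        m[20:26, 6:12] <- 2L
                        m
                      }))
  }
  tc <- train_config(epochs = 1, batch_size = 2, augment = FALSE, seed = 0)
  out <- train_segnet(net, list(mk(1), mk(2)), tc)
  expect_s3_class(out$history, "data.frame")
  expect_true(all(is.finite(out$history$loss)))
  expect_error(train_segnet(net, list(), tc),
               class = "lumbometry_data_error")
})

test_that("training is reproducible under identical config and seed", {
  mkd <- function() {
    lapply(1:2, function(s) {
      with_seed(s, list(image = matrix(runif(32 * 16), 32, 16),
                        mask = matrix(sample(0:2, 32 * 16, TRUE,
                                             prob = c(.8, .1, .1)),
                                      32, 16)))
    })
  }
  tc <- train_config(epochs = 2, batch_size = 2, augment = TRUE, seed = 4)
  n1 <- train_segnet(build_network(tiny_net_config(1), quiet = TRUE),
                     mkd(), tc)
  n2 <- train_segnet(build_network(tiny_net_config(1), quiet = TRUE),
                     mkd(), tc)
  expect_identical(n1$history, n2$history)
  img <- mkd()[[1]]$image
  expect_identical(predict_mask(n1, img), predict_mask(n2, img))
})

test_that("predict_mask: determinism, label range, resampling", {
  net <- build_network(tiny_net_config(4), quiet = TRUE)
  img <- with_seed(7, matrix(runif(32 * 16), 32, 16))
  m1 <- predict_mask(net, img)
  expect_identical(m1, predict_mask(net, img))
  expect_true(all(m1 %in% 0:2))
  expect_equal(dim(m1), c(32, 16))
  # off-size image is resampled through the network and mapped back
  img2 <- with_seed(8, matrix(runif(48 * 20), 48, 20))
  m2 <- predict_mask(net, img2)
  expect_equal(dim(m2), c(48, 20))
})

test_that("augment: identity parameters, equalisation, rotation behaviour", {
  img <- with_seed(3, matrix(runif(40 * 40), 40, 40))
  msk <- matrix(0L, 40, 40); msk[10:20, 12:25] <- 1L; msk[25:33, 5:15] <- 2L
  ident <- train_config(augment = TRUE, hist_eq_prob = 0,
                        gamma_range = c(1, 1), rotation_range = 0)
  a <- with_seed(1, augment(img, msk, ident))
  expect_equal(a$image, img)
  expect_identical(a$mask, msk)
  # 360-degree rotation is the identity up to interpolation at borders
  r360 <- lumbometry:::rotate_pair(img, msk, 360)
  expect_equal(r360$image[5:35, 5:35], img[5:35, 5:35], tolerance = 1e-9)
  # NN-resampled mask after 90 deg rotation of a square image conserves
  # the label multiset
  r90 <- lumbometry:::rotate_pair(img, msk, 90)
  expect_equal(as.vector(table(r90$mask)), as.vector(table(msk)))
  # keypoints rotate with the image
  kp <- keypoint_set(rbind(L5SA = c(12, 10), L5SP = c(25, 10)))
  rk <- lumbometry:::rotate_pair(img, msk, 30, kp)$keypoints
  expect_equal(sqrt(sum((rk$points["L5SA", ] - rk$points["L5SP", ])^2)),
               13, tolerance = 1e-9)
  # gamma = identity on {0, 1}; histogram equalisation keeps [0, 1]
  he <- hist_equalize(img)
  expect_gte(min(he), 0); expect_lte(max(he), 1)
})
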