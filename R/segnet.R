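# Multi-scale attention segmentation network.
#
# Topology: a three-branch backbone (full, half, quarter resolution) of
# conv-BN-SiLU blocks with residual channel attention; a fusion module that
# resamples the branches to the quarter scale, concatenates, 1x1-fuses,
# adds the minimum-scale map and applies a 3x3 conv; then two parallel
# heads - a residual dilated-convolution module (kernels 1/3/5, dilations
# 1/2/2) and a convolutional feature re-extraction module - combined by
# addition; a light decoder restores full resolution (nearest upsampling
# plus the full-resolution branch as a skip) before the class head.

#' Segmentation network configuration
#'
#' @param input_size image `(rows, cols)`, both divisible by 4.
#' @param n_classes number of labels (background, lumbar, sacrum).
#' @param branch_channels channels of the three scale branches.
#' @param reduction channel-attention squeeze ratio.
#' @param dilations list of `(kernel, dilation)` for the dilated module.
#' @param decoder_channels channels of the resolution-restoring decoder.
#' @param seed initialisation seed.
#' @return object of class `network_config`.
#' @export
network_config <- function(input_size = c(256, 128), n_classes = 3L,
                           branch_channels = c(8L, 16L, 32L),
                           reduction = 4L,
                           dilations = list(c(1L, 1L), c(3L, 2L), c(5L, 2L)),
                           decoder_channels = 16L, seed = 0L) {
  if (length(branch_channels) != 3) {
    abort_lm("lumbometry_config_error", "exactly three scale branches")
  }
  if (any(input_size %% 4 != 0)) {
    abort_lm("lumbometry_config_error",
             "input size must be divisible by 4, got %d x %d",
             input_size[1], input_size[2])
  }
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 branch_channels = as.integer(branch_channels),
                 reduction = as.integer(reduction), dilations = dilations,
                 decoder_channels = as.integer(decoder_channels),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Assemble the segmentation network
#'
#' @param config a [network_config()].
#' @param quiet suppress the parameter-count message.
#' @return a `segnet` model object.
#' @export
build_network <- function(config = network_config(), quiet = FALSE) {
  cb <- config$branch_channels
  cd <- config$decoder_channels
  ncls <- config$n_classes
  with_seed(config$seed, {
    L <- list(
      stem = cbs_make(3L, 1L, cb[1]),
      b1 = cbs_make(3L, cb[1], cb[1]),
      b1ra = ra_make(cb[1], config$reduction),
      b2 = cbs_make(3L, cb[1], cb[2]),
      b2ra = ra_make(cb[2], config$reduction),
      b3 = cbs_make(3L, cb[1], cb[3]),
      b3ra = ra_make(cb[3], config$reduction),
      fuse1 = nn_conv(1L, 1L, sum(cb), cb[3]),
      fuse2 = cbs_make(3L, cb[3], cb[3]),
      dil_br = lapply(config$dilations, function(kd) {
        cbs_make(as.integer(kd[1]), cb[3], cb[3] %/% 2L,
                 dil = as.integer(kd[2]))
      }),
      dil_fuse = nn_conv(1L, 1L, 3L * (cb[3] %/% 2L), cb[3]),
      cfe1 = cbs_make(3L, cb[3], cb[3]),
      cfe2 = cbs_make(3L, cb[3], cb[3]),
      dec1 = cbs_make(3L, cb[3], cd),
      dec2 = cbs_make(1L, cd + cb[1], cd),
      head = nn_conv(1L, 1L, cd, ncls)
    )
    collect <- function(x) {
      if (is.environment(x)) return(list(x))
      if (is.list(x)) return(unlist(lapply(x, collect)))
      list()
    }
    params <- collect(L)
    n_par <- sum(vapply(params, function(e) {
      if (e$kind == "conv") length(e$w) + length(e$b) else
        2 * length(e$gamma)
    }, numeric(1)))
    if (!quiet) {
      message(sprintf("segmentation network: %d trainable parameters", n_par))
    }
    structure(list(config = config, layers = L, params = params,
                   n_parameters = n_par),
              class = "segnet")
  })
}

forward_net <- function(net, x, training = FALSE) {
  L <- net$layers
  cc <- list()
  cc$stem <- cbs_f(L$stem, x, training)
  cc$b1 <- cbs_f(L$b1, cc$stem$y, training)
  cc$b1ra <- ra_f(L$b1ra, cc$b1$y, training)
  p2 <- cpp_avgpool(cc$stem$y, 2L)
  cc$b2 <- cbs_f(L$b2, p2, training)
  cc$b2ra <- ra_f(L$b2ra, cc$b2$y, training)
  p4 <- cpp_avgpool(cc$stem$y, 4L)
  cc$b3 <- cbs_f(L$b3, p4, training)
  cc$b3ra <- ra_f(L$b3ra, cc$b3$y, training)
  # fusion at the minimum (quarter) scale
  d1 <- cpp_avgpool(cc$b1ra$y, 4L)
  d2 <- cpp_avgpool(cc$b2ra$y, 2L)
  cat1 <- concat_channels(list(d1, d2, cc$b3ra$y))
  cc$fuse1 <- conv_f(L$fuse1, cat1)
  fsum <- cc$fuse1$y + cc$b3ra$y
  cc$fuse2 <- cbs_f(L$fuse2, fsum, training)
  # residual dilated module
  cc$dil <- lapply(L$dil_br, function(blk) cbs_f(blk, cc$fuse2$y, training))
  dcat <- concat_channels(lapply(cc$dil, `[[`, "y"))
  cc$dil_fuse <- conv_f(L$dil_fuse, dcat)
  dil_out <- cc$dil_fuse$y + cc$fuse2$y
  # convolutional feature re-extraction
  cc$cfe1 <- cbs_f(L$cfe1, cc$fuse2$y, training)
  cc$cfe2 <- cbs_f(L$cfe2, cc$cfe1$y, training)
  comb <- dil_out + cc$cfe2$y
  # decoder
  cc$dec1 <- cbs_f(L$dec1, comb, training)
  up <- cpp_upsample_nn(cc$dec1$y, 4L)
  cat2 <- concat_channels(list(up, cc$b1ra$y))
  cc$dec2 <- cbs_f(L$dec2, cat2, training)
  cc$head <- conv_f(L$head, cc$dec2$y)
  list(logits = cc$head$y, cache = cc)
}

backward_net <- function(net, cache, glogits) {
  # returns the input gradient invisibly (unused in training)
  L <- net$layers
  cc <- cache
  cb <- net$config$branch_channels
  g <- conv_b(L$head, cc$head, glogits)
  g <- cbs_b(L$dec2, cc$dec2, g)
  gs <- split_channels(g, c(net$config$decoder_channels, cb[1]))
  g_b1ra <- gs[[2]]
  g <- cpp_upsample_nn_bwd(gs[[1]], 4L)
  g_comb <- cbs_b(L$dec1, cc$dec1, g)
  # comb = dil_out + cfe2
  g_cfe <- cbs_b(L$cfe1, cc$cfe1, cbs_b(L$cfe2, cc$cfe2, g_comb))
  # dil_out = dil_fuse + fuse2
  g_dcat <- conv_b(L$dil_fuse, cc$dil_fuse, g_comb)
  half <- cb[3] %/% 2L
  gds <- split_channels(g_dcat, rep(half, 3))
  g_fuse2 <- g_comb + g_cfe
  for (i in 1:3) {
    g_fuse2 <- g_fuse2 + cbs_b(L$dil_br[[i]], cc$dil[[i]], gds[[i]])
  }
  g_fsum <- cbs_b(L$fuse2, cc$fuse2, g_fuse2)
  g_cat1 <- conv_b(L$fuse1, cc$fuse1, g_fsum)
  gcs <- split_channels(g_cat1, cb)
  g_b3ra <- g_fsum + gcs[[3]]
  g_b2ra <- cpp_avgpool_bwd(gcs[[2]], 2L)
  g_b1ra <- g_b1ra + cpp_avgpool_bwd(gcs[[1]], 4L)
  g_b3 <- ra_b(L$b3ra, cc$b3ra, g_b3ra)
  g_p4 <- cbs_b(L$b3, cc$b3, g_b3)
  g_b2 <- ra_b(L$b2ra, cc$b2ra, g_b2ra)
  g_p2 <- cbs_b(L$b2, cc$b2, g_b2)
  g_b1 <- ra_b(L$b1ra, cc$b1ra, g_b1ra)
  g_stem <- cbs_b(L$b1, cc$b1, g_b1) +
    cpp_avgpool_bwd(g_p2, 2L) + cpp_avgpool_bwd(g_p4, 4L)
  invisible(cbs_b(L$stem, cc$stem, g_stem))
}

zero_grads <- function(net) {
  for (e in net$params) {
    if (e$kind == "conv") {
      e$gw[] <- 0; e$gb[] <- 0
    } else {
      e$ggamma[] <- 0; e$gbeta[] <- 0
    }
  }
  invisible(net)
}

adam_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(e, p, g, m, v) {
    if (is.null(e[[m]])) {
      e[[m]] <- e[[p]] * 0
      e[[v]] <- e[[p]] * 0
    }
    e[[m]] <- beta1 * e[[m]] + (1 - beta1) * e[[g]]
    e[[v]] <- beta2 * e[[v]] + (1 - beta2) * e[[g]]^2
    e[[p]] <- e[[p]] - lr * (e[[m]] / bc1) / (sqrt(e[[v]] / bc2) + eps)
  }
  for (e in net$params) {
    if (e$kind == "conv") {
      upd(e, "w", "gw", "mw", "vw")
      upd(e, "b", "gb", "mb", "vb")
    } else {
      upd(e, "gamma", "ggamma", "mgamma", "vgamma")
      upd(e, "beta", "gbeta", "mbeta", "vbeta")
    }
  }
  invisible(net)
}

# per-class softmax over the channel axis, computed slice-wise (K is tiny)
softmax4 <- function(z) {
  d <- dim(z)
  K <- d[3]
  sl <- lapply(seq_len(K), function(c) z[, , c, , drop = FALSE])
  mx <- Reduce(pmax, sl)
  es <- lapply(sl, function(s) exp(s - mx))
  tot <- Reduce(`+`, es)
  p <- array(0, d)
  for (c in seq_len(K)) p[, , c, ] <- es[[c]] / tot
  p
}

# combined cross-entropy + soft-Dice loss on logits; returns loss terms and
# the gradient with respect to the logits
seg_loss <- function(logits, target_onehot, w_ce = 1, w_dice = 1) {
  d <- dim(logits)
  K <- d[3]
  npx <- d[1] * d[2] * d[4]
  p <- softmax4(logits)
  ce <- -sum(target_onehot * log(pmax(p, 1e-12))) / npx
  dice <- numeric(K)
  gp <- vector("list", K)
  pc <- lapply(seq_len(K), function(c) p[, , c, , drop = FALSE])
  for (c in seq_len(K)) {
    tc <- target_onehot[, , c, , drop = FALSE]
    s1 <- sum(pc[[c]] * tc)
    s2 <- sum(pc[[c]]) + sum(tc)
    dice[c] <- if (s2 > 0) 2 * s1 / s2 else 1
    gp[[c]] <- if (s2 > 0) {
      -(2 / K) * (tc * s2 - s1) / s2^2 * w_dice
    } else {
      tc * 0
    }
  }
  loss <- w_ce * ce + w_dice * (1 - mean(dice))
  # logits gradient: CE shortcut plus softmax jacobian applied to gp
  dotsum <- Reduce(`+`, Map(`*`, gp, pc))
  gz <- w_ce * (p - target_onehot) / npx
  for (c in seq_len(K)) {
    gz[, , c, ] <- gz[, , c, , drop = FALSE] +
      pc[[c]] * (gp[[c]] - dotsum)
  }
  list(loss = loss, ce = ce, dice = dice, gz = gz)
}

#' Training configuration
#'
#' @param epochs,batch_size training schedule.
#' @param lr,lr_min Adam learning rate with cosine decay to `lr_min`.
#' @param w_ce,w_dice loss weights (cross-entropy, soft Dice).
#' @param augment enable data augmentation.
#' @param hist_eq_prob probability of histogram equalisation per sample.
#' @param gamma_range random intensity gamma range.
#' @param rotation_range random rotation half-range, degrees.
#' @param seed training seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, lr = 5e-3,
                         lr_min = 2e-4, w_ce = 1, w_dice = 1,
                         augment = TRUE, hist_eq_prob = 0.3,
                         gamma_range = c(0.8, 1.25), rotation_range = 5,
                         seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, all(gamma_range > 0))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_min = lr_min, w_ce = w_ce, w_dice = w_dice,
                 augment = augment, hist_eq_prob = hist_eq_prob,
                 gamma_range = gamma_range, rotation_range = rotation_range,
                 seed = as.integer(seed)),
            class = "train_config")
}

mask_onehot <- function(masks, K) {
  d <- dim(masks[[1]])
  t <- array(0, c(d[1], d[2], K, length(masks)))
  for (n in seq_along(masks)) {
    for (c in seq_len(K)) t[, , c, n] <- masks[[n]] == (c - 1L)
  }
  t
}

#' Train the segmentation network
#'
#' @param net a model from [build_network()].
#' @param data list of samples, each a list with `image` (matrix in
#'   `[0, 1]`) and `mask` (integer matrix); e.g. the elements of
#'   [generate_dataset()]`$samples`.
#' @param config a [train_config()].
#' @param val_data optional held-out samples; hard Dice is recorded for
#'   them every `val_every` epochs (and at the final epoch).
#' @param val_every validation cadence in epochs.
#' @return the trained `segnet` with a `history` data frame attached.
#' @export
train_segnet <- function(net, data, config = train_config(),
                         val_data = NULL, val_every = 5L) {
  if (length(data) == 0) abort_data("empty training dataset")
  K <- net$config$n_classes
  n <- length(data)
  steps_total <- config$epochs * ceiling(n / config$batch_size)
  history <- vector("list", config$epochs)
  step <- 0
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1, n)]
        imgs <- list(); msks <- list()
        for (i in seq_along(idx)) {
          s <- data[[idx[i]]]
          if (config$augment) {
            a <- augment(s$image, s$mask, config)
            imgs[[i]] <- a$image; msks[[i]] <- a$mask
          } else {
            imgs[[i]] <- s$image; msks[[i]] <- s$mask
          }
        }
        d <- dim(imgs[[1]])
        x <- array(unlist(imgs), c(d[1], d[2], 1, length(imgs)))
        tgt <- mask_onehot(msks, K)
        fw <- forward_net(net, x, training = TRUE)
        ls <- seg_loss(fw$logits, tgt, config$w_ce, config$w_dice)
        if (!is.finite(ls$loss)) {
          abort_lm("lumbometry_training_error",
                   "non-finite loss at epoch %d", ep)
        }
        zero_grads(net)
        backward_net(net, fw$cache, ls$gz)
        step <- step + 1
        lr <- config$lr_min + 0.5 * (config$lr - config$lr_min) *
          (1 + cos(pi * step / steps_total))
        adam_step(net, lr, t = step)
        losses <- c(losses, ls$loss)
      }
      val_dice <- c(NA, NA)
      if (!is.null(val_data) &&
          (ep %% val_every == 0 || ep == config$epochs)) {
        dsum <- matrix(0, length(val_data), 2)
        for (i in seq_along(val_data)) {
          pm <- predict_mask(net, val_data[[i]]$image)
          dsum[i, 1] <- dice_coefficient(pm, val_data[[i]]$mask, 1L)
          dsum[i, 2] <- dice_coefficient(pm, val_data[[i]]$mask, 2L)
        }
        val_dice <- colMeans(dsum)
      }
      history[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                                  val_dice_lumbar = val_dice[1],
                                  val_dice_sacrum = val_dice[2])
    }
  })
  net$history <- do.call(rbind, history)
  net
}

#' Predict a label mask for one image
#'
#' Images whose size differs from the network input are resampled (nearest
#' neighbour) for inference and the predicted mask is mapped back, so
#' landmarks derived from it stay in the original pixel grid.
#'
#' @param net a `segnet` model.
#' @param image numeric matrix in `[0, 1]`.
#' @return integer matrix of labels (0 background, 1 lumbar, 2 sacrum).
#' @export
predict_mask <- function(net, image) {
  sz <- net$config$input_size
  orig <- dim(image)
  if (!all(orig == sz)) {
    image <- resize_nearest(image, sz)
  }
  x <- array(image, c(sz[1], sz[2], 1, 1))
  fw <- forward_net(net, x, training = FALSE)
  z <- fw$logits[, , , 1]
  lab <- max.col(matrix(z, ncol = dim(z)[3]), ties.method = "first") - 1L
  m <- matrix(as.integer(lab), sz[1], sz[2])
  if (!all(orig == sz)) m <- resize_nearest(m, orig)
  m
}

resize_nearest <- function(m, size_out) {
  ri <- pmin(pmax(round((seq_len(size_out[1]) - 0.5) *
                          nrow(m) / size_out[1] + 0.5), 1), nrow(m))
  ci <- pmin(pmax(round((seq_len(size_out[2]) - 0.5) *
                          ncol(m) / size_out[2] + 0.5), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Photometric and geometric training augmentation
#'
#' Applies (in order) probabilistic global histogram equalisation, a random
#' intensity gamma, and a random rotation about the image centre; the
#' rotation uses bilinear interpolation for the image and nearest-neighbour
#' for the mask, and is applied identically to landmark coordinates.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask integer label matrix.
#' @param config a [train_config()] (fields `hist_eq_prob`, `gamma_range`,
#'   `rotation_range`).
#' @param kps optional [keypoint_set()] rotated with the same transform.
#' @return list with `image`, `mask`, optionally `keypoints`, and `angle`.
#' @export
augment <- function(image, mask, config = train_config(), kps = NULL) {
  if (stats::runif(1) < config$hist_eq_prob) {
    image <- hist_equalize(image)
  }
  gma <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
  image <- pmin(pmax(image, 0), 1)^gma
  ang <- stats::runif(1, -config$rotation_range, config$rotation_range)
  r <- rotate_pair(image, mask, ang, kps)
  list(image = r$image, mask = r$mask, keypoints = r$keypoints, angle = ang)
}

#' Global histogram equalisation
#' @param image matrix in `[0, 1]`.
#' @return equalised matrix in `[0, 1]`.
#' @export
hist_equalize <- function(image) {
  q <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  cdf <- cumsum(tabulate(q + 1L, nbins = 256L))
  cdf_min <- cdf[which(cdf > 0)[1]]
  if (length(q) == cdf_min) return(image)  # constant image
  cdf <- (cdf - cdf_min) / (length(q) - cdf_min)
  matrix(pmin(pmax(cdf[q + 1L], 0), 1), nrow(image), ncol(image))
}

# rotate image (bilinear), mask (nearest) and keypoints by `angle` degrees
# about the image centre; out-of-frame pixels become 0 / background
rotate_pair <- function(image, mask, angle, kps = NULL) {
  if (abs(angle) < 1e-12) {
    return(list(image = image, mask = mask, keypoints = kps))
  }
  H <- nrow(image); W <- ncol(image)
  th <- deg2rad(angle)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  Y <- matrix(rep(seq_len(H) - 1, times = W), H, W) - cy
  # source coordinates: inverse rotation
  sx <- cos(th) * X + sin(th) * Y + cx
  sy <- -sin(th) * X + cos(th) * Y + cy
  bil <- function(m) {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    get <- function(yy, xx) {
      ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
      v <- matrix(0, H, W)
      v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
      v
    }
    get(y0, x0) * (1 - fx) * (1 - fy) + get(y0, x0 + 1) * fx * (1 - fy) +
      get(y0 + 1, x0) * (1 - fx) * fy + get(y0 + 1, x0 + 1) * fx * fy
  }
  nn <- function(m) {
    xx <- round(sx); yy <- round(sy)
    ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
    v <- matrix(0L, H, W)
    v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  out_k <- kps
  if (!is.null(kps)) {
    p <- kps$points
    px <- p[, 1] - cx; py <- p[, 2] - cy
    out_k <- kps
    out_k$points[, 1] <- cos(th) * px - sin(th) * py + cx
    out_k$points[, 2] <- sin(th) * px + cos(th) * py + cy
  }
  list(image = bil(image), mask = nn(mask), keypoints = out_k)
}
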