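# Minimal CNN primitives with explicit forward/backward passes.
#
# Feature maps are numeric arrays with dim (H, W, C, N).  Each trainable
# layer is an environment holding parameters, gradient accumulators and
# Adam state; backward passes accumulate into the environments so composite
# blocks need no gradient plumbing.

nn_conv <- function(kh, kw, cin, cout, dil = 1L, init_sd = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"
  if (is.null(init_sd)) init_sd <- sqrt(2 / (kh * kw * cin))
  e$w <- array(rnorm(kh * kw * cin * cout, 0, init_sd),
               c(kh, kw, cin, cout))
  e$b <- numeric(cout)
  e$dil <- as.integer(dil)
  e$gw <- array(0, dim(e$w)); e$gb <- numeric(cout)
  e
}

nn_bn <- function(c) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$rm <- numeric(c); e$rv <- rep(1, c)
  e$ggamma <- numeric(c); e$gbeta <- numeric(c)
  e
}

conv_f <- function(L, x) {
  list(y = cpp_conv2d_fwd(x, L$w, L$b, L$dil), x = x)
}
conv_b <- function(L, cache, gy) {
  r <- cpp_conv2d_bwd(cache$x, L$w, gy, L$dil)
  L$gw <- L$gw + r$gw
  L$gb <- L$gb + r$gb
  r$gx
}

# Per-channel statistics and broadcasts exploit the (H, W, C, N) layout:
# a length H*W*C vector recycles exactly once per batch sample, so channel
# broadcasting never needs sweep()/aperm() copies.
ch_mean <- function(x) {
  d <- dim(x)
  m <- .colMeans(x, d[1] * d[2], d[3] * d[4])
  .rowMeans(matrix(m, d[3], d[4]), d[3], d[4])
}
ch_sum <- function(x) {
  d <- dim(x)
  m <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(m, d[3], d[4]), d[3], d[4])
}
ch_rep <- function(v, d) rep(v, each = d[1] * d[2])

bn_f <- function(L, x, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    st <- cpp_channel_stats(x)
    mu <- st$mean
    v <- pmax(st$meansq - mu^2, 0)
    L$rm <- (1 - momentum) * L$rm + momentum * mu
    L$rv <- (1 - momentum) * L$rv + momentum * v
  } else {
    mu <- L$rm; v <- L$rv
  }
  istd <- 1 / sqrt(v + eps)
  r <- cpp_bn_fwd(x, mu, istd, L$gamma, L$beta)
  list(y = r$y, xhat = r$xhat, istd = istd, training = training)
}
bn_b <- function(L, cache, gy) {
  r <- cpp_bn_bwd(gy, cache$xhat, L$gamma, cache$istd, cache$training)
  L$ggamma <- L$ggamma + r$ggamma
  L$gbeta <- L$gbeta + r$gbeta
  r$gx
}

silu_f <- function(x) {
  r <- cpp_silu_fwd(x)
  list(y = r$y, s = r$s, x = x)
}
silu_b <- function(cache, gy) {
  cpp_silu_bwd(gy, cache$s, cache$x)
}

# channel-wise gate: g has dim (1, 1, C, N); rep(each = H*W) aligns one
# gate value per channel per sample with the flattened feature map
gate_apply <- function(x, g) {
  x * rep(as.vector(g), each = dim(x)[1] * dim(x)[2])
}
gate_b_x <- function(g, d, gy) {
  gy * rep(as.vector(g), each = d[1] * d[2])
}
gate_b_g <- function(x, gy) {
  d <- dim(x)
  array(.colSums(gy * x, d[1] * d[2], d[3] * d[4]), c(1, 1, d[3], d[4]))
}

gap_f <- function(x) {
  d <- dim(x)
  list(y = array(.colMeans(x, d[1] * d[2], d[3] * d[4]),
                 c(1, 1, d[3], d[4])),
       d = d)
}
gap_b <- function(cache, gy) {
  d <- cache$d
  g <- rep(as.vector(gy), each = d[1] * d[2]) / (d[1] * d[2])
  dim(g) <- d
  g
}

concat_channels <- function(xs) {
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  y <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  at <- 0
  for (x in xs) {
    C <- dim(x)[3]
    y[, , at + seq_len(C), ] <- x
    at <- at + C
  }
  y
}
split_channels <- function(gy, Cs) {
  at <- 0
  out <- vector("list", length(Cs))
  for (i in seq_along(Cs)) {
    out[[i]] <- gy[, , at + seq_len(Cs[i]), , drop = FALSE]
    at <- at + Cs[i]
  }
  out
}

## ---- conv + BN + SiLU block ------------------------------------------------

cbs_make <- function(kh, cin, cout, dil = 1L) {
  list(conv = nn_conv(kh, kh, cin, cout, dil), bn = nn_bn(cout))
}
cbs_f <- function(blk, x, training) {
  c1 <- conv_f(blk$conv, x)
  b1 <- bn_f(blk$bn, c1$y, training)
  s1 <- silu_f(b1$y)
  list(y = s1$y, c1 = c1, b1 = b1, s1 = s1)
}
cbs_b <- function(blk, cache, gy) {
  g <- silu_b(cache$s1, gy)
  g <- bn_b(blk$bn, cache$b1, g)
  conv_b(blk$conv, cache$c1, g)
}

## ---- residual channel-attention block (SE-ResNet variant) -----------------
# Residual branch: conv-bn-silu, conv-bn; squeeze-excite with 1x1 convs and
# SiLU in place of FC+ReLU; sigmoid channel gate on the branch; identity
# add; SiLU after the addition.

ra_make <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  if (c %% reduction != 0) {
    abort_lm("lumbometry_config_error",
             "attention reduction %d does not divide %d channels",
             reduction, c)
  }
  list(cbs1 = cbs_make(3L, c, c),
       conv2 = nn_conv(3L, 3L, c, c), bn2 = nn_bn(c),
       att1 = nn_conv(1L, 1L, c, cr), att2 = nn_conv(1L, 1L, cr, c))
}
ra_f <- function(blk, x, training, force_gate = NULL) {
  f1 <- cbs_f(blk$cbs1, x, training)
  c2 <- conv_f(blk$conv2, f1$y)
  b2 <- bn_f(blk$bn2, c2$y, training)
  z <- gap_f(b2$y)
  a1c <- conv_f(blk$att1, z$y)
  a1s <- silu_f(a1c$y)
  a2c <- conv_f(blk$att2, a1s$y)
  sg <- 1 / (1 + exp(-a2c$y))
  g <- if (is.null(force_gate)) sg else
    array(force_gate, dim(sg))
  scaled <- gate_apply(b2$y, g)
  out <- silu_f(x + scaled)
  list(y = out$y, f1 = f1, c2 = c2, b2 = b2, z = z, a1c = a1c, a1s = a1s,
       a2c = a2c, sg = sg, g = g, bd = dim(b2$y), bx = b2$y, out = out,
       forced = !is.null(force_gate))
}
ra_b <- function(blk, cache, gy) {
  g <- silu_b(cache$out, gy)
  gx_id <- g
  g_scaled <- g
  g_b2 <- gate_b_x(cache$g, cache$bd, g_scaled)
  if (!cache$forced) {
    gg <- gate_b_g(cache$bx, g_scaled)
    ga2 <- gg * cache$sg * (1 - cache$sg)
    ga1 <- conv_b(blk$att2, cache$a2c, ga2)
    ga1 <- silu_b(cache$a1s, ga1)
    gz <- conv_b(blk$att1, cache$a1c, ga1)
    g_b2 <- g_b2 + gap_b(cache$z, gz)
  }
  g2 <- bn_b(blk$bn2, cache$b2, g_b2)
  g2 <- conv_b(blk$conv2, cache$c2, g2)
  gx_id + cbs_b(blk$cbs1, cache$f1, g2)
}
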