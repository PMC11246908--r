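# Shared fixtures: all built in code at test time.

# keypoint set of an idealised spine with every endplate horizontal except
# as configured; coordinates chosen by hand for analytic checks
kps_rect_stack <- function(anterior_side = "left") {
  keypoint_set(rbind(
    L1SA = c(20, 10), L1SP = c(60, 10),
    L4IA = c(20, 85), L4IP = c(60, 85),
    L5SA = c(20, 92), L5SP = c(60, 92),
    L5IA = c(20, 118), L5IP = c(60, 118),
    S1SA = c(20, 125), S1SP = c(60, 125)
  ), anterior_side = anterior_side, pixel_spacing = c(1, 1))
}

# rotate a keypoint set about a centre (image-coordinate rotation)
rotate_kps <- function(kps, angle_deg, centre = c(0, 0)) {
  th <- angle_deg * pi / 180
  p <- kps$points
  px <- p[, 1] - centre[1]; py <- p[, 2] - centre[2]
  kps$points[, 1] <- cos(th) * px - sin(th) * py + centre[1]
  kps$points[, 2] <- sin(th) * px + cos(th) * py + centre[2]
  kps
}

mirror_kps <- function(kps, width) {
  kps$points[, 1] <- width - kps$points[, 1]
  kps$anterior_side <- if (kps$anterior_side == "left") "right" else "left"
  kps
}

# a filled convex quadrilateral region fixture (vertebra stand-in)
quad_region <- function(quad, rows = 140, cols = 140, identity = "L3",
                        class = "lumbar") {
  sup <- lumbometry:::fill_convex_quad(quad, rows, cols)
  list(support = sup, class = class, identity = identity,
       centroid = c(x = mean(which(sup, arr.ind = TRUE)[, 2]) - 1,
                    y = mean(which(sup, arr.ind = TRUE)[, 1]) - 1),
       area = sum(sup))
}

# rectangle centred at (cx, cy), half-width hw, half-height hh, rotated
rot_rect <- function(cx, cy, hw, hh, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t(R %*% rbind(c(-hw, hw, hw, -hw), c(-hh, -hh, hh, hh))) + c(cx, cy)
}

# brute-force Dice / accuracy by explicit pixel loops (independent oracle)
dice_brute <- function(a, b, cls) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    pa <- a[i, j] == cls; pb <- b[i, j] == cls
    if (pa && pb) inter <- inter + 1
    if (pa) na <- na + 1
    if (pb) nb <- nb + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}
acc_brute <- function(a, b, cls) {
  ok <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if ((a[i, j] == cls) == (b[i, j] == cls)) ok <- ok + 1
  }
  ok / length(a)
}

# ICC(2,1) oracle: mean squares from stats::aov on the long-format table
icc21_oracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# small deterministic phantom helpers
quick_phantom <- function(seed = 1, noise = 0, blur = 0, side = "left") {
  sp <- sample_spec(seed = seed, anterior_side = side)
  sp$noise_sd <- noise
  sp$blur_sigma <- blur
  render_phantom(sp)
}

tiny_net_config <- function(seed = 1) {
  network_config(input_size = c(32, 16), branch_channels = c(4L, 4L, 4L),
                 reduction = 2L, decoder_channels = 4L, seed = seed)
}

with_seed <- lumbometry:::with_seed
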