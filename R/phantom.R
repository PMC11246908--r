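# Synthetic standing-lateral-radiograph phantoms.
#
# Five lumbar bodies and a sacrum are drawn as bright convex quadrilaterals
# on a noisy gradient background, arranged along a lordotic curve that is
# solved so the measurement geometry applied to the generated corner points
# reproduces the requested LL/SHA/ISA/PLS targets exactly (closure to float
# precision).  The curve is built from S1 upward: the S1 superior endplate is
# set by SHA, the two targeted disc wedges by the ISA targets, and the wedge
# remaining to reach LL is spread evenly over the eight untargeted segments
# (five vertebral bodies and three untargeted discs).  Slip is imposed by
# translating a vertebra (and everything above it) along the superior
# endplate of the vertebra below, the same axis along which the slip ratio
# is measured.

#' Sampling population for phantom targets
#'
#' Defaults are the reference-standard means and standard deviations of the
#' six parameters in the clinical cohort the generator emulates
#' (LL 49.77 +/- 7.82 deg, SHA 38.09 +/- 6.85 deg, ISA(L4-L5)
#' 14.86 +/- 4.07 deg, ISA(L5-S1) 19.15 +/- 8.07 deg, PLS(L4-L5)
#' 12.27 +/- 10.31 %, PLS(L5-S1) 13.36 +/- 9.25 %).  Targets are drawn from
#' normals truncated to `ranges`.
#'
#' @param means,sds named numeric vectors over
#'   `c("LL","SHA","ISA_L4L5","ISA_L5S1","PLS_L4L5","PLS_L5S1")`.
#' @param ranges 2-row matrix of truncation bounds (low, high) per parameter.
#' @return list used by [sample_spec()].
#' @export
phantom_population <- function(
    means = c(LL = 49.77, SHA = 38.09, ISA_L4L5 = 14.86, ISA_L5S1 = 19.15,
              PLS_L4L5 = 12.27, PLS_L5S1 = 13.36),
    sds = c(LL = 7.82, SHA = 6.85, ISA_L4L5 = 4.07, ISA_L5S1 = 8.07,
            PLS_L4L5 = 10.31, PLS_L5S1 = 9.25),
    ranges = rbind(low = c(5, 5, -30, -30, -20, -20),
                   high = c(85, 70, 45, 45, 45, 45))) {
  colnames(ranges) <- PARAMETER_NAMES
  stopifnot(all(is.finite(means)), all(is.finite(sds)), all(sds >= 0))
  list(means = means[PARAMETER_NAMES], sds = sds[PARAMETER_NAMES],
       ranges = ranges)
}

#' Phantom specification
#'
#' @param LL,SHA,ISA_L4L5,ISA_L5S1 target angles, degrees.
#' @param PLS_L4L5,PLS_L5S1 target slip percentages.
#' @param size image `(rows, cols)`; portrait orientation fits the upright
#'   spine.
#' @param pixel_spacing mm per pixel `(row, col)`.
#' @param body_width,body_height,disc_height per-body sampling ranges, px.
#' @param sacrum_width S1 superior endplate AP diameter, px.
#' @param sacrum_depth sacral body depth below the endplate, px.
#' @param noise_sd additive Gaussian noise SD (intensity in `[0, 1]`).
#' @param blur_sigma Gaussian blur SD in px (0 = crisp).
#' @param background intensity gradient `(top, bottom)`.
#' @param body_intensity mean plateau intensity of bone.
#' @param anterior_side which image side the patient faces.
#' @param seed integer; makes [render_phantom()] deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(LL = 49.77, SHA = 38.09, ISA_L4L5 = 14.86,
                         ISA_L5S1 = 19.15, PLS_L4L5 = 12.27,
                         PLS_L5S1 = 13.36, size = c(256, 128),
                         pixel_spacing = c(1, 1),
                         body_width = c(26, 30), body_height = c(16, 20),
                         disc_height = c(5, 7), sacrum_width = 30,
                         sacrum_depth = 40, noise_sd = 0.04, blur_sigma = 1,
                         background = c(0.15, 0.35), body_intensity = 0.75,
                         anterior_side = c("left", "right"), seed = 1L) {
  anterior_side <- match.arg(anterior_side)
  spec <- list(
    targets = parameter_set(LL, SHA, ISA_L4L5, ISA_L5S1, PLS_L4L5, PLS_L5S1),
    size = as.integer(size), pixel_spacing = as.numeric(pixel_spacing),
    body_width = body_width, body_height = body_height,
    disc_height = disc_height, sacrum_width = sacrum_width,
    sacrum_depth = sacrum_depth, noise_sd = noise_sd,
    blur_sigma = blur_sigma, background = background,
    body_intensity = body_intensity, anterior_side = anterior_side,
    seed = as.integer(seed)
  )
  t <- spec$targets
  if (t[["LL"]] < 0 || t[["LL"]] > 90 || t[["SHA"]] < 0 || t[["SHA"]] > 90 ||
      any(abs(t[c("ISA_L4L5", "ISA_L5S1")]) > 90) ||
      any(abs(t[c("PLS_L4L5", "PLS_L5S1")]) > 100)) {
    abort_lm("lumbometry_infeasible_spec", "targets outside valid ranges")
  }
  structure(spec, class = "phantom_spec")
}

#' Draw one phantom specification from a population
#'
#' Rejection-samples truncated-normal targets until the lordotic curve is
#' feasible: the residual wedge per untargeted segment must stay in
#' `[-3, 8]` degrees so vertebral bodies remain near-rectangular.
#'
#' @param population a [phantom_population()].
#' @param seed integer seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
sample_spec <- function(population = phantom_population(), seed = 1L, ...) {
  with_seed(seed, {
    for (attempt in 1:100) {
      tg <- vapply(PARAMETER_NAMES, function(p) {
        m <- population$means[[p]]; s <- population$sds[[p]]
        lo <- population$ranges["low", p]; hi <- population$ranges["high", p]
        if (s == 0) return(min(max(m, lo), hi))
        for (k in 1:1000) {
          v <- rnorm(1, m, s)
          if (v >= lo && v <= hi) return(v)
        }
        m
      }, numeric(1))
      resid <- (tg[["LL"]] - tg[["ISA_L4L5"]] - tg[["ISA_L5S1"]]) / 8
      if (resid >= -3 && resid <= 8) {
        spec <- phantom_spec(LL = tg[["LL"]], SHA = tg[["SHA"]],
                             ISA_L4L5 = tg[["ISA_L4L5"]],
                             ISA_L5S1 = tg[["ISA_L5S1"]],
                             PLS_L4L5 = tg[["PLS_L4L5"]],
                             PLS_L5S1 = tg[["PLS_L5S1"]],
                             seed = sample.int(2147483646L, 1), ...)
        fits <- tryCatch({
          phantom_geometry(spec)
          TRUE
        }, lumbometry_infeasible_spec = function(e) FALSE)
        if (fits) return(spec)
      }
    }
    abort_lm("lumbometry_infeasible_spec",
             "no feasible target set in 100 attempts")
  })
}

# anterior-pointing unit vector of an endplate with elevation phi (degrees);
# elevation is positive when the endplate ascends toward the anterior side
dir_anterior <- function(phi, side) {
  r <- deg2rad(phi)
  if (side == "left") c(-cos(r), -sin(r)) else c(cos(r), -sin(r))
}
# unit normal pointing superiorly (toward decreasing y for small phi)
dir_up <- function(phi, side) {
  r <- deg2rad(phi)
  if (side == "left") c(sin(r), -cos(r)) else c(-sin(r), -cos(r))
}

# Solve body corner positions; returns list(corners = named list of 4x2
# matrices in draw order, keypoints = named x,y matrix)
solve_spine_geometry <- function(spec, dims) {
  t <- spec$targets; side <- spec$anterior_side
  resid <- (t[["LL"]] - t[["ISA_L4L5"]] - t[["ISA_L5S1"]]) / 8
  disc_wedge <- c(L5 = t[["ISA_L5S1"]], L4 = t[["ISA_L4L5"]],
                  L3 = resid, L2 = resid, L1 = resid)
  phi_s1 <- -t[["SHA"]]

  pts <- list()
  # sacrum
  s1sp <- c(0, 0)
  s1sa <- s1sp + spec$sacrum_width * dir_anterior(phi_s1, side)
  dn <- -dir_up(phi_s1, side)
  da <- dir_anterior(phi_s1, side)
  s1ip <- s1sp + spec$sacrum_depth * dn - 8 * da
  s1ia <- s1sa + 0.75 * spec$sacrum_depth * dn - 16 * da
  pts$S1 <- rbind(SA = s1sa, SP = s1sp, IP = s1ip, IA = s1ia)

  sp_low <- s1sp
  phi_sup_low <- phi_s1
  e_low <- NULL
  for (v in c("L5", "L4", "L3", "L2", "L1")) {
    phi_inf <- phi_sup_low + disc_wedge[[v]]
    e_own <- dir_up(phi_inf, side)
    # the L4 posterior border is measured as the line through L4IP parallel
    # to the L5 posterior border, so L4IP must sit on that line through L5SP
    e_place <- if (v == "L4") e_low else e_own
    ip <- sp_low + dims$disc[[v]] * e_place
    phi_sup <- phi_inf + resid
    sp <- ip + dims$height[[v]] * e_own
    ia <- ip + dims$width_inf[[v]] * dir_anterior(phi_inf, side)
    sa <- sp + dims$width_sup[[v]] * dir_anterior(phi_sup, side)
    pts[[v]] <- rbind(SA = sa, SP = sp, IP = ip, IA = ia)
    sp_low <- sp
    phi_sup_low <- phi_sup
    e_low <- e_own
  }

  # impose slips: translate a vertebra and everything above it along the
  # superior endplate of the vertebra below (anterior positive)
  slip <- function(pts, above, shift) {
    for (v in above) pts[[v]] <- sweep(pts[[v]], 2, shift, "+")
    pts
  }
  s51 <- t[["PLS_L5S1"]] / 100 * spec$sacrum_width
  pts <- slip(pts, c("L5", "L4", "L3", "L2", "L1"),
              s51 * dir_anterior(phi_s1, side))
  m_l5 <- sqrt(sum((pts$L5["SA", ] - pts$L5["SP", ])^2))
  phi_l5sup <- phi_s1 + disc_wedge[["L5"]] + resid
  s45 <- t[["PLS_L4L5"]] / 100 * m_l5
  pts <- slip(pts, c("L4", "L3", "L2", "L1"),
              s45 * dir_anterior(phi_l5sup, side))
  pts
}

# deterministic per-spec body dimensions and solved, frame-centred corner
# positions; raises an infeasible-spec error when the spine cannot fit
phantom_geometry <- function(spec) {
  with_seed(spec$seed, {
    vnames <- c("L5", "L4", "L3", "L2", "L1")
    dims <- list(
      width_sup = stats::setNames(runif(5, spec$body_width[1],
                                        spec$body_width[2]), vnames),
      height = stats::setNames(runif(5, spec$body_height[1],
                                     spec$body_height[2]), vnames),
      disc = stats::setNames(runif(5, spec$disc_height[1],
                                   spec$disc_height[2]), vnames)
    )
    dims$width_inf <- dims$width_sup * runif(5, 0.96, 1.04)
    pts <- solve_spine_geometry(spec, dims)

    all_xy <- do.call(rbind, pts)
    rows <- spec$size[1]; cols <- spec$size[2]; margin <- 6
    span <- apply(all_xy, 2, range)
    if (diff(span[, 1]) > cols - 2 * margin ||
        diff(span[, 2]) > rows - 2 * margin) {
      abort_lm("lumbometry_infeasible_spec",
               "spine (%.0f x %.0f px) does not fit the %d x %d frame",
               diff(span[, 1]), diff(span[, 2]), rows, cols)
    }
    shift <- c((cols - 1) / 2 - mean(span[, 1]),
               (rows - 1) / 2 - mean(span[, 2]))
    lapply(pts, function(m) sweep(m, 2, shift, "+"))
  })
}

#' Render one phantom sample
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_sample`: `image` (rows x cols matrix in
#'   `[0, 1]`), `mask` (integer matrix, 0 background / 1 lumbar / 2 sacrum),
#'   `keypoints` (a [keypoint_set()] with all 24 body corners), `truth`
#'   (the target `parameter_set`), and `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- phantom_geometry(spec)
  with_seed(spec$seed + 1L, {
    rows <- spec$size[1]; cols <- spec$size[2]
    vnames <- c("L5", "L4", "L3", "L2", "L1")
    mask <- matrix(0L, rows, cols)
    img <- matrix(spec$background[1], rows, cols) +
      (spec$background[2] - spec$background[1]) *
        matrix((seq_len(rows) - 1) / (rows - 1), rows, cols)
    for (v in c("S1", vnames)) {
      inside <- fill_convex_quad(pts[[v]], rows, cols)
      if (any(mask[inside] != 0L)) {
        abort_lm("lumbometry_infeasible_spec",
                 "vertebral bodies overlap (%s)", v)
      }
      mask[inside] <- if (v == "S1") 2L else 1L
      img[inside] <- spec$body_intensity + runif(1, -0.05, 0.05)
    }
    if (spec$blur_sigma > 0) {
      img <- cpp_sep_filter(img, gaussian_kernel(spec$blur_sigma))
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(rows * cols, 0, spec$noise_sd), rows, cols)
    }
    img <- pmin(pmax(img, 0), 1)

    kp <- do.call(rbind, lapply(names(pts), function(v) {
      m <- pts[[v]]
      rownames(m) <- paste0(v, rownames(m))
      m
    }))
    kps <- keypoint_set(kp, anterior_side = spec$anterior_side,
                        pixel_spacing = spec$pixel_spacing)
    structure(list(image = img, mask = mask, keypoints = kps,
                   truth = spec$targets, spec = spec),
              class = "phantom_sample")
  })
}

# pixels (centres at x = col-1, y = row-1) inside a convex quadrilateral
fill_convex_quad <- function(quad, rows, cols) {
  ctr <- colMeans(quad)
  ord <- order(atan2(quad[, 2] - ctr[2], quad[, 1] - ctr[1]))
  q <- quad[ord, , drop = FALSE]
  X <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  Y <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  inside <- matrix(TRUE, rows, cols)
  for (k in 1:4) {
    p1 <- q[k, ]; p2 <- q[if (k == 4) 1 else k + 1, ]
    cr <- (X - p1[1]) * (p2[2] - p1[2]) - (Y - p1[2]) * (p2[1] - p1[1])
    inside <- inside & (cr <= 1e-9)
  }
  inside
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Generate a phantom dataset with a train/validation/test split
#'
#' Samples `n` phantoms with per-sample seeds derived from `seed` and splits
#' them 8:1:1 (validation and test sizes are `round(n / 10)` each, matching
#' 992/124/124 at n = 1240).
#'
#' @param n number of samples.
#' @param population a [phantom_population()].
#' @param seed master seed.
#' @param dir optional output directory; when given, images and masks are
#'   written as PGM, keypoints as LabelMe-style JSON, plus `manifest.csv`.
#' @param ... passed to [sample_spec()] (e.g. `size`, `noise_sd`).
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data frame: id, seed, split, six target columns).
#' @export
generate_dataset <- function(n, population = phantom_population(),
                             seed = 1L, dir = NULL, ...) {
  stopifnot(n >= 1)
  samples <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    specs[[i]] <- sample_spec(population, seed = derive_seed(seed, i), ...)
    samples[[i]] <- render_phantom(specs[[i]])
  }
  sc <- split_counts(n)
  n_test <- sc[["test"]]
  n_val <- sc[["val"]]
  split <- rep("train", n)
  perm <- with_seed(derive_seed(seed, 0), sample.int(n))
  if (n_val > 0) split[perm[seq_len(n_val)]] <- "val"
  if (n_test > 0) split[perm[n_val + seq_len(n_test)]] <- "test"
  manifest <- data.frame(
    id = sprintf("phantom_%04d", seq_len(n)),
    seed = vapply(specs, function(s) as.double(s$seed), numeric(1)),
    split = split,
    do.call(rbind, lapply(samples, function(s) {
      as.data.frame(as.list(unclass(s$truth)))
    }))
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      id <- manifest$id[i]
      write_pgm(samples[[i]]$image, file.path(dir, paste0(id, ".pgm")),
                maxval = 65535L)
      write_mask_pgm(samples[[i]]$mask, file.path(dir, paste0(id, "_mask.pgm")))
      write_labelme(samples[[i]]$keypoints,
                    file.path(dir, paste0(id, ".json")),
                    image_path = paste0(id, ".pgm"),
                    image_size = dim(samples[[i]]$image))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Train/validation/test sizes of the 8:1:1 split
#'
#' Validation and test sets each get `round(n / 10)` samples; at the
#' published cohort size of 1240 this yields 992 / 124 / 124.
#' @param n dataset size.
#' @return named integer vector (train, val, test).
#' @export
split_counts <- function(n) {
  n_val <- round(n / 10)
  n_test <- round(n / 10)
  c(train = as.integer(n - n_val - n_test), val = as.integer(n_val),
    test = as.integer(n_test))
}

#' Keypoints and ground truth of a phantom without rendering
#'
#' Solves the spine geometry only (no rasterisation, blur or noise); useful
#' for large measurement-closure sweeps.
#'
#' @param spec a [phantom_spec()].
#' @return list with `keypoints` (a [keypoint_set()]) and `truth`.
#' @export
phantom_keypoints <- function(spec) {
  pts <- phantom_geometry(spec)
  kp <- do.call(rbind, lapply(names(pts), function(v) {
    m <- pts[[v]]
    rownames(m) <- paste0(v, rownames(m))
    m
  }))
  list(keypoints = keypoint_set(kp, anterior_side = spec$anterior_side,
                                pixel_spacing = spec$pixel_spacing),
       truth = spec$targets)
}
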