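# From a segmentation mask to named landmarks.
#
# Pipeline: 8-connected components per class (small specks removed), the
# five lumbar regions named L1..L5 by centroid row, Harris corner response
# on each region's binary support (after a light morphological opening),
# non-maximum suppression, anatomical assignment of the surviving corner
# candidates, and finally the 10-point measurement vocabulary.

#' Default corner-detection parameters
#'
#' @param k Harris sensitivity constant.
#' @param sigma structure-tensor smoothing SD, px.
#' @param pre_sigma support pre-smoothing SD before differentiation;
#'   suppresses the staircase response of rasterised oblique edges.
#' @param nms_radius non-maximum suppression radius, px (shrunk
#'   automatically for regions smaller than about 4 radii).
#' @param response_frac response threshold as a fraction of the maximum.
#' @param response_min absolute response floor; a discretised smooth
#'   boundary (e.g. a disk) still has a weakly positive Harris response,
#'   so a relative threshold alone would always "find" corners.  With
#'   `sigma = 2`, `pre_sigma = 1.5`: right-angle corners respond at about
#'   1.5e-4, corners up to ~120 deg above 5e-5, disks below 1.5e-5.
#' @param min_area minimum connected-component area, px^2.
#' @param max_candidates corner candidates kept per region (by response).
#' @param refine snap each accepted corner to the extreme boundary pixel of
#'   the (unsmoothed) support within `nms_radius`, removing the inward bias
#'   of the smoothed response peak.
#' @return list of parameters.
#' @export
keypoint_config <- function(k = 0.05, sigma = 2, pre_sigma = 1.5,
                            nms_radius = 5,
                            response_frac = 0.01, response_min = 4e-5,
                            min_area = 20, max_candidates = 12,
                            refine = TRUE) {
  list(k = k, sigma = sigma, pre_sigma = pre_sigma,
       nms_radius = nms_radius,
       response_frac = response_frac, response_min = response_min,
       min_area = min_area, max_candidates = max_candidates,
       refine = refine)
}

#' Extract vertebral regions from a label mask
#'
#' @param mask integer matrix (0 background, 1 lumbar, 2 sacrum).
#' @param config a [keypoint_config()].
#' @return list of regions (`support` logical matrix, `class`, `centroid`,
#'   `area`); lumbar regions sorted superior to inferior, sacrum last.
#'   Raises an anatomy-count error unless exactly 5 lumbar regions and a
#'   sacrum survive the area filter.
#' @export
extract_regions <- function(mask, config = keypoint_config()) {
  regions <- list()
  for (cls in c(1L, 2L)) {
    lab <- cpp_label_components(mask, cls)
    ids <- setdiff(unique(as.vector(lab)), 0L)
    for (id in ids) {
      sup <- lab == id
      area <- sum(sup)
      if (area < config$min_area) next
      idx <- which(sup, arr.ind = TRUE)
      regions[[length(regions) + 1]] <- list(
        support = sup,
        class = if (cls == 1L) "lumbar" else "sacrum",
        centroid = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
        area = area
      )
    }
  }
  classes <- vapply(regions, `[[`, character(1), "class")
  n_lum <- sum(classes == "lumbar")
  n_sac <- sum(classes == "sacrum")
  if (n_sac < 1) abort_anatomy("no sacrum region found")
  if (n_sac > 1) abort_anatomy("%d sacrum regions found", n_sac)
  if (n_lum != 5) {
    abort_anatomy("expected 5 lumbar regions, found %d", n_lum)
  }
  lum <- regions[classes == "lumbar"]
  lum <- lum[order(vapply(lum, function(r) r$centroid[["y"]], numeric(1)))]
  c(lum, regions[classes == "sacrum"])
}

#' Assign anatomical identities L1..L5 and S1 to regions
#'
#' Lumbar regions are named in order of increasing centroid row (superior
#' to inferior); the sacrum is S1.  Order of the input list is irrelevant.
#' @param regions output of [extract_regions()] (5 lumbar + 1 sacrum).
#' @return the regions with an `identity` field, ordered L1..L5, S1.
#' @export
label_vertebrae <- function(regions) {
  classes <- vapply(regions, `[[`, character(1), "class")
  if (sum(classes == "lumbar") != 5 || sum(classes == "sacrum") != 1) {
    abort_anatomy("need exactly 5 lumbar + 1 sacrum regions")
  }
  lum <- regions[classes == "lumbar"]
  ord <- order(vapply(lum, function(r) r$centroid[["y"]], numeric(1)))
  lum <- lum[ord]
  for (i in 1:5) lum[[i]]$identity <- paste0("L", i)
  sac <- regions[classes == "sacrum"][[1]]
  sac$identity <- "S1"
  c(lum, list(sac))
}

#' Harris corner response of a (binary) support patch
#'
#' Central-difference gradients, Gaussian-smoothed structure tensor
#' ("covariance matrix" of the local gradient), and the response
#' `R = det(M) - k * trace(M)^2`.
#'
#' @param patch numeric or logical matrix.
#' @param sigma structure-tensor smoothing SD in px.
#' @param k sensitivity constant.
#' @param pre_sigma pre-smoothing SD applied to the patch before
#'   differentiation (0 = none).
#' @return response matrix of the same size.
#' @export
harris_response <- function(patch, sigma = 2, k = 0.05, pre_sigma = 0) {
  m <- patch * 1.0
  if (pre_sigma > 0) {
    m <- cpp_sep_filter(m, gaussian_kernel(pre_sigma))
  }
  H <- nrow(m); W <- ncol(m)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  kern <- gaussian_kernel(sigma)
  sxx <- cpp_sep_filter(gx * gx, kern)
  syy <- cpp_sep_filter(gy * gy, kern)
  sxy <- cpp_sep_filter(gx * gy, kern)
  (sxx * syy - sxy^2) - k * (sxx + syy)^2
}

# 3x3 binary erosion / dilation (8-neighbourhood)
erode3 <- function(b) {
  H <- nrow(b); W <- ncol(b)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- b
  out <- matrix(TRUE, H, W)
  for (di in 0:2) for (dj in 0:2) {
    out <- out & p[di + 1:H, dj + 1:W]
  }
  out
}
dilate3 <- function(b) {
  H <- nrow(b); W <- ncol(b)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- b
  out <- matrix(FALSE, H, W)
  for (di in 0:2) for (dj in 0:2) {
    out <- out | p[di + 1:H, dj + 1:W]
  }
  out
}

#' Detect corner candidates on one vertebral region
#'
#' Thresholded Harris maxima after greedy non-maximum suppression, sorted
#' by descending response.
#'
#' @param region a region from [extract_regions()].
#' @param config a [keypoint_config()].
#' @param min_candidates raise a corner-shortage error below this count.
#' @return data frame with `x`, `y`, `response`.
#' @export
detect_corners <- function(region, config = keypoint_config(),
                           min_candidates = 4L) {
  sup <- dilate3(erode3(region$support))  # opening: despeckle the boundary
  resp <- harris_response(sup, config$sigma, config$k, config$pre_sigma)
  thr <- max(config$response_frac * max(resp), config$response_min)
  # candidates must sit in a narrow band around the region boundary:
  # smoothing tails otherwise create weak maxima just outside the corners
  band <- dilate3(sup) & !erode3(erode3(sup))
  resp[!band] <- -Inf
  cand <- which(resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    abort_lm("lumbometry_corner_shortage",
             "no corner candidates on %s region",
             region$identity %||% region$class)
  }
  rv <- resp[cand]
  ord <- order(rv, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  rv <- rv[ord]
  keep <- integer(0)
  bb <- range(which(rowSums(sup) > 0))
  bb2 <- range(which(colSums(sup) > 0))
  short_side <- min(diff(bb), diff(bb2)) + 1
  radius <- max(3, min(config$nms_radius, floor(short_side / 4)))
  r2 <- radius^2
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0) {
      keep <- i
    } else {
      d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
      if (all(d2 > r2)) keep <- c(keep, i)
    }
    if (length(keep) >= config$max_candidates) break
  }
  out <- data.frame(x = cand[keep, 2] - 1, y = cand[keep, 1] - 1,
                    response = rv[keep])
  if (isTRUE(config$refine) && nrow(out) > 0) {
    out <- refine_corners(out, region$support, config$nms_radius)
  }
  if (nrow(out) < min_candidates) {
    abort_lm("lumbometry_corner_shortage",
             "%s region: %d corner candidates, need %d",
             region$identity %||% region$class, nrow(out), min_candidates)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coarse snap of each candidate to the support boundary pixel (within
# `radius`) farthest from the region centroid: the smoothed Harris peak
# sits 1-2 px inside a binary corner, the true vertex is locally extreme.
# Sub-pixel accuracy comes later from edge-fit refinement on the assigned
# quadrilateral.
refine_corners <- function(cand, support, radius) {
  bnd <- which(support & !erode3(support), arr.ind = TRUE)
  bx <- bnd[, 2] - 1; by <- bnd[, 1] - 1
  ctr <- c(mean(bx), mean(by))
  r2 <- radius^2
  for (i in seq_len(nrow(cand))) {
    near <- (bx - cand$x[i])^2 + (by - cand$y[i])^2 <= r2
    if (!any(near)) next
    d2 <- (bx[near] - ctr[1])^2 + (by[near] - ctr[2])^2
    j <- which.max(d2)
    cand$x[i] <- bx[near][j]
    cand$y[i] <- by[near][j]
  }
  # refinement can merge neighbouring maxima; keep the strongest of each
  cand[!duplicated(cand[, c("x", "y")]), , drop = FALSE]
}

# boundary pixel coordinates (x, y) of a support
boundary_xy <- function(support) {
  bnd <- which(support & !erode3(support), arr.ind = TRUE)
  cbind(x = bnd[, 2] - 1, y = bnd[, 1] - 1)
}

# "crack" points of a support: midpoints between each region pixel centre
# and each 4-neighbouring background pixel centre.  These straddle the
# continuous region outline symmetrically, so line fits through them are
# unbiased -- boundary pixel centres, by contrast, all lie inside the
# region and would drag a fitted edge about a third of a pixel inward.
crack_xy <- function(support) {
  H <- nrow(support); W <- ncol(support)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- support
  pts <- NULL
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (sh in shifts) {
    nb <- pad[2:(H + 1) + sh[1], 2:(W + 1) + sh[2]]
    edge <- which(support & !nb, arr.ind = TRUE)
    if (nrow(edge) == 0) next
    pts <- rbind(pts, cbind(x = edge[, 2] - 1 + sh[2] / 2,
                            y = edge[, 1] - 1 + sh[1] / 2))
  }
  pts
}

# Total-least-squares line through crack points lying along the segment
# p -> q (excluding `trim` px at both ends).  Two passes: a wide band
# first (coarse corners can sit ~2 px off the true edge), then a tight
# refit around the first fit.  NULL when too few points or when the fit
# disagrees with the coarse edge direction.
fit_edge_line <- function(bxy, p, q, trim = 3, tol = 2.2, tol2 = 0.8) {
  d <- q - p
  L <- sqrt(sum(d^2))
  trim <- min(trim, L / 4)  # short edges keep enough pixels to fit
  if (L < 2 * trim + 2) return(NULL)
  u <- d / L
  tls <- function(anchor, dir0, tolk) {
    n <- c(-dir0[2], dir0[1])
    rel <- sweep(bxy, 2, anchor)
    t <- rel %*% dir0
    sdist <- rel %*% n
    sel <- abs(sdist) < tolk & t > trim & t < L - trim
    if (sum(sel) < 4) return(NULL)
    pts <- bxy[sel, , drop = FALSE]
    ev <- eigen(stats::cov(pts), symmetric = TRUE)
    list(anchor = colMeans(pts), direction = ev$vectors[, 1])
  }
  f1 <- tls(p, u, tol)
  if (is.null(f1)) return(NULL)
  # re-anchor the band on the first fit, projected back to p's end
  dir1 <- f1$direction
  if (sum(dir1 * u) < 0) dir1 <- -dir1
  p1 <- f1$anchor - as.numeric((f1$anchor - p) %*% dir1) * dir1
  f2 <- tls(p1, dir1, tol2)
  if (is.null(f2)) f2 <- f1
  if (abs(sum(f2$direction * u)) < cos(20 * pi / 180)) return(NULL)
  f2
}

# refine an ordered convex quadrilateral: fit its four edges on the support
# boundary and intersect adjacent fits; corners that cannot be refined (or
# that would move implausibly far) keep their coarse position
refine_quad_edges <- function(quad, support, max_move = 3) {
  bxy <- crack_xy(support)
  lines <- vector("list", 4)
  for (k in 1:4) {
    lines[k] <- list(fit_edge_line(bxy, quad[k, ],
                                   quad[if (k == 4) 1 else k + 1, ]))
  }
  # a rejected short-edge fit can borrow the opposite edge's direction
  # (bodies are near-parallelograms), anchored on the local crack points
  for (k in 1:4) {
    if (!is.null(lines[[k]])) next
    opp <- lines[[if (k <= 2) k + 2 else k - 2]]
    if (is.null(opp)) next
    p <- quad[k, ]; q <- quad[if (k == 4) 1 else k + 1, ]
    d <- q - p
    L <- sqrt(sum(d^2))
    if (L < 2) next
    u <- d / L
    n <- c(-u[2], u[1])
    rel <- sweep(bxy, 2, p)
    sel <- abs(rel %*% n) < 1.2 & rel %*% u > 1 & rel %*% u < L - 1
    if (sum(sel) < 3) next
    lines[k] <- list(list(anchor = colMeans(bxy[sel, , drop = FALSE]),
                          direction = opp$direction))
  }
  out <- quad
  for (k in 1:4) {
    prev <- lines[[if (k == 1) 4 else k - 1]]
    cur <- lines[[k]]
    if (is.null(prev) || is.null(cur)) next
    den <- prev$direction[1] * cur$direction[2] -
      prev$direction[2] * cur$direction[1]
    if (abs(den) < 1e-6) next
    rhs <- cur$anchor - prev$anchor
    tt <- (rhs[1] * cur$direction[2] - rhs[2] * cur$direction[1]) / den
    pt <- prev$anchor + tt * prev$direction
    if (sqrt(sum((pt - quad[k, ])^2)) <= max_move) out[k, ] <- pt
  }
  out
}

# refine the sacral superior endplate pair: fit the endplate line and move
# each corner to the extreme of the boundary pixels along that line
refine_endplate_pair <- function(pair, support, max_move = 3) {
  bxy <- crack_xy(support)
  ln <- fit_edge_line(bxy, pair[1, ], pair[2, ])
  if (is.null(ln)) return(pair)
  u <- ln$direction
  n <- c(-u[2], u[1])
  rel <- sweep(bxy, 2, ln$anchor)
  t <- rel %*% u
  sdist <- rel %*% n
  sel <- abs(sdist) < 1.2
  if (sum(sel) < 4) return(pair)
  lo <- ln$anchor + min(t[sel]) * u
  hi <- ln$anchor + max(t[sel]) * u
  out <- pair
  for (i in 1:2) {
    cands <- rbind(lo, hi)
    j <- which.min((cands[, 1] - pair[i, 1])^2 +
                   (cands[, 2] - pair[i, 2])^2)
    if (sqrt(sum((cands[j, ] - pair[i, ])^2)) <= max_move) {
      out[i, ] <- cands[j, ]
    }
  }
  out
}

quad_area <- function(p) {
  ctr <- colMeans(p)
  ord <- order(atan2(p[, 2] - ctr[2], p[, 1] - ctr[1]))
  q <- p[ord, , drop = FALSE]
  abs(sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2])) / 2
}

#' Name corner candidates anatomically
#'
#' Lumbar regions: the 4 candidates maximising the enclosed quadrilateral
#' area are split into a superior and an inferior pair by row, and within
#' each pair the anterior point is the one toward `anterior_side`.  Sacrum:
#' the 2 candidates with the smallest rows become S1SA/S1SP.
#'
#' @param candidates data frame from [detect_corners()].
#' @param region labelled region (field `identity`).
#' @param anterior_side `"left"` or `"right"`.
#' @param toward optional reference point (the L5 centroid): for the sacrum
#'   the superior endplate is the candidate hull edge facing it.
#' @return named list of `(x, y)` landmarks, e.g. `L4SA`.
#' @export
assign_anatomical_labels <- function(candidates, region, anterior_side,
                                     toward = NULL) {
  id <- region$identity
  if (is.null(id)) abort_anatomy("region has no anatomical identity")
  pm <- as.matrix(candidates[, c("x", "y")])
  if (id == "S1") {
    if (nrow(pm) < 2) {
      abort_lm("lumbometry_corner_shortage", "S1: need 2 corner candidates")
    }
    top <- superior_pair(pm, toward)
    top <- refine_endplate_pair(top, region$support)
    ant <- if (anterior_side == "left") which.min(top[, 1]) else
      which.max(top[, 1])
    out <- list(top[ant, ], top[3 - ant, ])
    names(out) <- paste0("S1", c("SA", "SP"))
    return(out)
  }
  if (nrow(pm) < 4) {
    abort_lm("lumbometry_corner_shortage", "%s: need 4 corner candidates", id)
  }
  combs <- utils::combn(seq_len(nrow(pm)), 4)
  areas <- apply(combs, 2, function(ix) quad_area(pm[ix, , drop = FALSE]))
  best <- pm[combs[, which.max(areas)], , drop = FALSE]
  # order the quad, take the longer pair of opposite edges as the two
  # endplates (vertebral bodies are wider than tall), then the edge whose
  # midpoint is superior; a plain row split fails for tilts near 45 deg
  ctr <- colMeans(best)
  best <- best[order(atan2(best[, 2] - ctr[2], best[, 1] - ctr[1])), ,
               drop = FALSE]
  best <- refine_quad_edges(best, region$support)
  edge_len <- function(a, b) sqrt(sum((best[a, ] - best[b, ])^2))
  pair1 <- edge_len(1, 2) + edge_len(3, 4)  # opposite edges 1-2 / 3-4
  pair2 <- edge_len(2, 3) + edge_len(4, 1)
  edges <- if (pair1 >= pair2) list(c(1, 2), c(3, 4)) else
    list(c(2, 3), c(4, 1))
  mid_y <- vapply(edges, function(e) mean(best[e, 2]), numeric(1))
  if (abs(diff(mid_y)) < 1e-9) {
    abort_lm("lumbometry_labeling_error",
             "%s: superior/inferior endplates not separable by row", id)
  }
  sup <- best[edges[[which.min(mid_y)]], , drop = FALSE]
  inf <- best[edges[[which.max(mid_y)]], , drop = FALSE]
  pick <- function(pair) {
    ant <- if (anterior_side == "left") which.min(pair[, 1]) else
      which.max(pair[, 1])
    list(A = pair[ant, ], P = pair[3 - ant, ])
  }
  s <- pick(sup); i <- pick(inf)
  out <- list(s$A, s$P, i$A, i$P)
  names(out) <- paste0(id, c("SA", "SP", "IA", "IP"))
  out
}

# the superior endplate corner pair: the convex-hull edge of the corner
# candidates whose outward normal points most nearly toward `toward` (the
# L5 body centroid when available, otherwise straight up).  Robust when an
# obtuse inferior corner is missing, when duplicated maxima cluster around
# one corner, or when a steep sacral slope makes a lateral edge more
# horizontal than the endplate (a plain smallest-two-rows rule fails in
# all three situations).
superior_pair <- function(pm, toward = NULL) {
  hull <- grDevices::chull(pm[, 1], pm[, 2])
  hp <- pm[hull, , drop = FALSE]
  ctr <- colMeans(pm)
  nh <- nrow(hp)
  best <- NULL; best_up <- -Inf
  for (i in seq_len(nh)) {
    p <- hp[i, ]; q <- hp[if (i == nh) 1 else i + 1, ]
    d <- q - p
    len <- sqrt(sum(d^2))
    if (len < 3) next
    n <- c(-d[2], d[1]) / len
    if (sum(n * (ctr - (p + q) / 2)) > 0) n <- -n  # outward
    aim <- if (is.null(toward)) c(0, -1) else {
      v <- toward - ctr
      v / sqrt(sum(v^2))
    }
    up <- sum(n * aim)
    if (up > best_up) {
      best_up <- up
      best <- rbind(p, q)
    }
  }
  if (is.null(best)) best <- pm[order(pm[, 2])[1:2], , drop = FALSE]
  best
}

# infer the anterior side from the sacral slope: the superior sacral
# endplate descends toward the patient's anterior
infer_anterior_side <- function(sacrum_candidates, toward = NULL) {
  pm <- as.matrix(sacrum_candidates[, c("x", "y")])
  top <- superior_pair(pm, toward)
  lower <- top[which.max(top[, 2]), ]
  upper <- top[which.min(top[, 2]), ]
  if (lower[1] < upper[1]) "left" else "right"
}

#' Full mask-to-landmarks pipeline
#'
#' Region extraction, anatomical naming, Harris corner detection and
#' labelling, returning the 10-point measurement vocabulary.
#'
#' @param mask integer label matrix.
#' @param anterior_side `"left"`, `"right"`, or `NULL` to infer from the
#'   sacral slope.
#' @param pixel_spacing optional mm per pixel, stored on the result.
#' @param config a [keypoint_config()].
#' @return a [keypoint_set()] with the 10 vocabulary landmarks.
#' @export
mask_to_keypoints <- function(mask, anterior_side = NULL,
                              pixel_spacing = NULL,
                              config = keypoint_config()) {
  regions <- label_vertebrae(extract_regions(mask, config))
  names(regions) <- vapply(regions, `[[`, character(1), "identity")
  wanted <- list(L1 = c("SA", "SP"), L4 = c("IA", "IP"),
                 L5 = c("SA", "SP", "IA", "IP"), S1 = c("SA", "SP"))
  sac_cand <- detect_corners(regions$S1, config, min_candidates = 2L)
  l5c <- regions$L5$centroid
  if (is.null(anterior_side)) {
    anterior_side <- infer_anterior_side(sac_cand, toward = l5c)
  }
  pts <- list()
  for (v in names(wanted)) {
    cand <- if (v == "S1") sac_cand else detect_corners(regions[[v]], config)
    lab <- assign_anatomical_labels(cand, regions[[v]], anterior_side,
                                    toward = if (v == "S1") l5c)
    pts <- c(pts, lab[paste0(v, wanted[[v]])])
  }
  keypoint_set(pts, anterior_side = anterior_side,
               pixel_spacing = pixel_spacing)
}
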