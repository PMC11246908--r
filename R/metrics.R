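# Evaluation statistics: segmentation overlap, landmark PCK, rater
# reliability, and model-vs-reference agreement (ICC, Pearson r, MD, SD,
# MAE, RMSE, paired t, error quartiles).

#' Dice coefficient for one class
#' @param pred,ref integer label matrices of equal shape.
#' @param class label value compared.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks lack the class.
#' @export
dice_coefficient <- function(pred, ref, class = 1L) {
  if (!all(dim(pred) == dim(ref))) abort_data("mask shapes differ")
  a <- pred == class; b <- ref == class
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Pixel accuracy for one class (one-vs-rest)
#' @param pred,ref integer label matrices of equal shape.
#' @param class label value compared.
#' @return `(TP + TN) / total`.
#' @export
pixel_accuracy <- function(pred, ref, class = 1L) {
  if (!all(dim(pred) == dim(ref))) abort_data("mask shapes differ")
  mean((pred == class) == (ref == class))
}

kp_distances_mm <- function(pred, ref, names = NULL) {
  sp <- ref$pixel_spacing %||% pred$pixel_spacing
  if (is.null(sp)) abort_data("pixel spacing required for mm distances")
  if (is.null(names)) {
    names <- intersect(rownames(ref$points), rownames(pred$points))
  }
  dx <- (pred$points[names, 1] - ref$points[names, 1]) * sp[2]
  dy <- (pred$points[names, 2] - ref$points[names, 2]) * sp[1]
  stats::setNames(sqrt(dx^2 + dy^2), names)
}

#' Percentage of correct key points (PCK)
#'
#' @param pred,ref lists of [keypoint_set()] (or single sets); matched
#'   element-wise.
#' @param thresholds distance thresholds in mm.
#' @param landmarks landmark names evaluated (default: the vocabulary).
#' @return matrix (landmark x threshold) of percentages, with an `overall`
#'   row pooling all landmarks.
#' @export
pck <- function(pred, ref, thresholds = 1:5,
                landmarks = KEYPOINT_VOCABULARY) {
  if (inherits(pred, "keypoint_set")) pred <- list(pred)
  if (inherits(ref, "keypoint_set")) ref <- list(ref)
  if (length(pred) != length(ref)) abort_data("unmatched image lists")
  d <- do.call(rbind, Map(function(p, r) {
    kp_distances_mm(p, r, landmarks)
  }, pred, ref))
  out <- sapply(thresholds, function(t) colMeans(d <= t) * 100)
  out <- rbind(out, overall = sapply(thresholds, function(t) {
    mean(d <= t) * 100
  }))
  colnames(out) <- paste0("<=", thresholds)
  out
}

#' Inter- and intra-observer reliability table
#'
#' Pooled percentages of matched landmarks within each distance threshold,
#' for every pair of annotation sessions.
#'
#' @param sessions named list; each element is a list of [keypoint_set()]
#'   over the same images (one per rater, or repeat sessions of one rater).
#' @param thresholds distance thresholds in mm.
#' @return data frame: one row per session pair, one column per threshold.
#' @export
observer_reliability <- function(sessions, thresholds = 1:5) {
  if (length(sessions) < 2) abort_data("need at least two sessions")
  ns <- vapply(sessions, length, numeric(1))
  if (length(unique(ns)) != 1) abort_data("sessions cover different images")
  nm <- names(sessions) %||% paste0("S", seq_along(sessions))
  pairs <- utils::combn(length(sessions), 2)
  rows <- apply(pairs, 2, function(ix) {
    d <- unlist(Map(function(p, r) kp_distances_mm(p, r),
                    sessions[[ix[1]]], sessions[[ix[2]]]))
    vapply(thresholds, function(t) mean(d <= t) * 100, numeric(1))
  })
  out <- as.data.frame(t(rows))
  colnames(out) <- paste0("<=", thresholds)
  rownames(out) <- apply(pairs, 2, function(ix) {
    paste(nm[ix[1]], "vs", nm[ix[2]])
  })
  out
}

#' Reference standard: average of several raters
#'
#' Coordinate-wise mean of matched landmark sets, or element-wise mean of
#' measurement vectors.
#'
#' @param annotations list of [keypoint_set()] (matched names) or list of
#'   equal-length numeric vectors.
#' @return averaged `keypoint_set` or numeric vector.
#' @export
reference_standard <- function(annotations) {
  if (length(annotations) == 0) abort_data("no annotations")
  if (inherits(annotations[[1]], "keypoint_set")) {
    names0 <- rownames(annotations[[1]]$points)
    for (a in annotations) {
      if (!setequal(rownames(a$points), names0)) {
        abort_data("unmatched landmark names across raters")
      }
    }
    m <- Reduce(`+`, lapply(annotations, function(a) {
      a$points[names0, , drop = FALSE]
    })) / length(annotations)
    out <- annotations[[1]]
    out$points <- m
    out
  } else {
    Reduce(`+`, lapply(annotations, as.numeric)) / length(annotations)
  }
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure, from the
#' two-way ANOVA mean squares, with the F-based 95% confidence interval.
#'
#' @param reference,model numeric vectors (the two raters), or `model`
#'   omitted and `reference` an n x k matrix.
#' @param conf confidence level.
#' @return list: `icc`, `ci` (length 2), `n`, `k`.
#' @export
icc21 <- function(reference, model = NULL, conf = 0.95) {
  Y <- if (is.null(model)) as.matrix(reference) else
    cbind(as.numeric(reference), as.numeric(model))
  if (any(!is.finite(Y))) abort_data("non-finite measurement")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) abort_data("need at least 3 paired measurements")
  m <- mean(Y)
  ri <- rowMeans(Y); cj <- colMeans(Y)
  if (sum((Y - m)^2) < 1e-24) {
    abort_lm("lumbometry_undefined_icc", "zero total variance")
  }
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  mse <- sum((Y - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # Shrout & Fleiss F-based interval
  alpha <- 1 - conf
  fj <- msc / mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci = c(lower, upper), n = n, k = k, fj = fj)
}

#' Agreement report between model and reference measurements
#'
#' @param reference,model numeric vectors of paired measurements.
#' @param parameter label carried into the report.
#' @param conf confidence level for the ICC interval.
#' @return list of class `agreement_report`: `icc`, `icc_ci`, `r`, `md`
#'   (signed mean difference, model - reference), `sd` (SD of differences),
#'   `mae`, `rmse`, `t`, `p`, `quartiles` (min, Q1, median, Q3, max of the
#'   differences), `n`.
#' @export
agreement_report <- function(reference, model, parameter = "", conf = 0.95) {
  reference <- as.numeric(reference); model <- as.numeric(model)
  if (length(reference) != length(model)) abort_data("unequal lengths")
  n <- length(reference)
  if (n < 3) abort_data("need at least 3 paired measurements")
  d <- model - reference
  r <- if (stats::sd(reference) == 0 || stats::sd(model) == 0) {
    warning("Pearson r undefined for constant measurements")
    NA_real_
  } else {
    stats::cor(reference, model)
  }
  tt <- if (stats::sd(d) == 0) list(statistic = c(t = 0), p.value = 1) else
    stats::t.test(model, reference, paired = TRUE)
  ic <- tryCatch(icc21(reference, model, conf),
                 lumbometry_undefined_icc = function(e) {
                   list(icc = NA_real_, ci = c(NA_real_, NA_real_))
                 })
  structure(list(
    parameter = parameter,
    icc = ic$icc, icc_ci = ic$ci,
    r = r,
    md = mean(d), sd = stats::sd(d),
    mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
    t = unname(tt$statistic), p = tt$p.value,
    quartiles = stats::quantile(d, c(0, 0.25, 0.5, 0.75, 1), names = FALSE),
    n = n
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "%s: ICC %.3f (%.3f-%.3f), r %.3f, MD %.3f, SD %.3f, MAE %.3f, RMSE %.3f, t %.2f, p %.3g (n=%d)\n",
    if (nzchar(x$parameter)) x$parameter else "agreement",
    x$icc, x$icc_ci[1], x$icc_ci[2], x$r, x$md, x$sd, x$mae, x$rmse,
    x$t, x$p, x$n))
  invisible(x)
}

#' Agreement table over all six parameters
#'
#' @param reference,model data frames / matrices with the six parameter
#'   columns, rows matched.
#' @return data frame, one row per parameter, Table-style column order
#'   (ICC, CI, r, MD, SD, MAE, RMSE, t, p).
#' @export
agreement_table <- function(reference, model) {
  do.call(rbind, lapply(PARAMETER_NAMES, function(p) {
    rep <- agreement_report(reference[[p]], model[[p]], p)
    data.frame(parameter = p, icc = rep$icc, icc_lo = rep$icc_ci[1],
               icc_hi = rep$icc_ci[2], r = rep$r, md = rep$md, sd = rep$sd,
               mae = rep$mae, rmse = rep$rmse, t = rep$t, p_value = rep$p)
  }))
}
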