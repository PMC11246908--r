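# Sagittal measurement geometry.
#
# All coordinates are image pixel coordinates: x = column (rightward),
# y = row (downward), origin at the top-left pixel centre.  Angles between
# undirected lines are unsigned and acute; the intervertebral space angle and
# the spondylolisthesis percentage are signed, with "anterior" defined by the
# `anterior_side` of the landmark set (the direction the patient faces).

#' Landmark vocabulary of the measurement pipeline
#'
#' Ten named vertebral corner points: superior (S) / inferior (I) endplate,
#' anterior (A) / posterior (P) vertex, for the vertebrae that enter the four
#' lumbosacral parameters.
#' @format character vector of length 10.
#' @export
KEYPOINT_VOCABULARY <- c(
  "L1SA", "L1SP", "L4IA", "L4IP", "L5SA", "L5SP",
  "L5IA", "L5IP", "S1SA", "S1SP"
)

#' Construct a named landmark set
#'
#' @param points numeric matrix with columns `x`, `y` and landmark names as
#'   row names, or a named list of length-2 vectors.  Names outside
#'   [KEYPOINT_VOCABULARY] are allowed (e.g. all four corners of every
#'   vertebra) but only vocabulary names are used by the measurements.
#' @param anterior_side `"left"` or `"right"`: the image side corresponding
#'   to the patient's anterior direction.  Never guessed here; the mask
#'   pipeline can infer it from the sacral slope.
#' @param pixel_spacing optional mm-per-pixel, length 1 or 2 `(row, col)`.
#' @return object of class `keypoint_set`.
#' @export
keypoint_set <- function(points, anterior_side = c("left", "right"),
                         pixel_spacing = NULL) {
  anterior_side <- match.arg(anterior_side)
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  if (is.null(rownames(points))) abort_data("key points must be named")
  if (anyDuplicated(rownames(points))) {
    abort_data("duplicate key point name: %s",
               rownames(points)[duplicated(rownames(points))][1])
  }
  if (any(!is.finite(points))) abort_data("non-finite key point coordinate")
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2)
    if (any(pixel_spacing <= 0)) abort_data("pixel spacing must be positive")
  }
  structure(
    list(points = points, anterior_side = anterior_side,
         pixel_spacing = pixel_spacing),
    class = "keypoint_set"
  )
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %d points, anterior side %s%s>\n",
              nrow(x$points), x$anterior_side,
              if (is.null(x$pixel_spacing)) "" else
                sprintf(", %.3g mm/px", x$pixel_spacing[1])))
  print(round(x$points, 3))
  invisible(x)
}

kp_get <- function(kps, name) {
  i <- match(name, rownames(kps$points))
  if (is.na(i)) abort_missing_keypoint(name)
  kps$points[i, ]
}

# unit vector pointing toward the patient's anterior along the image x axis
anterior_unit <- function(anterior_side) {
  if (anterior_side == "left") c(-1, 0) else c(1, 0)
}

#' Line through two endplate vertices
#'
#' Direction is normalised to unit length and oriented so that its component
#' toward `anterior_side` is non-negative, so downstream signed quantities
#' share one orientation convention.
#'
#' @param a,p anterior and posterior vertex, numeric `(x, y)`.
#' @param anterior_side `"left"` or `"right"`.
#' @return list with `anchor` and unit `direction` (class `line2d`).
#' @export
endplate_line <- function(a, p, anterior_side = "left") {
  a <- as.numeric(a); p <- as.numeric(p)
  d <- a - p
  len <- sqrt(sum(d^2))
  if (len < 1e-12) abort_degenerate("coincident endplate vertices")
  d <- d / len
  s <- sum(d * anterior_unit(anterior_side))
  if (s < 0) d <- -d
  if (s == 0 && d[2] > 0) d <- -d  # vertical line: orient upward, fixed rule
  structure(list(anchor = p, direction = d), class = "line2d")
}

line2d <- function(anchor, direction) {
  len <- sqrt(sum(direction^2))
  if (len < 1e-12) abort_degenerate("zero-length line direction")
  structure(list(anchor = as.numeric(anchor),
                 direction = as.numeric(direction) / len),
            class = "line2d")
}

#' Unsigned acute angle between two undirected lines, in degrees
#' @param l1,l2 `line2d` objects.
#' @return angle in `[0, 90]`.
#' @export
angle_between_lines <- function(l1, l2) {
  d <- abs(sum(l1$direction * l2$direction))
  rad2deg(acos(min(1, d)))
}

# elevation of a line's anterior-pointing direction: positive when the
# endplate ascends toward anterior (image y grows downward)
elevation_deg <- function(l, anterior_side) {
  s <- if (anterior_side == "left") -1 else 1
  rad2deg(atan2(-l$direction[2], s * l$direction[1]))
}

superior_endplate <- function(kps, v) {
  endplate_line(kp_get(kps, paste0(v, "SA")), kp_get(kps, paste0(v, "SP")),
                kps$anterior_side)
}
inferior_endplate <- function(kps, v) {
  endplate_line(kp_get(kps, paste0(v, "IA")), kp_get(kps, paste0(v, "IP")),
                kps$anterior_side)
}

#' Lumbar lordosis (LL)
#'
#' Unsigned angle between the superior endplate of L1 and the superior
#' endplate of S1.
#' @param kps a [keypoint_set()] containing L1SA, L1SP, S1SA, S1SP.
#' @return degrees in `[0, 90]`.
#' @export
lumbar_lordosis <- function(kps) {
  angle_between_lines(superior_endplate(kps, "L1"),
                      superior_endplate(kps, "S1"))
}

#' Sacral horizontal angle (SHA)
#'
#' Unsigned angle between the S1 superior endplate and the image horizontal.
#' @param kps a [keypoint_set()] containing S1SA, S1SP.
#' @return degrees in `[0, 90]`.
#' @export
sacral_horizontal_angle <- function(kps) {
  horiz <- line2d(c(0, 0), c(1, 0))
  angle_between_lines(superior_endplate(kps, "S1"), horiz)
}

#' Intervertebral space angle (ISA)
#'
#' Signed wedge angle of the disc space: the angle between the inferior
#' endplate of the upper vertebra and the superior endplate of the lower
#' vertebra, positive when the disc opens anteriorly (lordotic wedge).
#'
#' @param kps a [keypoint_set()].
#' @param segment `"L4L5"` or `"L5S1"`.
#' @return degrees, `|ISA| <= 90`.
#' @export
intervertebral_space_angle <- function(kps, segment = c("L4L5", "L5S1")) {
  segment <- match.arg(segment)
  upper <- if (segment == "L4L5") "L4" else "L5"
  lower <- if (segment == "L4L5") "L5" else "S1"
  a <- elevation_deg(inferior_endplate(kps, upper), kps$anterior_side)
  b <- elevation_deg(superior_endplate(kps, lower), kps$anterior_side)
  d <- a - b
  d <- ((d + 180) %% 360) - 180
  if (d > 90) d <- d - 180 else if (d < -90) d <- d + 180
  d
}

#' Posterior border line of a vertebra
#'
#' The landmark vocabulary carries both posterior corners only for L5, so the
#' construction is per-vertebra: L5 uses the line through L5SP and L5IP; L4
#' (no L4SP annotated) uses the line through L4IP parallel to the L5
#' posterior border; S1 (no S1IP annotated) uses the line through S1SP
#' perpendicular to the S1 superior endplate.
#'
#' @param kps a [keypoint_set()].
#' @param vertebra `"L4"`, `"L5"` or `"S1"`.
#' @return a `line2d`.
#' @export
posterior_edge_line <- function(kps, vertebra = c("L4", "L5", "S1")) {
  vertebra <- match.arg(vertebra)
  switch(vertebra,
    L5 = {
      sp <- kp_get(kps, "L5SP"); ip <- kp_get(kps, "L5IP")
      if (sum((sp - ip)^2) < 1e-24) abort_degenerate("L5SP == L5IP")
      line2d(sp, sp - ip)
    },
    L4 = {
      l5 <- posterior_edge_line(kps, "L5")
      line2d(kp_get(kps, "L4IP"), l5$direction)
    },
    S1 = {
      ep <- superior_endplate(kps, "S1")
      line2d(kp_get(kps, "S1SP"), c(-ep$direction[2], ep$direction[1]))
    }
  )
}

line_intersection <- function(l1, l2) {
  # solve a1 + t d1 = a2 + u d2
  A <- cbind(l1$direction, -l2$direction)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-9) abort_degenerate("lines are parallel")
  rhs <- l2$anchor - l1$anchor
  t <- (rhs[1] * A[2, 2] - rhs[2] * A[1, 2]) / det
  l1$anchor + t * l1$direction
}

#' Percentage of lumbar spondylolisthesis (PLS)
#'
#' Taillard-style slip ratio.  N is the distance, measured along the lower
#' vertebra's superior endplate, between the intersections of that endplate
#' line with the posterior border lines of the upper and lower vertebrae;
#' M is the anteroposterior diameter of the same endplate (SA to SP).
#' Returns `N / M * 100`, signed: positive for anterolisthesis.
#'
#' @param kps a [keypoint_set()].
#' @param segment `"L4L5"` or `"L5S1"`.
#' @return percent.
#' @export
percent_spondylolisthesis <- function(kps, segment = c("L4L5", "L5S1")) {
  segment <- match.arg(segment)
  upper <- if (segment == "L4L5") "L4" else "L5"
  lower <- if (segment == "L4L5") "L5" else "S1"
  sa <- kp_get(kps, paste0(lower, "SA"))
  sp <- kp_get(kps, paste0(lower, "SP"))
  M <- sqrt(sum((sa - sp)^2))
  if (M < 1e-9) abort_degenerate("degenerate endplate: M ~ 0")
  ep <- endplate_line(sa, sp, kps$anterior_side)
  x_up <- line_intersection(posterior_edge_line(kps, upper), ep)
  x_low <- line_intersection(posterior_edge_line(kps, lower), ep)
  n_signed <- sum((x_up - x_low) * ep$direction)  # ep direction is anterior
  n_signed / M * 100
}

#' All six lumbosacral parameters from one landmark set
#'
#' @param kps a [keypoint_set()] with the full 10-point vocabulary.
#' @return a `parameter_set`: LL, SHA, ISA_L4L5, ISA_L5S1 (degrees),
#'   PLS_L4L5, PLS_L5S1 (percent).
#' @export
compute_all_parameters <- function(kps) {
  parameter_set(
    LL = lumbar_lordosis(kps),
    SHA = sacral_horizontal_angle(kps),
    ISA_L4L5 = intervertebral_space_angle(kps, "L4L5"),
    ISA_L5S1 = intervertebral_space_angle(kps, "L5S1"),
    PLS_L4L5 = percent_spondylolisthesis(kps, "L4L5"),
    PLS_L5S1 = percent_spondylolisthesis(kps, "L5S1")
  )
}

#' Container for the six measured parameters
#' @param LL,SHA,ISA_L4L5,ISA_L5S1 degrees.
#' @param PLS_L4L5,PLS_L5S1 percent.
#' @return named numeric vector of class `parameter_set`.
#' @export
parameter_set <- function(LL, SHA, ISA_L4L5, ISA_L5S1, PLS_L4L5, PLS_L5S1) {
  structure(c(LL = LL, SHA = SHA, ISA_L4L5 = ISA_L4L5, ISA_L5S1 = ISA_L5S1,
              PLS_L4L5 = PLS_L4L5, PLS_L5S1 = PLS_L5S1),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Lumbosacral parameters:\n")
  cat(sprintf("  LL  %7.2f deg   SHA %7.2f deg\n", x[["LL"]], x[["SHA"]]))
  cat(sprintf("  ISA L4-L5 %7.2f deg   ISA L5-S1 %7.2f deg\n",
              x[["ISA_L4L5"]], x[["ISA_L5S1"]]))
  cat(sprintf("  PLS L4-L5 %7.2f %%     PLS L5-S1 %7.2f %%\n",
              x[["PLS_L4L5"]], x[["PLS_L5S1"]]))
  invisible(x)
}

PARAMETER_NAMES <- c("LL", "SHA", "ISA_L4L5", "ISA_L5S1",
                     "PLS_L4L5", "PLS_L5S1")
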