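# Shared helpers: classed conditions and seeded evaluation.

abort_lm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lumbometry_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_missing_keypoint <- function(name) {
  abort_lm("lumbometry_missing_keypoint", "missing key point: %s", name)
}
abort_degenerate <- function(msg, ...) {
  abort_lm("lumbometry_degenerate_geometry", msg, ...)
}
abort_data <- function(msg, ...) abort_lm("lumbometry_data_error", msg, ...)
abort_anatomy <- function(msg, ...) {
  abort_lm("lumbometry_anatomy_count", msg, ...)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so library functions do not
#' perturb user-level reproducibility.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds below 2^31
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 9973) %% 2147483629 + 1
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
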