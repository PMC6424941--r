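#' Co-registered multi-contrast T1-weighted stack
#'
#' A `contrast_stack` holds `n` co-registered 3D magnitude volumes acquired at
#' different delays after a saturation pulse, together with their saturation
#' times and the physical voxel spacing. The unprepared (fully recovered)
#' image is encoded with a saturation time of `Inf`; it is never represented
#' by a fake large finite delay.
#'
#' @param data A 4D numeric array with dimensions `(x, y, z, n)`, or a list of
#'   `n` 3D arrays sharing one grid shape.
#' @param times_ms Numeric vector of length `n`: saturation times in
#'   milliseconds, with `Inf` marking the unprepared image. Finite times must
#'   be positive.
#' @param spacing_mm Numeric length-3 vector of per-axis voxel spacing in mm.
#'
#' @return An object of class `contrast_stack` with elements `data` (4D
#'   array), `times_ms`, `spacing_mm` and `n`.
#' @examples
#' arr <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
#' s <- contrast_stack(arr, times_ms = c(100, 600, Inf), spacing_mm = c(1.4, 1.4, 8))
#' s$n
#' @export
contrast_stack <- function(data, times_ms, spacing_mm = c(1, 1, 1)) {
  if (is.list(data)) {
    shapes <- lapply(data, dim)
    if (any(vapply(shapes, length, 1L) != 3L))
      stop("each volume in the list must be a 3D array")
    if (length(unique(lapply(shapes, as.integer))) != 1L)
      stop("all volumes must share one grid shape")
    data <- array(unlist(data, use.names = FALSE),
                  c(shapes[[1]], length(shapes)))
  }
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, n) or a list of 3D arrays")
  n <- dim(data)[4]
  if (n < 2L)
    stop("a contrast stack needs at least 2 contrasts (n >= 2)")
  if (length(times_ms) != n)
    stop(sprintf("length(times_ms) is %d but the stack has %d contrasts",
                 length(times_ms), n))
  finite <- is.finite(times_ms)
  if (any(times_ms[finite] <= 0))
    stop("finite saturation times must be > 0")
  if (sum(!finite) > 1L)
    stop("at most one unprepared (Inf) contrast time is allowed")
  if (any(!is.finite(data)))
    stop("stack intensities must be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(
    list(data = data, times_ms = as.numeric(times_ms),
         spacing_mm = as.numeric(spacing_mm), n = as.integer(n)),
    class = "contrast_stack")
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<contrast_stack> %d x %d x %d grid, n = %d contrasts\n",
              d[1], d[2], d[3], x$n))
  cat("  spacing (mm):", paste(signif(x$spacing_mm, 4), collapse = " x "), "\n")
  tms <- ifelse(is.finite(x$times_ms), sprintf("%g", x$times_ms), "inf")
  cat("  times (ms):  ", paste(tms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.contrast_stack <- function(x) dim(x$data)

# grid shape (first three dims)
grid_shape <- function(stack) dim(stack$data)[1:3]

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("stacks do not share one grid/contrast shape")
  invisible(TRUE)
}
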