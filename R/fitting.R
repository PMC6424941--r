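#' Options for the three-parameter saturation-recovery fit
#'
#' @param t1_bounds_ms Lower/upper bounds on T1 (ms). Fits landing on a bound
#'   are flagged invalid.
#' @param b_bounds Bounds on the saturation-efficiency parameter B.
#' @param multi_start_t1_ms Fixed T1 starting grid; a data-driven log-linear
#'   start is tried in addition. Best residual wins, ties broken by the
#'   smallest T1.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param min_b Fits with B below this are treated as unidentifiable
#'   (a flat recovery curve carries no T1 information).
#' @param min_rel_range Signals whose range is below this fraction of their
#'   peak magnitude are rejected as degenerate before fitting.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(t1_bounds_ms = c(1, 5000), b_bounds = c(0, 2),
                        multi_start_t1_ms = c(300, 1000, 2000),
                        max_iter = 100L, min_b = 0.01,
                        min_rel_range = 1e-6) {
  stopifnot(t1_bounds_ms[1] > 0, t1_bounds_ms[2] > t1_bounds_ms[1],
            b_bounds[1] >= 0, b_bounds[2] > b_bounds[1])
  structure(list(t1_bounds_ms = t1_bounds_ms, b_bounds = b_bounds,
                 multi_start_t1_ms = sort(multi_start_t1_ms),
                 max_iter = as.integer(max_iter), min_b = min_b,
                 min_rel_range = min_rel_range),
            class = "fit_options")
}

# model S(TS) = A (1 - B exp(-TS/T1)); TS = Inf (unprepared) gives exactly A
sr3_model <- function(par, times) {
  e <- exp(-times / par[3])
  e[!is.finite(times)] <- 0
  par[1] * (1 - par[2] * e)
}

#' Fit one voxel's saturation-recovery curve
#'
#' Three-parameter nonlinear least-squares fit of
#' \eqn{S(TS) = A (1 - B e^{-TS/T_1})} to the intensities of one voxel
#' across contrasts. B absorbs imperfect saturation efficiency; the
#' unprepared image enters as the \eqn{TS \to \infty} asymptote (model value
#' exactly A). The fit is deterministic: a fixed multi-start grid on T1 plus
#' a log-linear data-driven start, each refined by bounded
#' Levenberg-Marquardt, no randomness.
#'
#' @param signals Numeric vector of `n >= 4` intensities.
#' @param times_ms Matching saturation times (ms), `Inf` for the unprepared
#'   image.
#' @param options A [fit_options()].
#' @return A list `t1_ms`, `a`, `b`, `residual` (root-mean-square misfit)
#'   and `converged`. Degenerate input (non-finite, all-zero, or flat
#'   signals) yields `converged = FALSE` with `NaN` estimates rather than an
#'   error; fits at the T1 bounds or with B below `min_b` are likewise
#'   flagged invalid.
#' @examples
#' ts <- c(seq(100, 700, length.out = 8), Inf)
#' s <- 1000 * (1 - 0.95 * c(exp(-ts[1:8] / 1200), 0))
#' fit_voxel(s, ts)
#' @export
fit_voxel <- function(signals, times_ms, options = fit_options()) {
  bad <- list(t1_ms = NaN, a = NaN, b = NaN, residual = NaN, converged = FALSE)
  n <- length(signals)
  if (n != length(times_ms)) stop("signals and times_ms must have equal length")
  if (n < 4L) stop("at least 4 samples are needed for a three-parameter fit")
  if (any(!is.finite(signals)) || all(signals == 0)) return(bad)
  rng <- max(signals) - min(signals)
  if (rng <= options$min_rel_range * max(abs(signals))) return(bad)

  lower <- c(1e-9, options$b_bounds[1], options$t1_bounds_ms[1])
  upper <- c(Inf, options$b_bounds[2], options$t1_bounds_ms[2])

  unprep <- !is.finite(times_ms)
  a0 <- if (any(unprep)) mean(signals[unprep]) else 1.05 * max(signals)
  if (!is.finite(a0) || a0 <= 0) a0 <- max(abs(signals))

  # log-linear start from the two largest prepared times (plus the asymptote):
  # log(A - S) = log(A B) - TS/T1
  starts <- options$multi_start_t1_ms
  prep <- which(is.finite(times_ms))
  ord <- prep[order(times_ms[prep], decreasing = TRUE)]
  if (length(ord) >= 2L) {
    i1 <- ord[2L]; i2 <- ord[1L]   # t_a < t_b
    r1 <- a0 - signals[i1]; r2 <- a0 - signals[i2]
    if (r1 > 0 && r2 > 0 && r1 > r2) {
      t1_ll <- (times_ms[i2] - times_ms[i1]) / log(r1 / r2)
      if (is.finite(t1_ll) && t1_ll > lower[3] && t1_ll < upper[3])
        starts <- c(t1_ll, starts)
    }
  }

  resid_fn <- function(par) sr3_model(par, times_ms) - signals
  i_early <- prep[which.min(times_ms[prep])]
  t_early <- times_ms[i_early]

  best <- NULL
  for (t1_0 in starts) {
    b0 <- (1 - signals[i_early] / a0) * exp(t_early / t1_0)
    b0 <- min(max(b0, options$b_bounds[1]), options$b_bounds[2])
    if (!is.finite(b0)) b0 <- 1
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, b0, t1_0), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- fit$deviance
    if (is.null(best) || dev < best$deviance - 1e-12 ||
        (abs(dev - best$deviance) <= 1e-12 && fit$par[3] < best$par[3]))
      best <- fit
  }
  if (is.null(best)) return(bad)
  par <- best$par
  tol_b <- 1e-6 * diff(options$t1_bounds_ms)
  at_bound <- par[3] <= options$t1_bounds_ms[1] + tol_b ||
    par[3] >= options$t1_bounds_ms[2] - tol_b
  identifiable <- par[2] >= options$min_b
  list(t1_ms = par[3], a = par[1], b = par[2],
       residual = sqrt(best$deviance / n),
       converged = best$info %in% 1:4 && !at_bound && identifiable)
}

#' Voxel-wise T1 map from a contrast stack
#'
#' Applies [fit_voxel()] to every voxel of a (raw or denoised)
#' [contrast_stack()], optionally restricted to a mask. The result is
#' independent of any processing order.
#'
#' @param stack A [contrast_stack()] with at least 4 contrasts.
#' @param mask Optional 3D logical array selecting voxels to fit; all
#'   others are `NaN`/invalid.
#' @param options A [fit_options()].
#' @return A `t1_map_result`: list of 3D arrays `t1_ms`, `a`, `b`,
#'   `residual` (all `NaN` outside `valid`), the logical `valid` mask of
#'   converged in-bounds fits, plus `times_ms` and `spacing_mm`.
#' @examples
#' gt <- build_phantom(vial_phantom_spec(grid_shape = c(16, 16, 1),
#'                                       noise_sigma = 0))
#' stk <- simulate_stack(gt)
#' res <- fit_t1_map(stk, mask = gt$label > 0)
#' range(res$t1_ms[res$valid])
#' @export
fit_t1_map <- function(stack, mask = NULL, options = fit_options()) {
  stopifnot(inherits(stack, "contrast_stack"))
  gs <- grid_shape(stack)
  if (is.null(mask)) mask <- array(TRUE, gs)
  if (!identical(dim(mask), as.integer(gs)) &&
      !identical(dim(mask), gs))
    stop("mask shape does not match the stack grid")
  if (stack$n < 4L)
    stop("at least 4 contrasts are needed for a three-parameter fit")

  vox <- prod(gs)
  smat <- matrix(stack$data, nrow = vox)  # voxels x contrasts
  t1 <- a <- b <- resd <- rep(NaN, vox)
  valid <- rep(FALSE, vox)
  idx <- which(as.logical(mask))
  for (v in idx) {
    f <- fit_voxel(smat[v, ], stack$times_ms, options)
    t1[v] <- f$t1_ms; a[v] <- f$a; b[v] <- f$b; resd[v] <- f$residual
    valid[v] <- isTRUE(f$converged)
  }
  t1[!valid] <- NaN; a[!valid] <- NaN; b[!valid] <- NaN
  structure(
    list(t1_ms = array(t1, gs), a = array(a, gs), b = array(b, gs),
         residual = array(resd, gs), valid = array(valid, gs),
         times_ms = stack$times_ms, spacing_mm = stack$spacing_mm),
    class = "t1_map_result")
}

#' @export
print.t1_map_result <- function(x, ...) {
  d <- dim(x$t1_ms)
  nv <- sum(x$valid)
  cat(sprintf("<t1_map_result> %d x %d x %d grid, %d valid voxels\n",
              d[1], d[2], d[3], nv))
  if (nv > 0)
    cat(sprintf("  T1 range (valid): %.1f - %.1f ms\n",
                min(x$t1_ms[x$valid]), max(x$t1_ms[x$valid])))
  invisible(x)
}
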