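#' Denoising parameters for the multi-contrast Beltrami energy
#'
#' Controls for the edge-preserving denoising energy
#' \deqn{\sum_i \|m_i - d_i\|_2^2 +
#'       \lambda \sum_v \sqrt{1 + \beta^2 \sum_i |\nabla^w m_i|^2}}
#' and its primal-dual hybrid gradient (PDHG) solver. The per-voxel square
#' root couples the spatial gradients of all `n` contrasts, so edges present
#' in several T1-weighted images are preserved while contrast-specific
#' intensity fluctuations are treated as noise.
#'
#' @param lam Regularization weight \eqn{\lambda \ge 0} balancing data
#'   fidelity against the Beltrami term. Default 0.25.
#' @param beta Beltrami constant \eqn{\beta > 0} interpolating between
#'   quadratic (small \eqn{\beta}) and total-variation-like (large
#'   \eqn{\beta}) behavior. Default 1.0.
#' @param h Gradient-weight smoothing parameter (> 0) of
#'   \eqn{w(m_i) = \exp(-|\nabla m_i|^2 / h^2)}. Default 5. Both `lam` and
#'   `h` are scale-dependent; see the `normalize` argument of
#'   [denoise_stack()].
#' @param max_iters Maximum PDHG iterations.
#' @param tol Relative-change stopping tolerance, assessed over 5-iteration
#'   windows of the primal iterate.
#' @param tau,sigma_dual Primal/dual step sizes. `NULL` (default) sets
#'   `tau = sigma_dual = 0.99 / L` with `L` the operator-norm bound of the
#'   weighted gradient estimated by power iteration; explicit values must
#'   satisfy the convergence condition `tau * sigma_dual * L^2 <= 1`
#'   (checked when the solver runs).
#' @param weight_update_every Iterations between recomputations of the
#'   gradient weights from the current denoised iterate; 1 (default)
#'   re-estimates them every iteration, 0 freezes them at the weights of the
#'   observed data (each inner problem is then convex).
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(lam = 0.25, beta = 1.0, h = 5,
                           max_iters = 300L, tol = 1e-5,
                           tau = NULL, sigma_dual = NULL,
                           weight_update_every = 1L) {
  if (lam < 0) stop("lam must be >= 0")
  if (beta <= 0) stop("beta must be > 0")
  if (h <= 0) stop("h must be > 0")
  if (max_iters < 1) stop("max_iters must be a positive integer")
  if (tol <= 0) stop("tol must be > 0")
  if (!is.null(tau) && tau <= 0) stop("tau must be > 0")
  if (!is.null(sigma_dual) && sigma_dual <= 0) stop("sigma_dual must be > 0")
  if (weight_update_every < 0) stop("weight_update_every must be >= 0")
  structure(list(lam = lam, beta = beta, h = h,
                 max_iters = as.integer(max_iters), tol = tol,
                 tau = tau, sigma_dual = sigma_dual,
                 weight_update_every = as.integer(weight_update_every)),
            class = "denoise_params")
}

# ---- discrete differential operators -------------------------------------
# Forward differences with Neumann (replicate-edge) boundary: the difference
# at the last voxel along an axis is zero. Differences are divided by the
# physical spacing so anisotropic voxels (e.g. 8 mm slices) are penalized
# consistently with the in-plane directions.

diff_fwd <- function(vol, axis, delta) {
  d <- dim(vol); n <- d[axis]
  out <- array(0, d)
  if (n < 2L) return(out)
  i <- seq_len(n - 1L)
  switch(axis,
    out[i, , ] <- (vol[i + 1L, , , drop = FALSE] - vol[i, , , drop = FALSE]) / delta,
    out[, i, ] <- (vol[, i + 1L, , drop = FALSE] - vol[, i, , drop = FALSE]) / delta,
    out[, , i] <- (vol[, , i + 1L, drop = FALSE] - vol[, , i, drop = FALSE]) / delta)
  out
}

# Backward-difference divergence, the exact negative adjoint of diff_fwd:
# <D u, p> = -<u, div p> holds to machine precision (the last plane of p
# along the axis is ignored, matching the zero row of D).
div_bwd <- function(p, axis, delta) {
  d <- dim(p); n <- d[axis]
  out <- array(0, d)
  if (n < 2L) return(out)
  q <- p
  switch(axis, q[n, , ] <- 0, q[, n, ] <- 0, q[, , n] <- 0)
  i <- 2:n
  switch(axis, {
    out[1, , ] <- q[1, , ]
    out[i, , ] <- q[i, , , drop = FALSE] - q[i - 1L, , , drop = FALSE]
  }, {
    out[, 1, ] <- q[, 1, ]
    out[, i, ] <- q[, i, , drop = FALSE] - q[, i - 1L, , drop = FALSE]
  }, {
    out[, , 1] <- q[, , 1]
    out[, , i] <- q[, , i, drop = FALSE] - q[, , i - 1L, drop = FALSE]
  })
  out / delta
}

grad3 <- function(vol, spacing) {
  list(diff_fwd(vol, 1L, spacing[1]),
       diff_fwd(vol, 2L, spacing[2]),
       diff_fwd(vol, 3L, spacing[3]))
}

div3 <- function(px, py, pz, spacing) {
  div_bwd(px, 1L, spacing[1]) + div_bwd(py, 2L, spacing[2]) +
    div_bwd(pz, 3L, spacing[3])
}

# squared gradient magnitude of one volume
grad_mag2 <- function(vol, spacing) {
  g <- grad3(vol, spacing)
  g[[1]]^2 + g[[2]]^2 + g[[3]]^2
}

# edge weights w = exp(-|grad|^2 / h^2), in (0, 1]
edge_weights <- function(vol, h, spacing) exp(-grad_mag2(vol, spacing) / h^2)

#' Edge-weighted spatial gradient of a volume
#'
#' Computes the weighted gradient \eqn{w(m)\,\nabla m} used inside the
#' Beltrami regularizer: forward-difference gradients with replicate-edge
#' (Neumann) boundary, scaled by the physical voxel spacing per axis, and
#' attenuated voxel-wise by \eqn{w = \exp(-|\nabla m|^2 / h^2)} so that
#' sharp transitions (\eqn{|\nabla m| \gg h}) contribute almost nothing to
#' the penalty.
#'
#' @param volume 3D numeric array.
#' @param h Weight smoothing parameter (> 0), in intensity-per-mm units of
#'   the gradient.
#' @param spacing_mm Per-axis voxel spacing (mm).
#' @return A list with components `x`, `y`, `z` (the weighted gradient
#'   field) and `w` (the weights).
#' @examples
#' ramp <- array(rep(1:8, 8 * 2), c(8, 8, 2))  # unit slope along x
#' g <- weighted_gradient(ramp, h = 5, spacing_mm = c(1, 1, 1))
#' g$x[3, 3, 1]  # exp(-1/25) ~ 0.9608
#' @export
weighted_gradient <- function(volume, h, spacing_mm = c(1, 1, 1)) {
  if (h <= 0) stop("h must be > 0")
  if (!all(is.finite(volume))) stop("volume must be finite")
  g <- grad3(volume, spacing_mm)
  w <- exp(-(g[[1]]^2 + g[[2]]^2 + g[[3]]^2) / h^2)
  list(x = w * g[[1]], y = w * g[[2]], z = w * g[[3]], w = w)
}

# weights for every contrast: 4D array (x,y,z,n)
stack_weights <- function(data4, h, spacing) {
  d <- dim(data4)
  w <- array(0, d)
  for (k in seq_len(d[4]))
    w[, , , k] <- edge_weights(data4[, , , k], h, spacing)
  w
}

# K m: weighted gradient of every contrast, 5D array (x,y,z,n,axis)
op_K <- function(m4, w4, spacing) {
  d <- dim(m4)
  y <- array(0, c(d, 3L))
  for (k in seq_len(d[4])) {
    g <- grad3(m4[, , , k], spacing)
    y[, , , k, 1] <- w4[, , , k] * g[[1]]
    y[, , , k, 2] <- w4[, , , k] * g[[2]]
    y[, , , k, 3] <- w4[, , , k] * g[[3]]
  }
  y
}

# K^T y = -div(w y) per contrast
op_Kt <- function(y5, w4, spacing) {
  d <- dim(y5)[1:4]
  out <- array(0, d)
  for (k in seq_len(d[4]))
    out[, , , k] <- -div3(w4[, , , k] * y5[, , , k, 1],
                          w4[, , , k] * y5[, , , k, 2],
                          w4[, , , k] * y5[, , , k, 3], spacing)
  out
}

# operator norm bound of the (unit-weight) gradient over the whole stack,
# by power iteration; weights <= 1 so this bounds any weighted operator
op_norm_bound <- function(d4, spacing, iters = 30L) {
  w1 <- array(1, d4)
  v0 <- array(sin(seq_len(prod(d4))), d4)  # fixed non-degenerate start, no RNG
  v <- v0 / sqrt(sum(v0^2))
  L <- 0
  for (i in seq_len(iters)) {
    u <- op_Kt(op_K(v, w1, spacing), w1, spacing)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(1e-12)
    v <- u / nu
    L <- sqrt(nu)
  }
  L
}

#' Multi-contrast Beltrami denoising energy
#'
#' Evaluates the objective minimized by [denoise_stack()]: the sum over
#' contrasts of the squared intensity misfit plus one coupled Beltrami term
#' per voxel,
#' \eqn{\sum_i \|m_i - d_i\|_2^2 + \lambda \sum_v
#' \sqrt{1 + \beta^2 \sum_i |\nabla^w m_i(v)|^2}}, where the inner sum runs
#' over all contrasts so that common edges are reinforced across the stack.
#'
#' @param candidate,observed [contrast_stack()]s on one grid (`m` and `d`).
#' @param params [denoise_params()].
#' @param weights Optional fixed 4D weight array (one weight volume per
#'   contrast); by default the weights are recomputed from `candidate`.
#' @return Scalar energy.
#' @export
beltrami_energy <- function(candidate, observed, params, weights = NULL) {
  stopifnot(inherits(candidate, "contrast_stack"),
            inherits(observed, "contrast_stack"))
  stopifnot_same_grid(candidate, observed)
  m <- candidate$data; d <- observed$data
  sp <- candidate$spacing_mm
  if (is.null(weights)) weights <- stack_weights(m, params$h, sp)
  y <- op_K(m, weights, sp)
  gm2 <- voxel_norm2(y)
  sum((m - d)^2) + params$lam * sum(sqrt(1 + params$beta^2 * gm2))
}

# fast per-voxel squared norm over (contrast, axis) of a 5D field
voxel_norm2 <- function(y5) {
  d <- dim(y5)
  v <- prod(d[1:3])
  array(rowSums(matrix(y5, nrow = v)^2), d[1:3])
}

beltrami_energy_fast <- function(m4, d4, w4, lam, beta, spacing) {
  y <- op_K(m4, w4, spacing)
  sum((m4 - d4)^2) + lam * sum(sqrt(1 + beta^2 * voxel_norm2(y)))
}

# prox of the conjugate of f(z) = lam * sqrt(1 + beta^2 |z|^2):
# f*(p) = -(1/beta) sqrt(lam^2 beta^2 - |p|^2) on |p| <= lam*beta.
# prox_{sig f*}(q) scales each voxel vector q_v to length t solving
#   t - s + (sig/beta) * t / sqrt(a^2 - t^2) = 0,  s = |q_v|, a = lam*beta,
# a strictly increasing convex function of t on [0, a), solved by a
# safeguarded vectorized Newton iteration (monotone from t = 0).
prox_dual_scale <- function(s, lam, beta, sig) {
  a <- lam * beta
  cc <- sig / beta
  t <- rep(0, length(s))
  pos <- s > 0
  if (!any(pos)) return(t)
  sv <- s[pos]
  tv <- rep(0, length(sv))
  for (it in 1:60) {
    rt <- sqrt(a^2 - tv^2)
    phi <- tv - sv + cc * tv / rt
    dphi <- 1 + cc * a^2 / rt^3
    step <- phi / dphi
    tv_new <- pmin(pmax(tv - step, 0), a * (1 - 1e-12))
    if (max(abs(tv_new - tv)) < 1e-14 * a) { tv <- tv_new; break }
    tv <- tv_new
  }
  t[pos] <- tv
  t
}

#' Denoise a multi-contrast stack by primal-dual hybrid gradient
#'
#' Minimizes the coupled Beltrami energy (see [beltrami_energy()]) over all
#' contrasts jointly, using a Chambolle-Pock primal-dual hybrid gradient
#' scheme. The per-voxel regularizer \eqn{\lambda\sqrt{1 + \beta^2 |z|^2}}
#' (with `z` the stacked weighted gradients of all contrasts) is dualized via
#' its convex conjugate; its dual proximal map is evaluated by a vectorized
#' Newton solve. The edge weights are recomputed from the current denoised
#' iterate every `weight_update_every` iterations.
#'
#' @param observed A [contrast_stack()] of magnitude images.
#' @param params A [denoise_params()].
#' @param normalize Logical. `lam` and `h` are intensity-scale dependent; by
#'   default the stack is scaled so that the 99th percentile of the
#'   unprepared image (or of the whole stack if no unprepared image is
#'   present) maps to 1 before denoising, and rescaled after. The scale used
#'   is recorded in the report. Set `FALSE` to apply the parameters on raw
#'   intensities.
#' @param index_space Logical; if `TRUE`, gradients are taken in index space
#'   (unit spacing) instead of physical mm, for comparison.
#' @param divergence_patience Number of consecutive energy increases (beyond
#'   a 1e-3 relative tolerance) after which the solver aborts with an error
#'   advising smaller step sizes.
#' @return A list with elements `stack` (the denoised [contrast_stack()])
#'   and `report`, a `solve_report` containing `iterations_run`,
#'   `energy_trace` (energy at each iterate, current weights),
#'   `final_relative_change`, `converged`, `scale` (the normalization
#'   constant), `energy_initial_weights` and `energy_final_weights` (energy
#'   of the output under the first and last weight estimates).
#' @details With `lam = 0` the fidelity-only problem has the closed-form
#'   minimizer `m = d`, which is returned directly. Step sizes default to
#'   `0.99 / L` with `L` bounded by power iteration on the unit-weight
#'   gradient operator; the convergence condition
#'   `tau * sigma_dual * L^2 <= 1` is enforced.
#' @examples
#' gt <- build_phantom(vial_phantom_spec(grid_shape = c(24, 24, 2)))
#' stk <- simulate_stack(gt)
#' out <- denoise_stack(stk, denoise_params(max_iters = 50))
#' out$report$converged
#' @export
denoise_stack <- function(observed, params = denoise_params(),
                          normalize = TRUE, index_space = FALSE,
                          divergence_patience = 10L) {
  stopifnot(inherits(observed, "contrast_stack"),
            inherits(params, "denoise_params"))
  sp <- if (index_space) c(1, 1, 1) else observed$spacing_mm
  d4 <- observed$data

  if (params$lam == 0) {  # exact minimizer of the fidelity-only energy
    rep0 <- structure(list(iterations_run = 0L, energy_trace = numeric(0),
                           final_relative_change = 0, converged = TRUE,
                           scale = 1,
                           energy_initial_weights = 0,
                           energy_final_weights = 0),
                      class = "solve_report")
    return(list(stack = observed, report = rep0))
  }

  # intensity normalization: lam and h act on a unit-scaled stack
  scale <- 1
  if (normalize) {
    unprep <- which(!is.finite(observed$times_ms))
    ref <- if (length(unprep) == 1L) d4[, , , unprep] else d4
    scale <- as.numeric(stats::quantile(ref, 0.99, names = FALSE))
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  d4 <- d4 / scale

  lam <- params$lam; beta <- params$beta; h <- params$h
  L <- op_norm_bound(dim(d4), sp)
  tau <- params$tau %||% (0.99 / L)
  sig <- params$sigma_dual %||% (0.99 / L)
  if (tau * sig * L^2 > 1 + 1e-9)
    stop(sprintf("step sizes violate tau * sigma_dual * L^2 <= 1 (L ~ %.3g)", L))

  m <- d4
  mbar <- m
  w <- stack_weights(m, h, sp)
  w_init <- w
  y <- array(0, c(dim(d4), 3L))
  dims3 <- dim(d4)[1:3]
  vox <- prod(dims3)
  ncomp <- dim(d4)[4] * 3L

  energy_trace <- numeric(params$max_iters)
  m_window <- m
  final_rel <- Inf
  converged <- FALSE
  iters <- 0L
  bad_streak <- 0L

  for (it in seq_len(params$max_iters)) {
    iters <- it
    # dual ascent + prox of conjugate Beltrami term
    q <- y + sig * op_K(mbar, w, sp)
    qmat <- matrix(q, nrow = vox)
    s <- sqrt(rowSums(qmat^2))
    t <- prox_dual_scale(s, lam, beta, sig)
    scl <- ifelse(s > 0, t / s, 0)
    y <- array(qmat * scl, dim = dim(q))
    # primal descent + prox of the fidelity term ||m - d||^2
    m_new <- (m - tau * op_Kt(y, w, sp) + 2 * tau * d4) / (1 + 2 * tau)
    mbar <- 2 * m_new - m
    m <- m_new
    # lagged weight update from the current denoised iterate
    if (params$weight_update_every > 0L &&
        it %% params$weight_update_every == 0L)
      w <- stack_weights(m, h, sp)
    energy_trace[it] <- beltrami_energy_fast(m, d4, w, lam, beta, sp)
    if (it > 1L) {
      if (energy_trace[it] > energy_trace[it - 1L] * (1 + 1e-3)) {
        bad_streak <- bad_streak + 1L
        if (bad_streak >= divergence_patience)
          stop("energy increased for ", bad_streak,
               " consecutive iterations; reduce tau/sigma_dual")
      } else bad_streak <- 0L
    }
    if (it %% 5L == 0L) {
      final_rel <- sqrt(sum((m - m_window)^2)) / max(sqrt(sum(m^2)), 1e-12)
      m_window <- m
      if (final_rel < params$tol) { converged <- TRUE; break }
    }
  }

  energy_trace <- energy_trace[seq_len(iters)]
  e_init <- beltrami_energy_fast(m, d4, w_init, lam, beta, sp)
  e_final <- beltrami_energy_fast(m, d4, w, lam, beta, sp)
  out <- contrast_stack(m * scale, times_ms = observed$times_ms,
                        spacing_mm = observed$spacing_mm)
  report <- structure(
    list(iterations_run = iters, energy_trace = energy_trace,
         final_relative_change = max(final_rel, 0), converged = converged,
         scale = scale,
         energy_initial_weights = e_init, energy_final_weights = e_final),
    class = "solve_report")
  list(stack = out, report = report)
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report> %d iterations, converged = %s\n",
              x$iterations_run, x$converged))
  cat(sprintf("  final relative change: %.3g; normalization scale: %.6g\n",
              x$final_relative_change, x$scale))
  if (length(x$energy_trace))
    cat(sprintf("  energy: %.6g -> %.6g (current weights)\n",
                x$energy_trace[1], x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}
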