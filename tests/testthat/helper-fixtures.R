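# Fixtures built in code: tiny stacks, phantoms and an independent
# first-order-descent minimizer of the fixed-weight Beltrami energy used as
# the oracle for the PDHG solver.

tiny_stack <- function(d = c(6, 5, 4), n = 2, spacing = c(1, 1, 1),
                       seed = 1) {
  set.seed(seed)
  arr <- array(stats::runif(prod(d) * n), c(d, n))
  times <- c(seq(100, 700, length.out = n - 1), Inf)
  contrast_stack(arr, times_ms = times, spacing_mm = spacing)
}

small_vial_spec <- function(...) {
  vial_phantom_spec(grid_shape = c(32, 32, 2), ...)
}

# Independent oracle: plain fixed-step gradient descent on the identical
# fixed-weight energy, written against its own finite-difference operators
# (forward differences, replicate-edge boundary, spacing-scaled).
oracle_grad3 <- function(v, sp) {
  d <- dim(v)
  gx <- gy <- gz <- array(0, d)
  if (d[1] > 1) gx[-d[1], , ] <- (v[-1, , ] - v[-d[1], , ]) / sp[1]
  if (d[2] > 1) gy[, -d[2], ] <- (v[, -1, ] - v[, -d[2], ]) / sp[2]
  if (d[3] > 1) gz[, , -d[3]] <- (v[, , -1] - v[, , -d[3]]) / sp[3]
  list(gx, gy, gz)
}

# adjoint of oracle_grad3 applied to a weighted field, by direct transposition
oracle_gradT <- function(px, py, pz, sp) {
  d <- dim(px)
  out <- array(0, d)
  acc <- function(p, axis, delta) {
    r <- array(0, d)
    n <- d[axis]
    if (n < 2) return(r)
    switch(axis, {
      r[-n, , ] <- r[-n, , ] - p[-n, , ] / delta
      r[-1, , ] <- r[-1, , ] + p[-n, , ] / delta
    }, {
      r[, -n, ] <- r[, -n, ] - p[, -n, ] / delta
      r[, -1, ] <- r[, -1, ] + p[, -n, ] / delta
    }, {
      r[, , -n] <- r[, , -n] - p[, , -n] / delta
      r[, , -1] <- r[, , -1] + p[, , -n] / delta
    })
    r
  }
  acc(px, 1, sp[1]) + acc(py, 2, sp[2]) + acc(pz, 3, sp[3])
}

oracle_energy <- function(m4, d4, w4, lam, beta, sp) {
  n <- dim(m4)[4]
  gm2 <- 0
  for (k in seq_len(n)) {
    g <- oracle_grad3(m4[, , , k], sp)
    gm2 <- gm2 + w4[, , , k]^2 * (g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  }
  sum((m4 - d4)^2) + lam * sum(sqrt(1 + beta^2 * gm2))
}

oracle_minimize <- function(d4, w4, lam, beta, sp, iters = 20000) {
  n <- dim(d4)[4]
  lip <- 2 + lam * beta^2 * 4 * sum(1 / sp^2)  # crude smoothness bound
  step <- 1 / lip
  m <- d4
  for (it in seq_len(iters)) {
    gm2 <- 0
    gs <- vector("list", n)
    for (k in seq_len(n)) {
      g <- oracle_grad3(m[, , , k], sp)
      gs[[k]] <- g
      gm2 <- gm2 + w4[, , , k]^2 * (g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
    }
    denom <- sqrt(1 + beta^2 * gm2)
    grad <- 2 * (m - d4)
    for (k in seq_len(n)) {
      w2 <- w4[, , , k]^2
      grad[, , , k] <- grad[, , , k] + lam * beta^2 *
        oracle_gradT(w2 * gs[[k]][[1]] / denom, w2 * gs[[k]][[2]] / denom,
                     w2 * gs[[k]][[3]] / denom, sp)
    }
    m <- m - step * grad
  }
  m
}
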