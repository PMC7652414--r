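# Adaptive Dormand-Prince 5(4) integrator for a scalar, non-stiff ODE.
# The length dynamics are one-dimensional and smooth, so a hand-rolled
# embedded Runge-Kutta pair with FSAL is all that is needed; it is
# cross-checked against a fixed-step RK4 oracle in the test suite.
#
# f: function(y) -> dy/dt (autonomous); times: increasing, times[1] = t0.
# Returns y evaluated at `times`. If clamp_zero, y is held at 0 whenever
# y = 0 and f(y) < 0 (no negative lengths).
rk45_integrate <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                           clamp_zero = TRUE) {
  stopifnot(length(times) >= 1L, !is.unsorted(times, strictly = TRUE))
  fc <- if (clamp_zero) {
    function(y) {
      r <- f(max(y, 0))
      if (y <= 0 && r < 0) 0 else r
    }
  } else f

  out <- numeric(length(times))
  out[1L] <- y0
  if (length(times) == 1L) return(out)

  t <- times[1L]
  y <- y0
  k1 <- fc(y)
  h <- min(1e-2, times[length(times)] - t)  # conservative first step
  hmin_factor <- 1e-12

  for (i in 2L:length(times)) {
    t_target <- times[i]
    while (t < t_target) {
      if (h < hmin_factor * max(1, abs(t)))
        stop("integration step underflow at t = ", signif(t, 6),
             ", L = ", signif(y, 6), call. = FALSE)
      h_full <- h                      # controller step, kept across caps
      h <- min(h, t_target - t)
      k2 <- fc(y + h * (k1 / 5))
      k3 <- fc(y + h * (3 / 40 * k1 + 9 / 40 * k2))
      k4 <- fc(y + h * (44 / 45 * k1 - 56 / 15 * k2 + 32 / 9 * k3))
      k5 <- fc(y + h * (19372 / 6561 * k1 - 25360 / 2187 * k2 +
                          64448 / 6561 * k3 - 212 / 729 * k4))
      k6 <- fc(y + h * (9017 / 3168 * k1 - 355 / 33 * k2 +
                          46732 / 5247 * k3 + 49 / 176 * k4 -
                          5103 / 18656 * k5))
      y5 <- y + h * (35 / 384 * k1 + 500 / 1113 * k3 + 125 / 192 * k4 -
                       2187 / 6784 * k5 + 11 / 84 * k6)
      k7 <- fc(y5)
      y4 <- y + h * (5179 / 57600 * k1 + 7571 / 16695 * k3 +
                       393 / 640 * k4 - 92097 / 339200 * k5 +
                       187 / 2100 * k6 + 1 / 40 * k7)
      sc <- atol + rtol * max(abs(y), abs(y5))
      err <- abs(y5 - y4) / sc
      if (is.nan(err)) err <- Inf
      if (err <= 1) {
        t <- t + h
        y <- if (clamp_zero) max(y5, 0) else y5
        k1 <- if (y == y5) k7 else fc(y)  # FSAL unless the clamp fired
        fac <- if (err > 0) 0.9 * err^(-0.2) else 5
        h <- max(h, h_full) * min(5, max(0.2, fac))
      } else {
        h <- h * max(0.2, 0.9 * err^(-0.2))
      }
    }
    out[i] <- y
  }
  out
}

# Fixed-step classical RK4; the independent low-tech oracle used by the
# tests to validate the adaptive integrator.
rk4_fixed <- function(f, y0, times, dt = 0.01, clamp_zero = TRUE) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  fc <- if (clamp_zero) {
    function(y) {
      r <- f(max(y, 0))
      if (y <= 0 && r < 0) 0 else r
    }
  } else f
  out <- numeric(length(times))
  out[1L] <- y0
  t <- times[1L]
  y <- y0
  for (i in seq_along(times)[-1L]) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- fc(y)
      k2 <- fc(y + h / 2 * k1)
      k3 <- fc(y + h / 2 * k2)
      k4 <- fc(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (clamp_zero) y <- max(y, 0)
      t <- t + h
    }
    out[i] <- y
  }
  out
}

# Fast closure for dL/dt of a given case (avoids per-call dispatch in the
# inner integration loop).
length_rate_fn <- function(params, case) {
  case <- check_case_params(params, case)
  N <- params$N; K <- params$K; v <- params$v; D <- params$D
  delta <- params$delta; d <- params$d
  switch(case,
    motor_limited = function(L) delta * N / (1 / K + L / v + L^2 / (2 * D)) - d,
    tubulin_limited = {
      alpha <- params$alpha; Tpool <- params$T
      function(L) alpha * N * (Tpool - L) / (1 / K + L / v + L^2 / (2 * D)) - d
    },
    length_dependent_disassembly = {
      d1 <- params$d1
      function(L) {
        J <- N / (1 / K + L / v + L^2 / (2 * D))
        delta * J - d - d1 * J * L / D
      }
    })
}
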