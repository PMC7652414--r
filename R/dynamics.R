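#' Simulate ciliary regeneration
#'
#' Integrates the selected rate law from an initial length `L0` (0 after
#' deflagellation) to `t_end`, with the injection rate `J` from the
#' quasi-steady flux balance at every instant. Transport across the cilium
#' takes seconds while regeneration takes hours, so the motor partition is
#' slaved to the current length and computed pointwise from `L(t)`.
#'
#' The integrator is an adaptive embedded Runge-Kutta (Dormand-Prince 5(4),
#' relative tolerance 1e-8, absolute 1e-10 by default); lengths are clamped
#' at zero when disassembly dominates an empty cilium.
#'
#' @inheritParams length_rate
#' @param L0 initial length (um), >= 0; default 0 (deflagellation).
#' @param t_end simulated time (s); default 3 h, beyond 99% convergence for
#'   the reference presets. See [suggest_t_end()] for other parameter sets.
#' @param dt_out output sampling interval (s); default 1 s uniform grid.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `"cilium_trajectory"`: a data frame with
#'   columns `t`, `L`, `J`, `n_ballistic`, `n_diffusive`, `n_free`, and
#'   attributes `params`, `case`, `L_ss` (closed form, `NA` if none),
#'   `converged` (final length within 1% of `L_ss`), and `solver`.
#' @examples
#' traj <- simulate_regeneration(preset_params("case1"), "case1",
#'                               t_end = 3600, dt_out = 60)
#' tail(traj, 2)
#' @export
simulate_regeneration <- function(params, case, L0 = 0, t_end = 3 * 3600,
                                  dt_out = 1, rtol = 1e-8, atol = 1e-10) {
  case <- check_case_params(params, case)
  if (L0 < 0) stop("L0 must be >= 0", call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (case == "tubulin_limited" && L0 > params$T)
    stop("L0 exceeds the tubulin pool T", call. = FALSE)

  times <- seq(0, t_end, by = dt_out)
  if (t_end - times[length(times)] > 1e-9 * t_end) times <- c(times, t_end)
  f <- length_rate_fn(params, case)
  L <- rk45_integrate(f, L0, times, rtol = rtol, atol = atol)
  part <- motor_partition(params, L)

  ss <- lss_closed_form(params, case)
  converged <- ss$exists &&
    abs(L[length(L)] - ss$L_ss) < 0.01 * ss$L_ss

  traj <- data.frame(t = times, L = L, J = injection_rate(params, L),
                     n_ballistic = part$n_ballistic,
                     n_diffusive = part$n_diffusive,
                     n_free = part$n_free)
  structure(traj,
            class = c("cilium_trajectory", "data.frame"),
            params = params, case = case,
            L_ss = ss$L_ss, converged = converged,
            solver = list(method = "dopri5(4)", rtol = rtol, atol = atol,
                          dt_out = dt_out, L0 = L0, t_end = t_end))
}

#' Suggest an integration horizon for convergence
#'
#' Heuristic `t_end` long enough for a regeneration trajectory to settle
#' at the steady state: a growth ramp (four times the steady length over
#' the mid-growth rate) plus fifteen relaxation times of the linearized
#' dynamics at `L_ss`.
#'
#' @inheritParams length_rate
#' @return Time horizon (s), or `NA` when no steady state exists.
#' @export
suggest_t_end <- function(params, case) {
  ss <- lss_closed_form(params, case)
  if (!ss$exists) return(NA_real_)
  f <- length_rate_fn(params, case)
  h <- 1e-4 * ss$L_ss
  fprime <- (f(ss$L_ss + h) - f(ss$L_ss - h)) / (2 * h)
  mid_rate <- max(f(ss$L_ss / 2), .Machine$double.eps)
  ramp <- 4 * ss$L_ss / mid_rate
  relax <- if (fprime < 0) 15 / abs(fprime) else 0
  ramp + relax
}

#' Time to reach a fraction of the steady-state length
#'
#' First time at which the trajectory reaches `fraction * L_ss`, by linear
#' interpolation between output samples. The growth-time metric used in
#' the sweeps is `fraction = 0.95`.
#'
#' @param traj a [simulate_regeneration()] trajectory that converged
#'   (final length within 1% of the closed-form steady state).
#' @param fraction target fraction of `L_ss`, in (0, 1).
#' @return Time (s).
#' @export
growth_time <- function(traj, fraction = 0.95) {
  stopifnot(inherits(traj, "cilium_trajectory"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  if (!isTRUE(attr(traj, "converged")))
    stop("trajectory has not converged to the steady state; ",
         "increase t_end", call. = FALSE)
  target <- fraction * attr(traj, "L_ss")
  L <- traj$L; t <- traj$t
  if (L[1L] >= target) return(t[1L])
  i <- which(L >= target)[1L]
  if (is.na(i)) stop("trajectory never reaches the target fraction", call. = FALSE)
  # linear interpolation on the bracketing interval
  t[i - 1L] + (target - L[i - 1L]) / (L[i] - L[i - 1L]) * (t[i] - t[i - 1L])
}

#' Injection rate versus length along a trajectory
#'
#' Pairs (L, J) traced out by a growing cilium; along growth `J` falls
#' monotonically with `L`, and a slower motor's curve lies below the
#' wild-type curve at every matched length.
#'
#' @param traj a [simulate_regeneration()] trajectory.
#' @return Data frame with columns `L` and `J`.
#' @export
injection_vs_length <- function(traj) {
  stopifnot(inherits(traj, "cilium_trajectory"))
  data.frame(L = traj$L, J = traj$J)
}

#' @export
print.cilium_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Ciliary regeneration trajectory (%s)\n", attr(x, "case")))
  cat(sprintf("  %d samples over %.0f s; L: %.3f -> %.3f um\n",
              n, x$t[n], x$L[1L], x$L[n]))
  if (is.finite(attr(x, "L_ss")))
    cat(sprintf("  closed-form L_ss = %.3f um; converged: %s\n",
                attr(x, "L_ss"), attr(x, "converged")))
  invisible(x)
}

#' Plot a regeneration trajectory
#'
#' Length and injection rate against time, base-graphics style.
#'
#' @param x a `cilium_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cilium_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$t / 60, x$L, type = "l", xlab = "time (min)",
                 ylab = "length (um)", main = "ciliary regeneration", ...)
  graphics::plot(x$t / 60, x$J, type = "l", xlab = "time (min)",
                 ylab = "injection rate (motors/s)", main = "IFT injection", ...)
  invisible(x)
}
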