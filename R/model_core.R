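#' Length-dependent IFT injection rate
#'
#' Flux of motors injected at the ciliary base for a cilium of length `L`,
#' under quasi-steady flux balance of a conserved motor pool:
#' \deqn{J(v, L) = \frac{N}{1/K + L/v + L^2/(2D)}}
#' The three denominator terms are the reinjection delay at the base, the
#' anterograde transit time and the mean diffusive return time. `J`
#' decreases with length (the empirical 1/L-like scaling) and increases
#' with each of `N`, `K`, `v` and `D`.
#'
#' @param params a [model_params()] object.
#' @param L ciliary length (um); vectorized, must be >= 0.
#' @return Injection rate (motors/s), same length as `L`.
#' @examples
#' injection_rate(preset_params("case1"), c(0, 6, 12))
#' @export
injection_rate <- function(params, L) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(L)) || any(L < 0))
    stop("L must be finite and >= 0", call. = FALSE)
  params$N / (1 / params$K + L / params$v + L^2 / (2 * params$D))
}

#' Partition of the motor pool at a given length
#'
#' Splits the conserved pool of `N` motors into motors in anterograde
#' transit (`n_ballistic = J*L/v`), motors diffusing back to the base
#' (`n_diffusive = J*L^2/(2D)`) and free motors waiting at the base
#' (`n_free = J/K`). The three always sum to `N`.
#'
#' @inheritParams injection_rate
#' @return A data frame with columns `L`, `n_ballistic`, `n_diffusive`,
#'   `n_free` (one row per element of `L`).
#' @examples
#' motor_partition(preset_params("case1"), L = c(0, 12))
#' @export
motor_partition <- function(params, L) {
  J <- injection_rate(params, L)
  data.frame(
    L = L,
    n_ballistic = J * L / params$v,
    n_diffusive = J * L^2 / (2 * params$D),
    n_free = J / params$K
  )
}

#' Length dynamics dL/dt for the three rate laws
#'
#' * motor-limited (`"case1"`): `dL/dt = delta * J - d`
#' * tubulin-limited (`"case2"`): `dL/dt = alpha * J * (T - L) - d`
#' * length-dependent disassembly (`"case3"`):
#'   `dL/dt = delta * J - d - d1 * J * L / D`
#'
#' with `J = injection_rate(params, L)` in each case.
#'
#' @inheritParams injection_rate
#' @param case model case label (see [normalize_case()]).
#' @return dL/dt (um/s), same length as `L`.
#' @export
length_rate <- function(params, case, L) {
  case <- check_case_params(params, case)
  J <- injection_rate(params, L)
  switch(case,
    motor_limited = params$delta * J - params$d,
    tubulin_limited = {
      if (any(L > params$T))
        stop("L exceeds the total tubulin pool T; tubulin-limited rate law ",
             "is undefined there", call. = FALSE)
      params$alpha * J * (params$T - L) - params$d
    },
    length_dependent_disassembly =
      params$delta * J - params$d - params$d1 * J * L / params$D
  )
}

#' Motor residence times in the cilium
#'
#' Time a motor spends in each leg of its cycle for a cilium of length `L`:
#' anterograde transit `t_ballistic = L/v`, mean 1-D diffusive return
#' `t_diffusive = L^2/(2D)`, and their sum. At the wild-type steady state
#' (L = 12 um, v = 2.3 um/s, D = 2 um^2/s) these are ~5 s, ~36 s, ~41 s:
#' diffusion dominates motor limitation at steady-state lengths.
#'
#' @param L ciliary length (um), vectorized, >= 0.
#' @param v anterograde speed (um/s), > 0.
#' @param D diffusion constant (um^2/s), > 0.
#' @return A data frame with columns `t_ballistic`, `t_diffusive`,
#'   `t_total` (seconds).
#' @export
residence_times <- function(L, v, D) {
  if (any(!is.finite(L)) || any(L < 0)) stop("L must be >= 0", call. = FALSE)
  if (length(v) != 1L || !is.finite(v) || v <= 0) stop("v must be > 0", call. = FALSE)
  if (length(D) != 1L || !is.finite(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  tb <- L / v
  td <- L^2 / (2 * D)
  data.frame(t_ballistic = tb, t_diffusive = td, t_total = tb + td)
}

#' Ciliary IFT mass
#'
#' Quantity of IFT material inside a cilium given its length, the
#' anterograde speed and the injection flux: `M = L/v * J` (flux times
#' anterograde residence time). Dimensionless amount (motor equivalents).
#'
#' @param L ciliary length (um), >= 0.
#' @param v anterograde speed (um/s), > 0.
#' @param J injection flux (motors/s), >= 0.
#' @return IFT mass `M` (dimensionless).
#' @export
ift_mass <- function(L, v, J) {
  if (any(L < 0) || any(J < 0)) stop("L and J must be >= 0", call. = FALSE)
  if (length(v) != 1L || !is.finite(v) || v <= 0)
    stop("v must be > 0", call. = FALSE)
  L * J / v
}
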