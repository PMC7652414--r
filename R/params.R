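#' Parameter set for the kinesin recycling model
#'
#' Bundles the parameters of the motor-recycling model of ciliary length
#' control. A conserved pool of `N` kinesin-II motors is injected at the
#' ciliary base at rate `J = K * N_free`, walks to the tip at speed `v`,
#' and returns to the base by diffusion with diffusion constant `D`.
#' Assembly and disassembly parameters (`delta`, `d`, and for the extended
#' rate laws `alpha`, `T`, `d1`) set the length dynamics.
#'
#' @param N total motor count (dimensionless, conserved pool).
#' @param K injection kinetic constant (1/s); `1/K` is the delay time for
#'   motor reinjection at the base.
#' @param v anterograde motor speed (um/s).
#' @param D retrograde diffusion constant (um^2/s).
#' @param delta length increment per motor arrival (um per motor); used by
#'   the motor-limited and length-dependent-disassembly rate laws.
#' @param d disassembly rate (um/s).
#' @param alpha tubulin binding factor (per motor, dimensionless); only
#'   used by the tubulin-limited rate law.
#' @param T total tubulin pool expressed as equivalent length (um); only
#'   used by the tubulin-limited rate law.
#' @param d1 length-dependent disassembly coefficient, stored as the plain
#'   numeric value `0.1 * d` convention; only used by the
#'   length-dependent-disassembly rate law.
#'
#' @return An object of class `"model_params"`: a named list with the
#'   fields above.
#' @seealso [preset_params()] for the reference parameterizations.
#' @examples
#' p <- model_params(N = 100, K = 1, v = 2.3, D = 2.5)
#' injection_rate(p, L = 0)  # = K * N
#' @export
model_params <- function(N = 100, K = 1, v = 2.3, D = 2.5,
                         delta = 1.5e-3, d = 0.004,
                         alpha = NA_real_, T = NA_real_, d1 = NA_real_) {
  p <- list(N = as.numeric(N), K = as.numeric(K), v = as.numeric(v),
            D = as.numeric(D), delta = as.numeric(delta), d = as.numeric(d),
            alpha = as.numeric(alpha), T = as.numeric(T), d1 = as.numeric(d1))
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  req <- c("N", "K", "v", "D", "delta", "d")
  for (f in req) {
    val <- p[[f]]
    if (length(val) != 1L || !is.finite(val))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$N <= 0) stop("N must be > 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  if (p$v <= 0) stop("v must be > 0", call. = FALSE)
  if (p$D <= 0) stop("D must be > 0", call. = FALSE)
  if (p$delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (p$d < 0) stop("d must be >= 0", call. = FALSE)
  for (f in c("alpha", "T", "d1")) {
    val <- p[[f]]
    if (length(val) != 1L) stop("parameter '", f, "' must be length 1", call. = FALSE)
    if (is.finite(val) && val < 0)
      stop(f, " must be >= 0 when supplied", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Kinesin recycling model parameters\n")
  cat(sprintf("  N     = %g motors (conserved pool)\n", x$N))
  cat(sprintf("  K     = %g /s (injection kinetic constant)\n", x$K))
  cat(sprintf("  v     = %g um/s (anterograde speed)\n", x$v))
  cat(sprintf("  D     = %g um^2/s (return diffusion)\n", x$D))
  cat(sprintf("  delta = %g um/motor (assembly increment)\n", x$delta))
  cat(sprintf("  d     = %g um/s (disassembly rate)\n", x$d))
  if (is.finite(x$alpha)) cat(sprintf("  alpha = %g per motor (tubulin binding)\n", x$alpha))
  if (is.finite(x$T)) cat(sprintf("  T     = %g um (tubulin pool as length)\n", x$T))
  if (is.finite(x$d1)) cat(sprintf("  d1    = %g (length-dependent disassembly)\n", x$d1))
  invisible(x)
}

# Canonical case labels; "case1".."case3" accepted as aliases everywhere.
.case_levels <- c("motor_limited", "tubulin_limited", "length_dependent_disassembly")

#' Normalize a model-case label
#'
#' The three rate laws are selected by a case label: `"motor_limited"`
#' (alias `"case1"`), `"tubulin_limited"` (alias `"case2"`) and
#' `"length_dependent_disassembly"` (alias `"case3"`).
#'
#' @param case case label or alias.
#' @return The canonical case string.
#' @export
normalize_case <- function(case) {
  stopifnot(is.character(case), length(case) == 1L)
  alias <- c(case1 = "motor_limited", case2 = "tubulin_limited",
             case3 = "length_dependent_disassembly")
  if (case %in% names(alias)) return(unname(alias[case]))
  if (case %in% .case_levels) return(case)
  stop("unknown model case '", case, "'; use one of ",
       paste(c(.case_levels, names(alias)), collapse = ", "), call. = FALSE)
}

#' Reference parameter presets
#'
#' The reference parameterization used throughout: N = 100 motors, K = 1/s,
#' D = 2.5 um^2/s, delta = 1.5e-3 um, d = 0.004 um/s, wild-type speed
#' v = 2.3 um/s. The `"case2"` preset adds the tubulin pool (T = 30 um,
#' alpha = 0.8e-4); the `"case3"` preset uses d = 0.002 um/s with
#' d1 = 0.1 * d.
#'
#' @param case `"case1"`, `"case2"`, `"case3"` (or the long case labels).
#' @param v anterograde speed override (um/s); default 2.3 (wild-type).
#'   The measured slow chimeric speed is 0.80 um/s.
#' @return A [model_params()] object.
#' @examples
#' lss_closed_form(preset_params("case1"), "case1")$L_ss  # ~12.47 um
#' @export
preset_params <- function(case = c("case1", "case2", "case3",
                                   "motor_limited", "tubulin_limited",
                                   "length_dependent_disassembly"),
                          v = 2.3) {
  case <- normalize_case(match.arg(case))
  switch(case,
    motor_limited = model_params(N = 100, K = 1, v = v, D = 2.5,
                                 delta = 1.5e-3, d = 0.004),
    tubulin_limited = model_params(N = 100, K = 1, v = v, D = 2.5,
                                   delta = 1.5e-3, d = 0.004,
                                   alpha = 0.8e-4, T = 30),
    length_dependent_disassembly = model_params(N = 100, K = 1, v = v, D = 2.5,
                                                delta = 1.5e-3, d = 0.002,
                                                d1 = 0.1 * 0.002)
  )
}

# Clone a parameter set with fields overridden (used by sweeps and curves).
override_params <- function(params, ...) {
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(params)) stop("unknown parameter '", nm, "'", call. = FALSE)
    params[[nm]] <- as.numeric(ov[[nm]])
  }
  validate_params(params)
  structure(params, class = "model_params")
}

# Check the extra parameters a case needs are present and finite.
check_case_params <- function(params, case) {
  case <- normalize_case(case)
  if (case == "tubulin_limited" &&
      (!is.finite(params$alpha) || !is.finite(params$T)))
    stop("tubulin-limited case requires finite alpha and T", call. = FALSE)
  if (case == "length_dependent_disassembly" && !is.finite(params$d1))
    stop("length-dependent disassembly case requires finite d1", call. = FALSE)
  case
}
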