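#' Default sweep grids over motor number and diffusion constant
#'
#' Eight log-spaced motor counts from 50 to 400 and ten evenly spaced
#' diffusion constants from 1 to 10 um^2/s — a physiological window around
#' the reference values N = 100, D = 2.5.
#'
#' @return Numeric vector of grid values.
#' @export
default_N_grid <- function() round(exp(seq(log(50), log(400), length.out = 8)))

#' @rdname default_N_grid
#' @export
default_D_grid <- function() seq(1, 10, length.out = 10)

#' Phase space of steady-state length and growth time over (N, D)
#'
#' Evaluates the closed-form steady state (and optionally the 95% growth
#' time from ODE simulation) over a grid of motor numbers and diffusion
#' constants, at a fast (wild-type) and a slow (chimeric) motor speed, and
#' the slow/fast length ratio map. Across the default grid the slow motor
#' always yields a mildly shorter cilium (ratio < 1) in all three cases.
#'
#' @inheritParams length_rate
#' @param N_values,D_values grid values (positive, non-empty).
#' @param v_fast,v_slow the two motor speeds (um/s), `v_slow < v_fast`.
#' @param growth if `TRUE`, also compute 95% growth-time maps by ODE
#'   simulation (slower); cells that do not converge are `NA`.
#' @param fraction growth-time fraction of `L_ss`.
#' @return An object of class `"sweep_grid"`: list with the grids, the
#'   matrices `L_ss_fast`, `L_ss_slow`, `ratio` (and `T_growth_fast`,
#'   `T_growth_slow` when `growth = TRUE`), logical `exists_fast`,
#'   `exists_slow`, and `case`. Matrix rows index `D_values`, columns
#'   `N_values`; cells without a steady state are `NA`.
#' @examples
#' ps <- phase_space(preset_params("case1"), "case1",
#'                   N_values = c(50, 100), D_values = c(1, 2.5),
#'                   growth = FALSE)
#' ps$ratio
#' @export
phase_space <- function(params, case, N_values = default_N_grid(),
                        D_values = default_D_grid(),
                        v_fast = 2.3, v_slow = 0.8,
                        growth = TRUE, fraction = 0.95) {
  case <- check_case_params(params, case)
  if (length(N_values) == 0L || length(D_values) == 0L)
    stop("N_values and D_values must be non-empty", call. = FALSE)
  if (any(N_values <= 0) || any(D_values <= 0))
    stop("grid values must be positive", call. = FALSE)
  if (!(v_slow < v_fast)) stop("v_slow must be < v_fast", call. = FALSE)

  dims <- c(length(D_values), length(N_values))
  dn <- list(D = as.character(D_values), N = as.character(N_values))
  mk <- function() matrix(NA_real_, dims[1], dims[2], dimnames = dn)
  L_fast <- mk(); L_slow <- mk()
  Tg_fast <- mk(); Tg_slow <- mk()
  ex_fast <- matrix(FALSE, dims[1], dims[2], dimnames = dn)
  ex_slow <- ex_fast

  cell <- function(p) {
    ss <- lss_closed_form(p, case)
    tg <- NA_real_
    if (ss$exists && growth) {
      t_end <- suggest_t_end(p, case)
      traj <- simulate_regeneration(p, case, L0 = 0, t_end = t_end,
                                    dt_out = max(1, t_end / 2000))
      if (isTRUE(attr(traj, "converged")))
        tg <- growth_time(traj, fraction)
    }
    list(L = ss$L_ss, exists = ss$exists, tg = tg)
  }

  for (i in seq_along(D_values)) {
    for (j in seq_along(N_values)) {
      pf <- override_params(params, N = N_values[j], D = D_values[i], v = v_fast)
      psl <- override_params(params, N = N_values[j], D = D_values[i], v = v_slow)
      cf <- cell(pf); cs <- cell(psl)
      if (cf$exists) { L_fast[i, j] <- cf$L; Tg_fast[i, j] <- cf$tg }
      if (cs$exists) { L_slow[i, j] <- cs$L; Tg_slow[i, j] <- cs$tg }
      ex_fast[i, j] <- cf$exists; ex_slow[i, j] <- cs$exists
    }
  }

  out <- list(N_values = N_values, D_values = D_values,
              v_fast = v_fast, v_slow = v_slow,
              L_ss_fast = L_fast, L_ss_slow = L_slow,
              ratio = L_slow / L_fast,
              exists_fast = ex_fast, exists_slow = ex_slow,
              case = case, params = params)
  if (growth) {
    out$T_growth_fast <- Tg_fast
    out$T_growth_slow <- Tg_slow
  }
  structure(out, class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Phase-space sweep (%s): %d D values x %d N values\n",
              x$case, length(x$D_values), length(x$N_values)))
  cat(sprintf("  speeds %.2f vs %.2f um/s; slow/fast L_ss ratio range: %.3f - %.3f\n",
              x$v_fast, x$v_slow,
              min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Long-format view of a sweep grid
#'
#' @param x a [phase_space()] result.
#' @param row.names,optional ignored (S3 signature).
#' @param ... ignored.
#' @return Data frame with columns `case`, `N`, `D`, `v`, `L_ss_um`,
#'   `T_growth_s`, `exists`.
#' @export
as.data.frame.sweep_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  grid <- expand.grid(D = x$D_values, N = x$N_values, KEEP.OUT.ATTRS = FALSE)
  one <- function(v, L, Tg, ex) {
    data.frame(case = x$case, N = grid$N, D = grid$D, v = v,
               L_ss_um = as.vector(L),
               T_growth_s = if (is.null(Tg)) NA_real_ else as.vector(Tg),
               exists = as.vector(ex))
  }
  rbind(one(x$v_fast, x$L_ss_fast, x$T_growth_fast, x$exists_fast),
        one(x$v_slow, x$L_ss_slow, x$T_growth_slow, x$exists_slow))
}

#' Heatmap of a sweep-grid matrix
#'
#' @param x a `sweep_grid`.
#' @param what which matrix to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_grid <- function(x, what = c("ratio", "L_ss_fast", "L_ss_slow"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(x = x$N_values, y = x$D_values, z = t(m),
                  col = grDevices::hcl.colors(24, "viridis"),
                  xlab = "motor number N", ylab = "diffusion D (um^2/s)",
                  main = what, ...)
  invisible(x)
}

#' Sensitivity regime of the steady-state length
#'
#' Log-log elasticities of `L_ss` with respect to the diffusion constant
#' (`e_D`) and the motor number (`e_N`), by central finite differences
#' with a relative step, and the label of the larger one: growth is
#' "diffusion-limited" when `e_D > e_N`, "motor-limited" when `e_N > e_D`,
#' "mixed" on a tie.
#'
#' @inheritParams length_rate
#' @param rel_step relative perturbation for the central difference.
#' @return List with `label`, `e_N`, `e_D`.
#' @export
limitation_regime <- function(params, case, rel_step = 0.01) {
  case <- check_case_params(params, case)
  ss <- lss_closed_form(params, case)
  if (!ss$exists)
    stop("no steady state at these parameters", call. = FALSE)
  perturb <- function(field, factor) {
    do.call(override_params,
            c(list(params), stats::setNames(list(params[[field]] * factor), field)))
  }
  elast <- function(field) {
    up <- lss_closed_form(perturb(field, 1 + rel_step), case)
    dn <- lss_closed_form(perturb(field, 1 - rel_step), case)
    if (!up$exists || !dn$exists)
      stop("steady state vanished under the perturbation of ", field, call. = FALSE)
    (log(up$L_ss) - log(dn$L_ss)) / (log(1 + rel_step) - log(1 - rel_step))
  }
  e_N <- elast("N")
  e_D <- elast("D")
  label <- if (isTRUE(all.equal(e_N, e_D))) "mixed"
           else if (e_D > e_N) "diffusion-limited" else "motor-limited"
  list(label = label, e_N = e_N, e_D = e_D)
}
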