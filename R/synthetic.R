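# Seed handling: run code under a fixed seed, restoring the caller's RNG
# state afterwards, so generators are bit-reproducible per seed without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic per-cell regeneration length measurements
#'
#' Emulates a fixed-timepoint regeneration assay: cells are deflagellated,
#' fixed at each timepoint, and ciliary length is measured in `n_cells`
#' cells per timepoint (reported as mean +/- SD). Each observation is the
#' deterministic model length at that time plus additive Gaussian
#' measurement noise, truncated at zero. The default noise SD of 1.3 um
#' matches the spread of steady-state length distributions of the kind
#' "12.6 +/- 1.3 um (n = 50)".
#'
#' @inheritParams length_rate
#' @param timepoints sampling times (s), sorted ascending; default 0 to
#'   120 min every 10 min.
#' @param n_cells cells measured per timepoint (default 50).
#' @param noise_sd measurement SD (um), >= 0.
#' @param seed integer seed; same seed gives bit-identical data.
#' @return An object of class `"synthetic_regen"`: a data frame with
#'   columns `t_s`, `cell_id`, `L_um`, and attributes `true_params`,
#'   `case`, `noise_sd`, `n_cells`, `seed`, `L_model` (noise-free lengths
#'   per timepoint).
#' @export
generate_regen <- function(params, case = "case1",
                           timepoints = seq(0, 7200, by = 600),
                           n_cells = 50, noise_sd = 1.3, seed = 1L) {
  case <- check_case_params(params, case)
  if (is.unsorted(timepoints) || any(timepoints < 0))
    stop("timepoints must be sorted ascending and >= 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)

  tp <- unique(timepoints)
  if (length(tp) != length(timepoints))
    stop("timepoints must be distinct", call. = FALSE)
  f <- length_rate_fn(params, case)
  times <- if (tp[1L] == 0) tp else c(0, tp)
  L_model <- rk45_integrate(f, 0, times)
  if (tp[1L] != 0) L_model <- L_model[-1L]

  obs <- with_seed(seed, {
    vapply(L_model, function(mu) pmax(stats::rnorm(n_cells, mu, noise_sd), 0),
           numeric(n_cells))
  })
  dat <- data.frame(
    t_s = rep(tp, each = n_cells),
    cell_id = rep(seq_len(n_cells), times = length(tp)),
    L_um = as.vector(obs)
  )
  structure(dat, class = c("synthetic_regen", "data.frame"),
            true_params = params, case = case, noise_sd = noise_sd,
            n_cells = n_cells, seed = seed,
            L_model = stats::setNames(L_model, tp))
}

#' @export
print.synthetic_regen <- function(x, ...) {
  tp <- unique(x$t_s)
  cat(sprintf("Synthetic regeneration dataset: %d timepoints x %d cells (seed %d)\n",
              length(tp), attr(x, "n_cells"), attr(x, "seed")))
  cat(sprintf("  noise SD %.2f um; final mean length %.2f um\n",
              attr(x, "noise_sd"), mean(x$L_um[x$t_s == max(tp)])))
  invisible(x)
}

#' Synthetic injection-rate observations in arbitrary units
#'
#' Emulates fluorescence-based IFT injection measurements at given ciliary
#' lengths: the model injection rate scaled by an unknown multiplicative
#' gain (au per motor/s) with multiplicative lognormal noise of mean 1 and
#' the stated coefficient of variation. Only the composite `gain * N` and
#' the base delay `1/K` are identifiable from such data.
#'
#' @inheritParams length_rate
#' @param lengths observed ciliary lengths (um), >= 0.
#' @param gain arbitrary-units gain per motor/s, > 0.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return An object of class `"synthetic_injection"`: a data frame with
#'   columns `L_um`, `J_au`, and attributes `true_params`, `case`,
#'   `gain`, `noise_cv`, `seed`.
#' @export
generate_injection <- function(params, case = "case1",
                               lengths = seq(1, 12, length.out = 100),
                               gain = 100, noise_cv = 0.15, seed = 1L) {
  case <- check_case_params(params, case)
  if (any(lengths < 0)) stop("lengths must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  J <- injection_rate(params, lengths)
  # lognormal factor with mean exactly 1 and sd ~ noise_cv
  sdlog <- sqrt(log(1 + noise_cv^2))
  fac <- if (noise_cv == 0) rep(1, length(lengths)) else with_seed(seed, {
    stats::rlnorm(length(lengths), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  dat <- data.frame(L_um = lengths, J_au = gain * J * fac)
  structure(dat, class = c("synthetic_injection", "data.frame"),
            true_params = params, case = case, gain = gain,
            noise_cv = noise_cv, seed = seed)
}

#' @export
print.synthetic_injection <- function(x, ...) {
  cat(sprintf("Synthetic injection dataset: %d observations (seed %d)\n",
              nrow(x), attr(x, "seed")))
  cat(sprintf("  gain %.3g au per motor/s (unknown to the fitter), CV %.2f\n",
              attr(x, "gain"), attr(x, "noise_cv")))
  invisible(x)
}
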