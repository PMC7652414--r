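# Flat key-value configuration and tabular export helpers. Configs use the
# Debian-control "key: value" format (read.dcf / write.dcf from base R);
# manifests are JSON via jsonlite.

.param_keys <- c("N", "K", "v", "D", "delta", "d", "alpha", "T", "d1")

#' Read a model configuration file
#'
#' Flat `key: value` file with keys among `N, K, v, D, delta, d, alpha, T,
#' d1, case` (numeric fields parsed as numbers). Unknown keys are
#' rejected.
#'
#' @param path file path.
#' @return Named list with a `params` ([model_params()]) element and a
#'   `case` string (default `"case1"` when absent).
#' @export
read_model_config <- function(path) {
  raw <- read.dcf(path)
  if (nrow(raw) != 1L) stop("config must contain a single record", call. = FALSE)
  vals <- stats::setNames(as.list(raw[1L, ]), colnames(raw))
  unknown <- setdiff(names(vals), c(.param_keys, "case"))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  case <- if ("case" %in% names(vals)) normalize_case(vals$case) else "motor_limited"
  num <- lapply(vals[intersect(names(vals), .param_keys)], function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (is.na(y)) stop("non-numeric parameter value: ", x, call. = FALSE)
    y
  })
  params <- do.call(model_params, num)
  list(params = params, case = case)
}

#' Write a model configuration file
#'
#' @param params a [model_params()] object.
#' @param case model case label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, case, path) {
  case <- check_case_params(params, case)
  fields <- params[.param_keys]
  fields <- fields[vapply(fields, is.finite, logical(1))]
  m <- matrix(c(vapply(fields, format, character(1), digits = 15), case),
              nrow = 1,
              dimnames = list(NULL, c(names(fields), "case")))
  write.dcf(m, path)
  invisible(path)
}

#' Export a trajectory as delimiter-separated text with a JSON manifest
#'
#' Writes columns `t_s, L_um, J_per_s, n_ballistic, n_diffusive, n_free`
#' as TSV, plus `<path>.manifest.json` recording the parameters, case,
#' solver settings and convergence flag.
#'
#' @param traj a [simulate_regeneration()] trajectory.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cilium_trajectory"))
  tab <- data.frame(t_s = traj$t, L_um = traj$L, J_per_s = traj$J,
                    n_ballistic = traj$n_ballistic,
                    n_diffusive = traj$n_diffusive,
                    n_free = traj$n_free)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    type = "cilium_trajectory",
    params = unclass(attr(traj, "params")),
    case = attr(traj, "case"),
    L_ss_um = attr(traj, "L_ss"),
    converged = attr(traj, "converged"),
    solver = attr(traj, "solver"),
    package_version = as.character(utils::packageVersion("ciliaflux"))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Export a phase-space sweep as long-format TSV
#'
#' @param grid a [phase_space()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_sweep <- function(grid, path) {
  stopifnot(inherits(grid, "sweep_grid"))
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a synthetic dataset with a metadata sidecar
#'
#' Regeneration datasets get columns `t_s, cell_id, L_um`; injection
#' datasets `L_um, J_au`. The sidecar `<path>.manifest.json` records the
#' ground-truth parameters, case, noise settings and seed.
#'
#' @param dataset a [generate_regen()] or [generate_injection()] dataset.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, c("synthetic_regen", "synthetic_injection")))
  utils::write.table(as.data.frame(dataset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    type = class(dataset)[1L],
    true_params = unclass(attr(dataset, "true_params")),
    case = attr(dataset, "case"),
    seed = attr(dataset, "seed"),
    package_version = as.character(utils::packageVersion("ciliaflux"))
  )
  if (inherits(dataset, "synthetic_regen")) {
    meta$noise_sd <- attr(dataset, "noise_sd")
    meta$n_cells <- attr(dataset, "n_cells")
  } else {
    meta$gain <- attr(dataset, "gain")
    meta$noise_cv <- attr(dataset, "noise_cv")
  }
  jsonlite::write_json(meta, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
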