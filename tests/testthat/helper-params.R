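# Shared fixtures: reference parameter sets and random parameter draws.

ref1 <- function(v = 2.3) preset_params("case1", v = v)
ref2 <- function(v = 2.3) preset_params("case2", v = v)
ref3 <- function(v = 2.3) preset_params("case3", v = v)

all_cases <- c("motor_limited", "tubulin_limited", "length_dependent_disassembly")

# Random parameter draw in a physiological window around the reference
# values; extra fields filled so every case is evaluable.
draw_params <- function() {
  model_params(
    N = runif(1, 50, 400),
    K = runif(1, 0.5, 2),
    v = runif(1, 0.5, 3),
    D = runif(1, 1, 10),
    delta = runif(1, 1e-3, 2e-3),
    d = runif(1, 0.002, 0.006),
    alpha = runif(1, 0.4e-4, 1.6e-4),
    T = runif(1, 20, 40),
    d1 = runif(1, 1e-4, 4e-4)
  )
}

# Independent flux-balance oracle: solve Eq-1-style implicit relation
# J = K (N - J L/v - J L^2/(2D)) numerically for J by root bracketing.
oracle_injection <- function(params, L) {
  g <- function(J) params$K * (params$N - J * L / params$v -
                                 J * L^2 / (2 * params$D)) - J
  stats::uniroot(g, c(0, params$K * params$N), tol = 1e-14)$root
}
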