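test_that("injection rate: boundary value, steady-state value, monotonicity", {
  p <- ref1()
  # empty cilium: both transit terms vanish, J = K*N
  expect_equal(injection_rate(p, 0), p$K * p$N)

  # at the case-1 steady state the flux balances disassembly: J = d/delta
  Lss <- lss_closed_form(p, "case1")$L_ss
  expect_equal(injection_rate(p, Lss), p$d / p$delta, tolerance = 1e-10)

  # strictly decreasing in L
  L <- seq(0, 30, by = 0.5)
  expect_true(all(diff(injection_rate(p, L)) < 0))
  expect_gt(injection_rate(p, 6), injection_rate(p, 12))

  # strictly increasing in each of N, v, D, K
  for (f in c("N", "v", "D", "K")) {
    up <- p; up[[f]] <- up[[f]] * 1.1
    expect_gt(injection_rate(up, 8), injection_rate(p, 8))
  }

  expect_error(injection_rate(p, -1), "L must be")
})

test_that("flux-balance identity: implicit relation matches closed form", {
  set.seed(101)
  for (i in 1:200) {
    p <- draw_params()
    L <- runif(1, 0, 25)
    expect_equal(injection_rate(p, L), oracle_injection(p, L),
                 tolerance = 1e-10)
  }
})

test_that("motor partition sums to N, matches quasi-steady formulas", {
  p <- ref1()
  # empty cilium: all motors free at the base
  mp0 <- motor_partition(p, 0)
  expect_equal(unlist(mp0[c("n_ballistic", "n_diffusive", "n_free")]),
               c(n_ballistic = 0, n_diffusive = 0, n_free = p$N))

  # at the case-1 steady state (values derived from J = d/delta)
  Lss <- lss_closed_form(p, "case1")$L_ss
  mp <- motor_partition(p, Lss)
  J <- p$d / p$delta
  expect_equal(mp$n_ballistic, J * Lss / p$v, tolerance = 1e-10)
  expect_equal(mp$n_diffusive, J * Lss^2 / (2 * p$D), tolerance = 1e-10)
  expect_equal(mp$n_free, J / p$K, tolerance = 1e-10)
  expect_equal(mp$n_ballistic, 14.45, tolerance = 1e-3)
  expect_equal(mp$n_diffusive, 82.88, tolerance = 1e-3)
  expect_equal(mp$n_free, 2.667, tolerance = 1e-3)

  # conservation over random draws
  set.seed(202)
  for (i in 1:1000) {
    p <- draw_params()
    mp <- motor_partition(p, runif(1, 0, 25))
    expect_equal(mp$n_ballistic + mp$n_diffusive + mp$n_free, p$N,
                 tolerance = 1e-10)
    expect_true(all(unlist(mp[-1]) >= 0))
  }

  expect_error(motor_partition(p, -0.1), "L must be")
})

test_that("growing short cilium holds more motors than a steady-state one", {
  # fractional ballistic+diffusive share is larger (and basal share smaller)
  # at 0.3*L_ss than at L_ss
  p <- ref1()
  Lss <- lss_closed_form(p, "case1")$L_ss
  short <- motor_partition(p, 0.3 * Lss)
  full <- motor_partition(p, Lss)
  expect_gt(short$n_free / p$N, full$n_free / p$N)
  expect_lt(short$n_ballistic + short$n_diffusive,
            full$n_ballistic + full$n_diffusive)
  # injection is higher in the short cilium, hence more motors at the base
  expect_gt(injection_rate(p, 0.3 * Lss), injection_rate(p, Lss))
})

test_that("length rate laws: direct substitution, steady-state zero, signs", {
  p <- ref1()
  # case 1 at L=0: delta*K*N - d
  expect_equal(length_rate(p, "case1", 0), p$delta * p$K * p$N - p$d)
  expect_equal(length_rate(p, "case1", 0), 0.146)

  # zero at each case's closed-form steady state
  for (case in all_cases) {
    pc <- preset_params(case)
    Lss <- lss_closed_form(pc, case)$L_ss
    expect_lt(abs(length_rate(pc, case, Lss)), 1e-9)
  }

  # disassembly dominating an empty cilium: no growth possible
  p_dead <- model_params(N = 10, K = 1, v = 2.3, D = 2.5,
                         delta = 1e-4, d = 0.01)
  expect_lt(length_rate(p_dead, "case1", 0), 0)

  # tubulin-limited law rejects lengths beyond the pool
  expect_error(length_rate(ref2(), "case2", 31), "tubulin pool")
})

test_that("residence times: hand arithmetic and degenerate input", {
  rt <- residence_times(12, 2.3, 2)
  expect_equal(rt$t_ballistic, 12 / 2.3)
  expect_equal(rt$t_ballistic, 5.217, tolerance = 1e-4)
  expect_equal(rt$t_diffusive, 36)
  expect_equal(rt$t_total, rt$t_ballistic + rt$t_diffusive)

  rt0 <- residence_times(0, 1, 1)
  expect_equal(unlist(rt0), c(t_ballistic = 0, t_diffusive = 0, t_total = 0))

  expect_error(residence_times(5, 0, 1), "v must be")
  expect_error(residence_times(5, 1, -2), "D must be")
})

test_that("IFT mass relation M = L*J/v", {
  expect_equal(ift_mass(12, 2.3, 0), 0)
  expect_equal(ift_mass(10, 2, 4), 2 * ift_mass(10, 2, 2))
  # fold-change arithmetic: L ratio 0.85, J ratio 1/2.2, v ratio 1/2.8
  # leaves the ciliary IFT mass nearly unchanged
  ratio <- ift_mass(0.85, 1 / 2.8, 1 / 2.2) / ift_mass(1, 1, 1)
  expect_equal(ratio, 0.85 * 2.8 / 2.2, tolerance = 1e-12)
  expect_equal(ratio, 1.08, tolerance = 0.005)
  expect_error(ift_mass(1, 0, 1), "v must be")
  expect_error(ift_mass(-1, 1, 1), ">= 0")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(model_params(N = -5), "N must be")
  expect_error(model_params(K = 0), "K must be")
  expect_error(model_params(v = 0), "v must be")
  expect_error(model_params(D = -1), "D must be")
  expect_error(model_params(delta = -1e-3), "delta must be")
  expect_error(model_params(alpha = -1), "alpha must be")
  # extended-case parameters must be present when the case needs them
  expect_error(length_rate(ref1(), "case2", 1), "alpha and T")
  expect_error(length_rate(ref1(), "case3", 1), "d1")
  expect_error(normalize_case("case4"), "unknown model case")
})
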