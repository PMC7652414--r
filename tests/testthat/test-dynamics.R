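test_that("regeneration converges to the closed-form steady state", {
  p <- ref1()
  traj <- simulate_regeneration(p, "case1", L0 = 0, t_end = 3 * 3600,
                                dt_out = 10)
  expect_equal(traj$L[1], 0)
  Lss <- lss_closed_form(p, "case1")$L_ss
  expect_lt(abs(traj$L[nrow(traj)] - Lss) / Lss, 0.01)
  expect_true(attr(traj, "converged"))
  # strictly increasing time grid, non-negative and monotone growth
  expect_true(all(diff(traj$t) > 0))
  expect_true(all(traj$L >= 0))
  expect_true(all(diff(traj$L) >= -1e-12))
})

test_that("trajectory samples are internally consistent with the algebra", {
  p <- ref1(0.8)
  traj <- simulate_regeneration(p, "case1", t_end = 3600, dt_out = 60)
  expect_equal(traj$J, injection_rate(p, traj$L), tolerance = 1e-12)
  mp <- motor_partition(p, traj$L)
  expect_equal(traj$n_ballistic, mp$n_ballistic, tolerance = 1e-12)
  # conservation of the motor pool at every output time
  expect_equal(traj$n_ballistic + traj$n_diffusive + traj$n_free,
               rep(p$N, nrow(traj)), tolerance = 1e-10)
})

test_that("length stays clamped at zero when disassembly dominates", {
  p <- model_params(N = 10, K = 1, v = 2.3, D = 2.5, delta = 1e-4, d = 0.01)
  traj <- simulate_regeneration(p, "case1", L0 = 0, t_end = 600, dt_out = 10)
  expect_true(all(traj$L == 0))
})

test_that("adaptive integrator agrees with a fixed-step RK4 oracle", {
  for (case in all_cases) {
    p <- preset_params(case)
    times <- seq(0, 1800, by = 60)
    f <- ciliaflux:::length_rate_fn(p, case)
    L_adaptive <- ciliaflux:::rk45_integrate(f, 0, times)
    L_rk4 <- ciliaflux:::rk4_fixed(f, 0, times, dt = 0.01)
    expect_lt(max(abs(L_adaptive - L_rk4)), 1e-4)
  }
})

test_that("ODE endpoint matches the closed form across random draws", {
  set.seed(404)
  for (case in all_cases) {
    n_done <- 0
    while (n_done < 25) {
      p <- draw_params()
      ss <- lss_closed_form(p, case)
      if (!ss$exists) next
      t_end <- suggest_t_end(p, case)
      traj <- simulate_regeneration(p, case, t_end = t_end,
                                    dt_out = max(1, t_end / 400))
      expect_lt(abs(traj$L[nrow(traj)] - ss$L_ss), 0.01 * ss$L_ss)
      n_done <- n_done + 1
    }
  }
})

test_that("growth time: interpolation, monotonicity, error handling", {
  p <- ref1()
  traj <- simulate_regeneration(p, "case1", t_end = 3 * 3600, dt_out = 10)
  t50 <- growth_time(traj, 0.5)
  t95 <- growth_time(traj, 0.95)
  expect_lt(t50, t95)
  # a tiny fraction is reached almost immediately from L0 = 0
  expect_lt(growth_time(traj, 1e-4), 1)
  # interpolated crossing really brackets the target
  Lss <- attr(traj, "L_ss")
  i <- findInterval(t95, traj$t)
  expect_true(traj$L[i] <= 0.95 * Lss && traj$L[i + 1] >= 0.95 * Lss)

  short <- simulate_regeneration(p, "case1", t_end = 60, dt_out = 1)
  expect_false(attr(short, "converged"))
  expect_error(growth_time(short, 0.95), "not converged")
  expect_error(growth_time(traj, 1.2), "fraction")
})

test_that("growth timescales are similar for wild-type and slow motors", {
  # the ~3x slower motor changes the 95% growth time by less than 50%
  t95 <- vapply(c(2.3, 0.8), function(v) {
    traj <- simulate_regeneration(ref1(v), "case1", t_end = 3 * 3600,
                                  dt_out = 10)
    growth_time(traj, 0.95)
  }, numeric(1))
  expect_lt(abs(t95[2] - t95[1]) / t95[1], 0.5)
})

test_that("injection-vs-length curves: monotone, slow motor lies below", {
  traj_wt <- simulate_regeneration(ref1(2.3), "case1", t_end = 3 * 3600,
                                   dt_out = 10)
  traj_slow <- simulate_regeneration(ref1(0.8), "case1", t_end = 3 * 3600,
                                     dt_out = 10)
  cw <- injection_vs_length(traj_wt)
  cs <- injection_vs_length(traj_slow)
  # J = K*N at L = 0 for both speeds
  expect_equal(cw$J[1], 100)
  expect_equal(cs$J[1], 100)
  expect_true(all(diff(cw$J) <= 0))
  # matched lengths: slow-motor curve below wild-type for L > 0
  L_grid <- seq(0.5, 10, by = 0.5)
  expect_true(all(injection_rate(ref1(0.8), L_grid) <
                    injection_rate(ref1(2.3), L_grid)))
  # pointwise consistency with the flux-balance formula
  expect_equal(cw$J, injection_rate(ref1(2.3), cw$L), tolerance = 1e-12)
})

test_that("slow motors redistribute toward the ballistic state in short cilia", {
  p_wt <- ref1(2.3)
  p_slow <- ref1(0.8)
  L_short <- 0.3 * lss_closed_form(p_wt, "case1")$L_ss
  frac_ball <- function(p) {
    mp <- motor_partition(p, L_short)
    mp$n_ballistic / p$N
  }
  expect_gt(frac_ball(p_slow), frac_ball(p_wt))
  # and fewer motors wait at the base in the slow mutant
  expect_lt(motor_partition(p_slow, L_short)$n_free,
            motor_partition(p_wt, L_short)$n_free)
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_regeneration(ref1(), "case1", L0 = -1), "L0")
  expect_error(simulate_regeneration(ref1(), "case1", t_end = 0), "t_end")
  expect_error(simulate_regeneration(ref2(), "case2", L0 = 40), "tubulin")
})
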