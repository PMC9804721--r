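test_that("integration preserves equilibria and relaxes to the chemostat", {
  # started at a stable equilibrium, the state stays there
  eq <- chemostat_equilibria(20, cp_std, chp_std) |>
    dplyr::filter(equilibrium == "coexistence")
  tr <- simulate_dynamics("chemostat", 20, c(eq$R_hat, eq$C_hat), 200,
                          cp_std, chp_std, dt = 1)
  expect_lt(max(abs(tr$R - eq$R_hat)), 1e-8)
  expect_lt(max(abs(tr$C - eq$C_hat)), 1e-8)
  # consumer-free chemostat relaxes monotonically to S
  tr <- simulate_dynamics("chemostat", 25, c(0.2, 0), 50, cp_std, chp_std)
  expect_true(all(diff(tr$R) > -1e-12))
  expect_equal(tr$R[nrow(tr)], chp_std$S, tolerance = 1e-8)
  expect_true(all(tr$C == 0))
  expect_error(simulate_dynamics("chemostat", 25, c(-1, 0), 10, cp_std,
                                 chp_std), "nonnegative")
})

test_that("past the Hopf point orbits settle on a cycle, not the focus", {
  set.seed(7)
  tr <- simulate_dynamics("logistic", 25, c(runif(1, 0.2, 1), runif(1, 0.2, 1)),
                          3000, cp_std, rt_std, dt = 0.25)
  late <- tr[tr$time > 2500, ]
  eq <- logistic_equilibria(25, cp_std, rt_std) |>
    dplyr::filter(equilibrium == "coexistence")
  # bounded orbit of positive amplitude enclosing the unstable equilibrium
  expect_gt(max(late$R) - min(late$R), 0.5)
  expect_true(min(late$R) < eq$R_hat && eq$R_hat < max(late$R))
  expect_true(min(late$C) < eq$C_hat && eq$C_hat < max(late$C))
  expect_true(all(late$R >= 0 & late$C >= 0))
})

test_that("cycle summaries collapse to the point attractor when stable", {
  eq <- logistic_equilibria(25, cp_r2, rt_std) |>
    dplyr::filter(equilibrium == "coexistence")
  cs <- cycle_summary("logistic", 25, cp_r2, rt_std,
                      transient = 1500, window = 300)
  expect_true(cs$converged)
  expect_lt(abs(cs$R_min - eq$R_hat), 1e-6)
  expect_lt(abs(cs$R_max - eq$R_hat), 1e-6)
  expect_lt(abs(cs$C_max - eq$C_hat), 1e-6)
  expect_true(is.na(cs$period))
  expect_error(cycle_summary("logistic", 42, cp_std, rt_std),
               "no coexistence")
})

test_that("cycle amplitude grows with distance beyond the Hopf point", {
  h <- hopf_points(seq(0, 40, by = 0.05), cp_std, rt_std)
  amp <- function(T, transient = 2000) {
    cs <- cycle_summary("logistic", T, cp_std, rt_std,
                        transient = transient, window = 400)
    cs$R_max - cs$R_min
  }
  a_in <- amp(h[1] - 0.4)           # just inside: spiral to equilibrium
  a_1 <- amp(h[1] + 0.4)            # just beyond: small cycle
  a_2 <- amp(h[1] + 1.5)            # further: larger cycle (supercritical)
  expect_lt(a_in, 1e-5)
  expect_gt(a_1, 1e-3)
  expect_gt(a_2, a_1)
  # amplitudes bracket the unstable equilibrium
  eq <- logistic_equilibria(h[1] + 1.5, cp_std, rt_std) |>
    dplyr::filter(equilibrium == "coexistence")
  cs <- cycle_summary("logistic", h[1] + 1.5, cp_std, rt_std,
                      transient = 2000, window = 400)
  expect_true(cs$R_min < eq$R_hat && eq$R_hat < cs$R_max)
})

test_that("eigenvalue-predicted stability matches simulated behaviour", {
  probes <- list(chemostat = list(params = chp_std, T = c(9, 15, 25, 30.5, 33)),
                 logistic = list(params = rt_std, T = c(12.5, 14, 22, 30, 31.5)))
  for (model in names(probes)) {
    p <- probes[[model]]
    for (T in p$T) {
      eqs <- if (model == "chemostat") chemostat_equilibria(T, cp_std, p$params)
             else logistic_equilibria(T, cp_std, p$params)
      stable <- eqs[eqs$stable, ]
      stable <- stable[which.max(stable$R_hat + stable$C_hat), ]
      has_cycle <- nrow(stable) == 0
      if (has_cycle) next  # cycle regime covered elsewhere
      tr <- simulate_dynamics(model, T, c(0.3, 0.2), 1500, cp_std, p$params,
                              dt = 2)
      fin <- tr[nrow(tr), ]
      expect_lt(abs(fin$R - stable$R_hat), 1e-5)
      expect_lt(abs(fin$C - stable$C_hat), 1e-5)
    }
  }
})

test_that("turnover equals respiration along any coexistence branch", {
  T <- seq(11, 30, by = 0.5)
  for (setup in list(list(chp_std, "chemostat"), list(rt_std, "logistic"))) {
    to <- consumer_turnover(T, cp_std, setup[[1]], setup[[2]])
    ok <- !is.na(to)
    expect_gt(sum(ok), 10)
    expect_equal(to[ok], respiration(T[ok], cp_std), tolerance = 1e-14)
    # lowest at the branch's cold end, then increasing with warming
    expect_equal(which.min(to[ok]), 1L)
    expect_true(all(diff(to[ok]) > 0))
  }
  expect_true(is.na(consumer_turnover(40, cp_std, chp_std, "chemostat")))
})
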