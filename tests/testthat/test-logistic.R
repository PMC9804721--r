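test_that("logistic RHS honours the sign-constrained density dependence", {
  expect_equal(logistic_rhs(c(0, 3), 25, cp_std, rt_std)[["dR"]], 0)
  # under thermal stress (r < 0) a consumer-free resource declines;
  # density dependence never rescues it
  expect_lt(resource_growth(42, rt_std, cp_std), 0)
  for (R in c(0.01, 0.5, 2))
    expect_lt(logistic_rhs(c(R, 0), 42, cp_std, rt_std)[["dR"]], 0)
  # consumer-free resource is at rest at K(T)
  K25 <- carrying_capacity(25, rt_std, cp_std)
  expect_lt(abs(logistic_rhs(c(K25, 0), 25, cp_std, rt_std)[["dR"]]), 1e-10)
  expect_error(logistic_rhs(c(1, -1), 25, cp_std, rt_std), "nonnegative")
})

test_that("logistic equilibria: three states with closed-form coexistence", {
  # r <= 0: only the trivial state, stable
  eq <- logistic_equilibria(42, cp_std, rt_std)
  expect_identical(eq$equilibrium, "trivial")
  expect_true(eq$stable)
  # efficient consumer at T = 25: coexistence exists but is unstable
  # (inside the limit-cycle region)
  eq <- logistic_equilibria(25, cp_std, rt_std)
  expect_setequal(eq$equilibrium, c("trivial", "resource_only", "coexistence"))
  co <- eq[eq$equilibrium == "coexistence", ]
  expect_equal(co$R_hat, 0.26178854, tolerance = 1e-7)
  expect_equal(co$C_hat, 0.57758294, tolerance = 1e-7)
  expect_false(co$stable)
  expect_gt(co$eig_im, 0)  # unstable focus
  # prudent consumer: same temperature, stable coexistence
  co2 <- logistic_equilibria(25, cp_r2, rt_std) |>
    dplyr::filter(equilibrium == "coexistence")
  expect_equal(co2$R_hat, 1.04715416, tolerance = 1e-7)
  expect_equal(co2$C_hat, 1.11376669, tolerance = 1e-7)
  expect_true(co2$stable)
  # negative K is never listed as an equilibrium
  eq42 <- logistic_equilibria(42, cp_std, rt_std)
  expect_false("resource_only" %in% eq42$equilibrium)
})

test_that("RHS residuals vanish at every reported equilibrium", {
  for (T in seq(1, 39, by = 2)) {
    eq <- logistic_equilibria(T, cp_std, rt_std)
    for (i in seq_len(nrow(eq)))
      expect_lt(max(abs(logistic_rhs(c(eq$R_hat[i], eq$C_hat[i]), T,
                                     cp_std, rt_std))), 1e-10)
  }
})

test_that("Hopf points match the closed-form enrichment threshold", {
  # closed-form oracle: trace is zero exactly where
  # K(T) = R0 ((1-d) Imax + m)/((1-d) Imax - m)
  oracle <- function(T, cp) {
    a <- (1 - cp$delta) * max_ingestion(T, cp)
    m <- respiration(T, cp)
    v <- carrying_capacity(T, rt_std, cp) - cp$R_0 * (a + m) / (a - m)
    ifelse(a <= m, NA_real_, v)
  }
  h <- hopf_points(seq(0, 40, by = 0.05), cp_std, rt_std)
  expect_length(h, 2)
  expect_equal(h, c(16.01495496, 28.87606769), tolerance = 1e-7)
  o1 <- uniroot(oracle, c(13, 25), cp = cp_std, tol = 1e-12)$root
  o2 <- uniroot(oracle, c(25, 31), cp = cp_std, tol = 1e-12)$root
  expect_lt(max(abs(h - c(o1, o2))), 1e-6)
  # at each Hopf point the finite-difference trace is ~0, determinant > 0
  for (T in h) {
    eq <- logistic_equilibria(T, cp_std, rt_std) |>
      dplyr::filter(equilibrium == "coexistence")
    J <- numeric_jacobian(function(s) logistic_rhs(s, T, cp_std, rt_std),
                          c(eq$R_hat, eq$C_hat))
    expect_lt(abs(J[1, 1] + J[2, 2]), 1e-6)
    expect_gt(det(J), 0)
  }
  # no limit cycles for the prudent consumers
  expect_length(hopf_points(seq(0, 40, by = 0.05), cp_r1, rt_std), 0)
  expect_length(hopf_points(seq(0, 40, by = 0.05), cp_r2, rt_std), 0)
})

test_that("branch scan detects both transcritical families", {
  br <- logistic_branch_scan(seq(0, 40, by = 0.05), cp_r1, rt_std)
  bif <- bifurcations(br)
  tc <- sort(bif$T[bif$type == "transcritical"])
  expect_length(tc, 4)
  # trivial <-> resource-only at the zeros of r(T)
  expect_equal(tc[c(1, 4)], c(4.314717, 38.653224), tolerance = 1e-5)
  # resource-only <-> coexistence where K(T) = R*(T)
  expect_equal(tc[c(2, 3)], c(13.722298, 29.901331), tolerance = 1e-5)
  expect_length(bif$T[bif$type == "hopf"], 0)
  # coexistence strictly inside the resource-only interval
  co <- tidy(br) |> dplyr::filter(equilibrium == "coexistence")
  expect_true(min(co$T) > tc[1] && max(co$T) < tc[4])
  # approaching the warm coexistence boundary, R_hat rises toward K(T)
  edge <- co[co$T > 28, ]
  expect_true(all(diff(edge$R_hat) > 0))
  expect_lt(1 - max(edge$R_hat) / edge$K_T[which.max(edge$T)], 0.1)
})

test_that("a narrow-niched resource imposes Liebig-style limits", {
  # resource fundamental niche shrunk inside the consumer's saturated niche
  rt_narrow <- resource_traits(beta_r = 20)
  rz <- c(uniroot(function(T) resource_growth(T, rt_narrow, cp_std),
                  c(10, 25), tol = 1e-10)$root,
          uniroot(function(T) resource_growth(T, rt_narrow, cp_std),
                  c(25, 35), tol = 1e-10)$root)
  sat <- thermal_limits(Inf, cp_std)
  expect_true(rz[1] > sat$T_min && rz[2] < sat$T_max)
  lim <- realized_limits(0, cp_std, rt_narrow)
  # coexistence confined inside the resource's own thermal niche,
  # well inside the consumer's physiological limits
  expect_true(lim["T_min"] > rz[1] && lim["T_max"] < rz[2])
  expect_gt(lim["T_min"], sat$T_min + 2)
  expect_lt(lim["T_max"], sat$T_max - 2)
})
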