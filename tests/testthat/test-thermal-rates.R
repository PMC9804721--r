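test_that("respiration follows the exponential-plus-offset form", {
  expect_equal(respiration(0, cp_std), 0.06)
  expect_equal(respiration(25, cp_std), 0.01 * exp(2.5) + 0.05)
  expect_equal(respiration(25, cp_std), 0.1718249396, tolerance = 1e-9)
  # offset is the cold-limit floor
  expect_equal(respiration(-1e3, cp_std), cp_std$m_c)
  # strictly increasing and positive on a fine grid
  v <- respiration(seq(-50, 60, by = 0.1), cp_std)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))
})

test_that("maximum ingestion is unimodal, symmetric, and peaks at T_I", {
  expect_equal(max_ingestion(cp_std$T_I, cp_std), 1)
  x <- c(0.5, 3, 11.7)
  expect_equal(max_ingestion(cp_std$T_I + x, cp_std),
               max_ingestion(cp_std$T_I - x, cp_std))
  # half-width: Imax = 1/2 at T_I +- sqrt(beta log 2)
  hw <- sqrt(150 * log(2))
  expect_equal(max_ingestion(25 + hw, cp_std), 0.5, tolerance = 1e-12)
  expect_equal(max_ingestion(25 - hw, cp_std), 0.5, tolerance = 1e-12)
  # single interior maximum: discrete derivative changes sign exactly once
  v <- max_ingestion(seq(0, 50, by = 0.05), cp_std)
  expect_equal(sum(diff(sign(diff(v))) != 0), 1L)
  expect_true(all(v > 0 & v <= 1))
})

test_that("functional response saturates Michaelis-Menten style", {
  expect_equal(functional_response(0, 17, cp_std), 0)
  expect_equal(functional_response(Inf, cp_std$T_I, cp_std), 1)
  expect_error(functional_response(-0.1, 25, cp_std), "R must be")
  # half-saturation identity for random (T, params) draws
  set.seed(11)
  for (i in 1:100) {
    cp <- consumer_params(T_I = runif(1, 10, 35), beta = runif(1, 50, 400),
                          R_0 = runif(1, 0.1, 5))
    T <- runif(1, -5, 45)
    expect_equal(functional_response(cp$R_0, T, cp),
                 max_ingestion(T, cp) / 2, tolerance = 1e-14)
  }
  # strictly increasing in R at fixed T
  v <- functional_response(seq(0, 20, by = 0.05), 22, cp_std)
  expect_true(all(diff(v) > 0))
})

test_that("per-capita consumer growth is assimilation minus respiration", {
  expect_equal(consumer_growth(0, 31, cp_std), -respiration(31, cp_std))
  expect_equal(consumer_growth(Inf, 25, cp_std), 0.3281750604,
               tolerance = 1e-9)
  # once saturated assimilation falls below respiration, growth is negative
  # at every resource density (T = 40 is outside the fundamental niche)
  expect_true((1 - cp_std$delta) * max_ingestion(40, cp_std) <
                respiration(40, cp_std))
  expect_true(all(consumer_growth(c(0.01, 1, 100, Inf), 40, cp_std) < 0))
  # strictly increasing in R at fixed T
  v <- consumer_growth(seq(0, 10, by = 0.01), 20, cp_std)
  expect_true(all(diff(v) > 0))
})

test_that("resource intrinsic growth has the unimodal-minus-exponential shape", {
  rt0 <- resource_traits(d_0 = 0, d_1 = 1e-12)  # maintenance ~ 0
  expect_true(all(resource_growth(seq(-20, 60, 1), rt0, cp_std) > 0))
  expect_equal(resource_growth(25, rt_std, cp_std), 0.8890875302,
               tolerance = 1e-9)
  # zeros of the default traits (frozen from a bisection oracle)
  expect_equal(uniroot(function(T) resource_growth(T, rt_std, cp_std),
                       c(0, 25), tol = 1e-10)$root, 4.314717,
               tolerance = 1e-6)
  expect_equal(uniroot(function(T) resource_growth(T, rt_std, cp_std),
                       c(25, 45), tol = 1e-10)$root, 38.653224,
               tolerance = 1e-6)
  # negative at thermal extremes
  expect_true(resource_growth(-10, rt_std, cp_std) < 0)
  expect_true(resource_growth(45, rt_std, cp_std) < 0)
})

test_that("carrying capacity shares sign and zeros with r exactly", {
  T <- seq(-10, 50, length.out = 1000)
  r <- resource_growth(T, rt_std, cp_std)
  K <- carrying_capacity(T, rt_std, cp_std)
  expect_identical(K * rt_std$gamma, r)
  expect_identical(sign(K), sign(r))
  expect_equal(carrying_capacity(25, rt_std, cp_std), 0.8890875302 / 0.5,
               tolerance = 1e-9)
  # delta_T shifts the growth optimum away from the consumer's T_I
  rt_sh <- resource_traits(delta_T = 7)
  Tfine <- seq(0, 50, by = 0.001)
  expect_equal(Tfine[which.max(resource_growth(Tfine, rt_sh, cp_std))],
               Tfine[which.max(resource_growth(Tfine, rt_std, cp_std))] + 7,
               tolerance = 0.2)
})

test_that("Holling coefficients match the Michaelis-Menten equivalence", {
  hc <- holling_coefs(c(20, 25), cp_std)
  # Imax = 1/h and R_0 = 1/(a h)
  expect_equal(1 / hc$handling, max_ingestion(c(20, 25), cp_std))
  expect_equal(1 / (hc$attack * hc$handling), rep(cp_std$R_0, 2))
})

test_that("parameter invariants are enforced", {
  expect_error(consumer_params(beta = -150), "beta must be > 0")
  expect_error(consumer_params(delta = 1), "delta")
  expect_error(consumer_params(m_a = 0), "m_a")
  expect_error(resource_traits(gamma = 0), "gamma")
  expect_error(resource_traits(d_0 = -0.1), "d_0")
  expect_error(chemostat_params(S = -1), "S and D")
})
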