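#' Temperature-dependent respiration rate
#'
#' Exponential approximation to Boltzmann-Arrhenius metabolic scaling:
#' `m(T) = m_a * exp(m_b * T) + m_c`. Strictly positive and strictly
#' increasing in `T`.
#'
#' @param T Temperature (degrees C); vectorized.
#' @param cp A [consumer_params()] object.
#' @return Respiration rate (per time), same length as `T`.
#' @export
#' @examples
#' respiration(c(0, 25), consumer_params())
respiration <- function(T, cp) {
  stopifnot(inherits(cp, "consumer_params"))
  cp$m_a * exp(cp$m_b * T) + cp$m_c
}

#' Maximum ingestion rate
#'
#' Symmetric unimodal temperature response of the maximum uptake rate,
#' `Imax(T) = exp(-(T - T_I)^2 / beta)`: value in (0, 1], maximal (= 1) at
#' the ingestion optimum `T_I`.
#'
#' @inheritParams respiration
#' @return Maximum ingestion rate (per time), same length as `T`.
#' @export
max_ingestion <- function(T, cp) {
  stopifnot(inherits(cp, "consumer_params"))
  exp(-(T - cp$T_I)^2 / cp$beta)
}

#' Type II (Michaelis-Menten) functional response
#'
#' `f(R, T) = Imax(T) * R / (R + R_0)`: zero at `R = 0`, half of `Imax(T)` at
#' the half-saturation density `R = R_0`, saturating to `Imax(T)` as R grows.
#' `R = Inf` is accepted and returns the analytic saturated limit `Imax(T)`.
#'
#' @param R Resource density (`>= 0`); vectorized, recycled against `T`.
#' @inheritParams respiration
#' @return Per-capita ingestion rate (per time).
#' @export
functional_response <- function(R, T, cp) {
  stopifnot(inherits(cp, "consumer_params"))
  if (any(R < 0, na.rm = TRUE))
    stop("functional_response: R must be >= 0", call. = FALSE)
  sat <- ifelse(is.infinite(R), 1, R / (R + cp$R_0))
  max_ingestion(T, cp) * sat
}

#' Per-capita consumer growth rate
#'
#' The demographic thermal performance of the consumer at resource density
#' `R`: assimilated intake minus respiration,
#' `(1 - delta) * f(R, T) - m(T)`. `R = Inf` gives the resource-saturated
#' ("fundamental") TPC `(1 - delta) * Imax(T) - m(T)`.
#'
#' @inheritParams functional_response
#' @return Per-capita growth rate (per time); may be negative.
#' @export
#' @examples
#' cp <- consumer_params()
#' consumer_growth(Inf, 25, cp)  # fundamental TPC peak region
consumer_growth <- function(R, T, cp) {
  (1 - cp$delta) * functional_response(R, T, cp) - respiration(T, cp)
}

#' Resource intrinsic growth rate
#'
#' Difference between a symmetric unimodal birth function, centred at
#' `T_I + delta_T`, and an exponentially increasing maintenance function:
#' `r(T) = b_max * exp(-(T - T_I - delta_T)^2 / beta_r) -
#' (d_0 + d_1 * exp(d_2 * T))`. Negative at thermal extremes.
#'
#' The consumer's ingestion optimum `T_I` anchors the resource optimum so the
#' mismatch `delta_T` is expressed relative to the consumer; it is threaded in
#' from the paired [consumer_params()] (or given as a plain number).
#'
#' @param T Temperature (degrees C); vectorized.
#' @param rt A [resource_traits()] object.
#' @param T_I The paired consumer's ingestion optimum (degrees C), or a
#'   [consumer_params()] object from which it is taken.
#' @return Per-capita growth rate (per time).
#' @export
resource_growth <- function(T, rt, T_I) {
  stopifnot(inherits(rt, "resource_traits"))
  if (inherits(T_I, "consumer_params")) T_I <- T_I$T_I
  rt$b_max * exp(-(T - T_I - rt$delta_T)^2 / rt$beta_r) -
    (rt$d_0 + rt$d_1 * exp(rt$d_2 * T))
}

#' Temperature-dependent carrying capacity
#'
#' `K(T) = r(T) / gamma`. Because the same `r(T)` appears in the numerator,
#' `K` shares its sign and zeros with `r` at every temperature — the sign
#' constraint that keeps density dependence acting against growth during
#' thermal stress. Negative values are legal and meaningful: they never
#' constitute equilibria but steer declining populations to extinction.
#'
#' @inheritParams resource_growth
#' @return Carrying capacity (resource units); may be negative.
#' @export
carrying_capacity <- function(T, rt, T_I) {
  resource_growth(T, rt, T_I) / rt$gamma
}

#' Holling type II coefficients implied by the Michaelis-Menten form
#'
#' The Michaelis-Menten parameterization relates to the Holling disc equation
#' through `Imax(T) = 1 / h(T)` and `R_0 = 1 / (a(T) * h(T))`, so the implied
#' handling time is `1 / Imax(T)` and the attack rate `Imax(T) / R_0`.
#'
#' @inheritParams respiration
#' @return A tibble with columns `T`, `attack`, `handling`.
#' @export
holling_coefs <- function(T, cp) {
  Imax <- max_ingestion(T, cp)
  tibble::tibble(T = T, attack = Imax / cp$R_0, handling = 1 / Imax)
}
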