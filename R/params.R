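#' Consumer bioenergetic and thermal parameters
#'
#' Bundles the traits that govern a heterotrophic consumer's temperature
#' response: assimilation loss, exponential respiration, a symmetric unimodal
#' maximum ingestion rate, and the half-saturation density of a Michaelis-Menten
#' (type II) functional response.
#'
#' The defaults are the worked-example consumer used throughout the package:
#' `delta = 0.5`, `m_a = 0.01`, `m_b = 0.1`, `m_c = 0.05`, `T_I = 25`,
#' `beta = 150` (the mapping of the numeric values to `T_I`, `m_a`, `m_b`,
#' `m_c` is inferred from the order in which the rate functions are defined;
#' see the methods vignette) and `R_0 = 0.5`, an "efficient" consumer.
#'
#' @param delta Fraction of ingested biomass lost to assimilation
#'   inefficiency (dimensionless, `0 <= delta < 1`). The assimilated fraction
#'   is `1 - delta`.
#' @param m_a Respiration scale (per time), `> 0`.
#' @param m_b Respiration exponent (per degree C), `> 0`.
#' @param m_c Temperature-independent respiration offset (per time), `> 0`.
#' @param T_I Optimum temperature for consumption (degrees C). Note this is
#'   the optimum of the ingestion rate, not of the growth TPC.
#' @param beta Breadth parameter of the ingestion response (degrees C
#'   squared), `> 0`.
#' @param R_0 Half-saturation resource density of the functional response
#'   (resource units), `> 0`. Larger values describe more "prudent" consumers.
#'
#' @return An object of class `consumer_params` (a validated named list).
#' @seealso [respiration()], [max_ingestion()], [functional_response()],
#'   [consumer_growth()], [holling_coefs()]
#' @export
#' @examples
#' cp <- consumer_params()
#' respiration(25, cp)
consumer_params <- function(delta = 0.5, m_a = 0.01, m_b = 0.1, m_c = 0.05,
                            T_I = 25, beta = 150, R_0 = 0.5) {
  cp <- list(delta = delta, m_a = m_a, m_b = m_b, m_c = m_c,
             T_I = T_I, beta = beta, R_0 = R_0)
  validate_consumer_params(cp)
  structure(cp, class = "consumer_params")
}

validate_consumer_params <- function(cp) {
  check_scalar_num(cp, c("delta", "m_a", "m_b", "m_c", "T_I", "beta", "R_0"),
                   "consumer_params")
  bad <- character()
  if (!(cp$delta >= 0 && cp$delta < 1)) bad <- c(bad, "delta must satisfy 0 <= delta < 1")
  for (k in c("m_a", "m_b", "m_c", "beta", "R_0"))
    if (cp[[k]] <= 0) bad <- c(bad, sprintf("%s must be > 0", k))
  if (length(bad)) stop("invalid consumer_params: ", paste(bad, collapse = "; "),
                        call. = FALSE)
  invisible(cp)
}

#' Chemostat resource-supply parameters
#'
#' Inflow density and flow rate of an abiotic (non-living) resource supplied
#' by a chemostat. Both are temperature-independent.
#'
#' @param S Inflow resource density (resource units), `> 0`.
#' @param D Flow (dilution) rate (per time), `> 0`.
#'
#' @return An object of class `chemostat_params`.
#' @seealso [chemostat_equilibria()], [chemostat_branch_scan()]
#' @export
chemostat_params <- function(S = 1, D = 1) {
  chp <- list(S = S, D = D)
  check_scalar_num(chp, c("S", "D"), "chemostat_params")
  if (chp$S <= 0 || chp$D <= 0)
    stop("invalid chemostat_params: S and D must be > 0", call. = FALSE)
  structure(chp, class = "chemostat_params")
}

#' Thermal traits of a logistically growing resource
#'
#' The resource's intrinsic growth rate is the difference between a symmetric
#' unimodal "birth" function, centred at the consumer's ingestion optimum
#' `T_I` shifted by the thermal mismatch `delta_T`, and an exponentially
#' increasing "maintenance" function. The carrying capacity is `K = r / gamma`,
#' which forces `r` and `K` to share sign and zeros at every temperature.
#'
#' All default values are package-calibrated stand-ins chosen so that (i) the
#' resource has a wider fundamental thermal niche than the default consumer
#' and (ii) the coexistence equilibrium cycles for `R_0 = 0.5` but not for
#' `R_0 = 1` or `2`; see the methods vignette for the calibration.
#'
#' @param b_max Maximum birth scale (per time), `> 0`.
#' @param delta_T Thermal mismatch (degrees C, signed): shift of the
#'   resource's growth optimum relative to the consumer's `T_I`. Positive
#'   values move the resource's thermal performance to warmer temperatures.
#' @param beta_r Breadth of the resource growth response (degrees C squared),
#'   `> 0`. Defaults to the consumer's breadth (150).
#' @param d_0,d_1 Maintenance offset and scale (per time), `>= 0`.
#' @param d_2 Maintenance exponent (per degree C), `> 0`.
#' @param gamma Strength of density dependence (per resource-unit per time),
#'   `> 0`.
#'
#' @return An object of class `resource_traits`.
#' @seealso [resource_growth()], [carrying_capacity()], [logistic_equilibria()]
#' @export
resource_traits <- function(b_max = 1, delta_T = 0, beta_r = 150,
                            d_0 = 0.05, d_1 = 0.005, d_2 = 0.1, gamma = 0.5) {
  rt <- list(b_max = b_max, delta_T = delta_T, beta_r = beta_r,
             d_0 = d_0, d_1 = d_1, d_2 = d_2, gamma = gamma)
  validate_resource_traits(rt)
  structure(rt, class = "resource_traits")
}

validate_resource_traits <- function(rt) {
  check_scalar_num(rt, c("b_max", "delta_T", "beta_r", "d_0", "d_1", "d_2", "gamma"),
                   "resource_traits")
  bad <- character()
  for (k in c("b_max", "beta_r", "d_2", "gamma"))
    if (rt[[k]] <= 0) bad <- c(bad, sprintf("%s must be > 0", k))
  for (k in c("d_0", "d_1"))
    if (rt[[k]] < 0) bad <- c(bad, sprintf("%s must be >= 0", k))
  if (length(bad)) stop("invalid resource_traits: ", paste(bad, collapse = "; "),
                        call. = FALSE)
  invisible(rt)
}

check_scalar_num <- function(x, keys, what) {
  for (k in keys) {
    v <- x[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("%s: field '%s' must be a single finite number", what, k),
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.consumer_params <- function(x, ...) {
  cat("<consumer_params>\n")
  cat(sprintf("  assimilation loss delta = %g, half-saturation R_0 = %g\n",
              x$delta, x$R_0))
  cat(sprintf("  respiration m(T) = %g exp(%g T) + %g\n", x$m_a, x$m_b, x$m_c))
  cat(sprintf("  ingestion Imax(T) = exp(-(T - %g)^2 / %g)\n", x$T_I, x$beta))
  invisible(x)
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat(sprintf("<chemostat_params> S = %g, D = %g (temperature-independent)\n",
              x$S, x$D))
  invisible(x)
}

#' @export
print.resource_traits <- function(x, ...) {
  cat("<resource_traits>\n")
  cat(sprintf("  birth b(T) = %g exp(-(T - T_I - %g)^2 / %g)\n",
              x$b_max, x$delta_T, x$beta_r))
  cat(sprintf("  maintenance d(T) = %g + %g exp(%g T)\n", x$d_0, x$d_1, x$d_2))
  cat(sprintf("  density dependence gamma = %g (K = r / gamma)\n", x$gamma))
  invisible(x)
}
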