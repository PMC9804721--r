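with_mismatch <- function(rt, delta_T) {
  rt$delta_T <- delta_T
  rt
}

#' Classify the stable dynamical regime at one (T, delta_T) combination
#'
#' Labels the stable attractor of the logistic-resource model with the
#' resource's thermal optimum shifted by `delta_T`:
#' `"extinct"` when `r(T) <= 0` (trivial state stable), `"resource_only"`
#' when the resource persists but the consumer cannot invade,
#' `"coexist_stable"` when the coexistence equilibrium exists and is stable,
#' and `"coexist_cycles"` when it exists but is unstable (limit cycles).
#'
#' @param T Temperature (degrees C); vectorized.
#' @param delta_T Thermal mismatch (degrees C); vectorized, recycled
#'   against `T`.
#' @inheritParams logistic_rhs
#' @return Character vector of regime labels.
#' @export
#' @examples
#' classify_regime(25, 0, consumer_params(R_0 = 1), resource_traits())
classify_regime <- function(T, delta_T, cp, rt) {
  stopifnot(inherits(cp, "consumer_params"), inherits(rt, "resource_traits"))
  n <- max(length(T), length(delta_T))
  T <- rep_len(T, n); delta_T <- rep_len(delta_T, n)
  mapply(function(Ti, dTi) {
    rti <- with_mismatch(rt, dTi)
    r <- resource_growth(Ti, rti, cp$T_I)
    if (r <= 0) return("extinct")
    co <- logistic_coexistence(Ti, cp, rti)
    if (is.null(co)) return("resource_only")
    J <- logistic_jacobian(co$R, co$C, Ti, cp, rti)
    if (J[1, 1] + J[2, 2] < 0) "coexist_stable" else "coexist_cycles"
  }, T, delta_T)
}

#' Regime diagram over a (delta_T, T) lattice
#'
#' Classifies the stable dynamical outcome of the logistic-resource model at
#' every combination of thermal mismatch and temperature, producing the
#' regime diagram in long (tidy) format.
#'
#' @param T_grid Temperatures (degrees C); default 0.25-degree resolution.
#' @param delta_T_grid Mismatch values (degrees C); default 1-degree
#'   resolution.
#' @inheritParams logistic_rhs
#' @return A `regime_grid` object: tibble `(delta_T, T, regime)`.
#' @export
regime_grid <- function(T_grid = seq(0, 40, by = 0.25),
                        delta_T_grid = seq(-25, 15, by = 1), cp, rt) {
  grid <- tidyr::expand_grid(delta_T = delta_T_grid, T = T_grid)
  grid$regime <- classify_regime(grid$T, grid$delta_T, cp, rt)
  structure(grid, class = c("regime_grid", class(grid)))
}

#' Realized niche limits of the consumer for one mismatch value
#'
#' The coexistence band edges in temperature — realized Tmin and Tmax — for
#' the logistic model at mismatch `delta_T`, from sign changes of
#' `K(T) - R*(T)` (positive exactly where the consumer can invade).
#'
#' @param delta_T Thermal mismatch (degrees C), scalar.
#' @inheritParams logistic_rhs
#' @param T_grid Bracketing grid for the root scan.
#' @return Named numeric `c(T_min, T_max)`; `NA` when no coexistence.
#' @export
realized_limits <- function(delta_T, cp, rt, T_grid = seq(-10, 50, by = 0.05)) {
  rti <- with_mismatch(rt, delta_T)
  roots <- scan_roots(function(T) {
    v <- carrying_capacity(T, rti, cp$T_I) - rstar(T, cp)
    ifelse(is.na(v), -1, v)
  }, T_grid)
  if (length(roots) < 2) return(c(T_min = NA_real_, T_max = NA_real_))
  c(T_min = min(roots), T_max = max(roots))
}

#' Metabolic-meltdown diagnostic
#'
#' Locates the consumer's realized thermal limits under the logistic
#' resource, attributes each edge to consumer physiology or to the
#' resource's thermal traits, and reports whether the conditions for a
#' metabolic meltdown hold: equilibrium resource density *declining* as
#' temperature approaches the realized Tmax, which happens exactly when
#' Tmax falls on the negative-sloping (cold) side of the consumer's
#' zero-net-growth isocline, i.e. left of `argmin_T R*(T)`.
#'
#' Edge attribution uses the sign of the ZNGI slope at the edge: a warm edge
#' is consumer-limited when `R*` is rising there (the consumer's physiology
#' failing with warmth) and resource-limited when `R*` is still falling (the
#' consumer thwarted only by the resource's thermal collapse); the cold edge
#' is the mirror image. The mirrored cold-edge scenario (positive mismatch
#' placing Tmin on the positive-sloping side of the ZNGI, resource density
#' declining under cooling) is reported via `slope_at_tmin` and
#' `tmin_limited_by`.
#'
#' @inheritParams logistic_rhs
#' @return A `meltdown_report`: one-row tibble with columns `T_min`, `T_max`
#'   (realized limits, degrees C), `tmin_limited_by`, `tmax_limited_by`
#'   (`"consumer_physiology"` or `"resource_thermal_traits"`),
#'   `slope_at_tmin`, `slope_at_tmax` (sign of dR*/dT approaching each
#'   edge), `zngi_min_T` (temperature of the ZNGI minimum) and `meltdown`
#'   (logical).
#' @export
#' @examples
#' meltdown_report(consumer_params(R_0 = 1), resource_traits(delta_T = -22))
meltdown_report <- function(cp, rt) {
  lim <- realized_limits(rt$delta_T, cp, rt)
  if (any(is.na(lim)))
    stop("meltdown_report: no coexistence band for these parameters",
         call. = FALSE)
  # temperature of the ZNGI minimum (collapse point of the envelope)
  sat <- thermal_limits(Inf, cp)
  zngi_min <- stats::optimize(function(T) rstar(T, cp),
                              c(sat$T_min, sat$T_max), tol = 1e-10)$minimum
  eps <- 1e-4
  slope_at <- function(Te) {
    s <- (rstar(Te + eps, cp) - rstar(Te - eps, cp)) / (2 * eps)
    if (is.na(s)) s <- sign(Te - zngi_min)  # edge at the envelope rim
    sign(s)
  }
  s_min <- slope_at(lim["T_min"]); s_max <- slope_at(lim["T_max"])
  structure(tibble::tibble(
    T_min = unname(lim["T_min"]), T_max = unname(lim["T_max"]),
    tmin_limited_by = if (s_min < 0) "consumer_physiology" else "resource_thermal_traits",
    tmax_limited_by = if (s_max > 0) "consumer_physiology" else "resource_thermal_traits",
    slope_at_tmin = s_min, slope_at_tmax = s_max,
    zngi_min_T = zngi_min,
    meltdown = unname(lim["T_max"]) < zngi_min),
    class = c("meltdown_report", "tbl_df", "tbl", "data.frame"))
}

#' Family of realized thermal performance curves across mismatch values
#'
#' Stacks [realized_tpc()] curves for several thermal mismatch values: the
#' full range of TPC shapes that resource thermal sensitivity can impose on
#' one and the same consumer.
#'
#' @param delta_T Vector of mismatch values (degrees C).
#' @inheritParams logistic_rhs
#' @param T_grid Temperatures (degrees C).
#' @return A tibble `(delta_T, T, K, growth)`.
#' @export
tpc_family <- function(delta_T, cp, rt, T_grid = seq(0, 40, by = 0.1)) {
  purrr::map_dfr(delta_T, function(dT) {
    out <- realized_tpc(T_grid, cp, with_mismatch(rt, dT))
    out$delta_T <- dT
    out[, c("delta_T", "T", "K", "growth")]
  })
}
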