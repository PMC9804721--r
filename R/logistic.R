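#' Right-hand side of the logistic-resource consumer-resource model
#'
#' A biotic resource with temperature-dependent logistic growth, consumed
#' through the type II functional response. Density dependence is evaluated
#' in the form `r(T) R - gamma R^2` (algebraically identical to
#' `r R (1 - R/K)` wherever `K != 0` after substituting `K = r / gamma`),
#' which removes the removable singularity at `r(T) = 0` and keeps density
#' dependence working against growth when `r < 0`:
#' `dR/dt = r(T) R - gamma R^2 - f(R, T) C`,
#' `dC/dt = C ((1 - delta) f(R, T) - m(T))`.
#'
#' @inheritParams chemostat_rhs
#' @param rt A [resource_traits()] object.
#' @return Named numeric vector `c(dR, dC)`.
#' @export
logistic_rhs <- function(state, T, cp, rt) {
  stopifnot(inherits(rt, "resource_traits"))
  if (any(state < 0)) stop("logistic_rhs: state must be nonnegative", call. = FALSE)
  R <- state[1]; C <- state[2]
  r <- resource_growth(T, rt, cp$T_I)
  f <- functional_response(R, T, cp)
  c(dR = r * R - rt$gamma * R^2 - f * C,
    dC = C * ((1 - cp$delta) * f - respiration(T, cp)))
}

# Analytic Jacobian of the logistic model at (R, C).
logistic_jacobian <- function(R, C, T, cp, rt) {
  r <- resource_growth(T, rt, cp$T_I)
  Imax <- max_ingestion(T, cp)
  f <- functional_response(R, T, cp)
  fR <- Imax * cp$R_0 / (R + cp$R_0)^2
  g <- (1 - cp$delta) * f - respiration(T, cp)
  matrix(c(r - 2 * rt$gamma * R - fR * C, -f,
           (1 - cp$delta) * fR * C, g),
         nrow = 2, byrow = TRUE)
}

# Coexistence equilibrium of the logistic model; NULL when infeasible.
logistic_coexistence <- function(T, cp, rt) {
  Rh <- rstar(T, cp)
  if (is.na(Rh)) return(NULL)
  r <- resource_growth(T, rt, cp$T_I)
  Ch <- (r - rt$gamma * Rh) * (Rh + cp$R_0) / max_ingestion(T, cp)
  if (Ch <= 0) return(NULL)  # K(T) at or below the ZNGI: consumer cannot invade
  list(R = Rh, C = Ch)
}

#' Equilibria of the logistic-resource model at one temperature
#'
#' Up to three equilibria: the trivial state `(0, 0)` (always), the
#' resource-only state `(K(T), 0)` when `r(T) > 0` (a negative carrying
#' capacity is never listed as an equilibrium), and the coexistence state
#' `R_hat = R*(T)`,
#' `C_hat = (r(T) - gamma R_hat)(R_hat + R_0) / Imax(T)` when `R*(T)` exists
#' and `C_hat > 0` (i.e. `K(T) > R*(T)`). Stability from the analytic
#' Jacobian's eigenvalues; unlike the chemostat, the coexistence state here
#' can lose stability through a Hopf bifurcation.
#'
#' @inheritParams logistic_rhs
#' @return A tibble of equilibrium records with columns `T`, `equilibrium`
#'   (`"trivial"`, `"resource_only"`, `"coexistence"`), `R_hat`, `C_hat`,
#'   `stable`, `eig_re_max`, `eig_im`, `r_T`, `K_T`.
#' @export
#' @examples
#' logistic_equilibria(25, consumer_params(R_0 = 2), resource_traits())
logistic_equilibria <- function(T, cp, rt) {
  stopifnot(inherits(cp, "consumer_params"), inherits(rt, "resource_traits"))
  r <- resource_growth(T, rt, cp$T_I)
  K <- r / rt$gamma
  out <- equilibrium_row(T, "trivial", 0, 0, logistic_jacobian(0, 0, T, cp, rt))
  if (r > 0)
    out <- dplyr::bind_rows(out,
      equilibrium_row(T, "resource_only", K, 0,
                      logistic_jacobian(K, 0, T, cp, rt)))
  co <- logistic_coexistence(T, cp, rt)
  if (!is.null(co))
    out <- dplyr::bind_rows(out,
      equilibrium_row(T, "coexistence", co$R, co$C,
                      logistic_jacobian(co$R, co$C, T, cp, rt)))
  out$r_T <- r
  out$K_T <- K
  out
}

# Trace of the coexistence Jacobian as a function of T; NA when infeasible.
coexistence_trace <- function(T, cp, rt) {
  vapply(T, function(Ti) {
    co <- logistic_coexistence(Ti, cp, rt)
    if (is.null(co)) return(NA_real_)
    J <- logistic_jacobian(co$R, co$C, Ti, cp, rt)
    J[1, 1] + J[2, 2]
  }, numeric(1))
}

#' Hopf bifurcation temperatures of the logistic-resource model
#'
#' Temperatures at which the coexistence equilibrium's Jacobian trace crosses
#' zero with positive determinant, located by a coarse scan over the
#' coexistence band and refined by bisection. The determinant at coexistence
#' is always positive for this model, so a trace zero is a Hopf point.
#'
#' @param T_grid Temperature grid used to bracket trace sign changes.
#' @inheritParams logistic_rhs
#' @param tol Refinement tolerance (degrees C).
#' @return Numeric vector of Hopf temperatures (possibly empty).
#' @export
hopf_points <- function(T_grid = seq(0, 40, by = 0.05), cp, rt, tol = 1e-10) {
  stopifnot(inherits(cp, "consumer_params"), inherits(rt, "resource_traits"))
  scan_roots(function(T) coexistence_trace(T, cp, rt), T_grid, tol = tol)
}

#' Equilibrium branch scan of the logistic-resource model over temperature
#'
#' All three equilibrium branches with stability flags across a monotone
#' temperature grid, plus the detected bifurcations: transcritical points
#' where `r(T) = 0` (trivial/resource-only exchange) and where
#' `K(T) = R*(T)` (resource-only/coexistence exchange, the consumer's
#' realized thermal limits), and Hopf points from [hopf_points()].
#'
#' @inheritParams hopf_points
#' @return An `eq_branch` object (see [chemostat_branch_scan()]); records
#'   carry the extra columns `r_T` and `K_T`.
#' @export
logistic_branch_scan <- function(T_grid = seq(0, 40, by = 0.05), cp, rt,
                                 tol = 1e-6) {
  stopifnot(all(diff(T_grid) > 0))
  recs <- purrr::map_dfr(T_grid, logistic_equilibria, cp = cp, rt = rt)
  r_roots <- scan_roots(function(T) resource_growth(T, rt, cp$T_I),
                        T_grid, tol = tol)
  inv_roots <- scan_roots(function(T) {
    v <- carrying_capacity(T, rt, cp$T_I) - rstar(T, cp)
    ifelse(is.na(v), -1, v)  # infeasible R*: consumer cannot invade
  }, T_grid, tol = tol)
  hopf <- hopf_points(T_grid, cp, rt)
  bif <- dplyr::bind_rows(
    tibble::tibble(T = r_roots, type = rep("transcritical", length(r_roots))),
    tibble::tibble(T = inv_roots, type = rep("transcritical", length(inv_roots))),
    tibble::tibble(T = hopf, type = rep("hopf", length(hopf))))
  new_eq_branch(recs, dplyr::arrange(bif, .data$T), model = "logistic")
}
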