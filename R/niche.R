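#' Minimum resource requirement R*(T): the consumer's zero-net-growth isocline
#'
#' The lowest resource density at which the consumer's per-capita growth is
#' zero at temperature `T`:
#' `R*(T) = R_0 * m(T) / ((1 - delta) * Imax(T) - m(T))`,
#' defined only where saturated assimilation exceeds respiration,
#' `(1 - delta) * Imax(T) > m(T)`. Outside that range no resource density
#' permits growth and `NA` is returned (infeasible).
#'
#' @inheritParams respiration
#' @return Resource density (same length as `T`), `NA` where infeasible.
#' @seealso [thermal_limits()], [niche_envelope()]
#' @export
#' @examples
#' rstar(25, consumer_params())
rstar <- function(T, cp) {
  stopifnot(inherits(cp, "consumer_params"))
  a <- (1 - cp$delta) * max_ingestion(T, cp)
  m <- respiration(T, cp)
  ifelse(a > m, cp$R_0 * m / (a - m), NA_real_)
}

# Saturated (R -> Inf) per-capita growth: the fundamental TPC.
saturated_growth <- function(T, cp) {
  (1 - cp$delta) * max_ingestion(T, cp) - respiration(T, cp)
}

# Bracketed root refinement of g(T) = 0 on [lo, hi] where sign(g(lo)) != sign(g(hi)).
refine_root <- function(f, lo, hi, tol = 1e-10) {
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# Coarse scan for sign changes of f over a grid; returns refined roots.
scan_roots <- function(f, T_grid, tol = 1e-10) {
  v <- f(T_grid)
  v[!is.finite(v)] <- NA_real_
  ok <- !is.na(v)
  roots <- numeric()
  idx <- which(ok[-length(ok)] & ok[-1])
  for (i in idx) {
    if (v[i] == 0) roots <- c(roots, T_grid[i])
    else if (sign(v[i]) != sign(v[i + 1]) && v[i + 1] != 0)
      roots <- c(roots, refine_root(f, T_grid[i], T_grid[i + 1], tol))
  }
  if (length(v) && !is.na(v[length(v)]) && v[length(v)] == 0)
    roots <- c(roots, T_grid[length(v)])
  sort(unique(roots))
}

#' Thermal limits of consumer growth at a fixed resource density
#'
#' The two roots `Tmin < Tmax` of per-capita growth in temperature at
#' resource density `R`, bracketing the temperatures of positive growth.
#' `R = Inf` gives the saturated (fundamental) limits using the analytic
#' `R -> Inf` growth limit rather than a large finite density. When `R` lies
#' below the minimum of R*(T) no temperature permits growth ("no niche") and
#' both limits are `NA`.
#'
#' @param R Resource density or densities (`> 0`, may be `Inf`).
#' @inheritParams respiration
#' @param T_range Temperatures bracketing the search (degrees C).
#' @param step Coarse scan step (degrees C) used to bracket roots.
#' @return A tibble with columns `R`, `T_min`, `T_max`.
#' @export
#' @examples
#' thermal_limits(Inf, consumer_params())
thermal_limits <- function(R, cp, T_range = c(-20, 60), step = 0.05) {
  stopifnot(inherits(cp, "consumer_params"))
  if (any(R <= 0, na.rm = TRUE))
    stop("thermal_limits: R must be > 0", call. = FALSE)
  grid <- seq(T_range[1], T_range[2], by = step)
  one <- function(Ri) {
    f <- function(T) consumer_growth(Ri, T, cp)
    roots <- scan_roots(f, grid)
    if (length(roots) < 2) c(NA_real_, NA_real_) else range(roots)
  }
  lim <- vapply(R, one, numeric(2))
  tibble::tibble(R = R, T_min = lim[1, ], T_max = lim[2, ])
}

#' Optimal temperature for growth at a fixed resource density
#'
#' The temperature maximizing per-capita consumer growth at resource density
#' `R`, located by golden-section search ([stats::optimize()]) inside the
#' thermal limits. Nondecreasing in `R`, and always below the ingestion
#' optimum `T_I` because respiration rises with temperature. Returns `NA`
#' where `R` admits no niche.
#'
#' @inheritParams thermal_limits
#' @param tol Convergence tolerance of the search (degrees C).
#' @return Optimal temperature(s) (degrees C), same length as `R`.
#' @export
optimal_temperature <- function(R, cp, T_range = c(-20, 60), tol = 1e-8) {
  stopifnot(inherits(cp, "consumer_params"))
  lim <- thermal_limits(R, cp, T_range)
  vapply(seq_along(R), function(i) {
    if (is.na(lim$T_min[i])) return(NA_real_)
    stats::optimize(function(T) consumer_growth(R[i], T, cp),
                    c(lim$T_min[i], lim$T_max[i]),
                    maximum = TRUE, tol = tol)$maximum
  }, numeric(1))
}

#' Realized thermal niche envelope of the consumer
#'
#' Assembles the consumer's zero-net-growth isocline R*(T) over a temperature
#' grid, the ridge of optimal temperatures Topt(R), and the collapse point
#' where Tmin and Tmax converge (the minimum of R* over temperature, at which
#' the TPC shrinks to a single temperature). Symmetry of the boundary about
#' the collapse point is measured, never assumed.
#'
#' @inheritParams respiration
#' @param T_grid Temperatures at which to evaluate the boundary.
#' @return An object of class `niche_envelope`: a list with
#'   \describe{
#'     \item{boundary}{tibble `(T, R_star)` along the feasible grid}
#'     \item{topt_ridge}{tibble `(R, T_opt)` for densities above collapse}
#'     \item{collapse}{one-row tibble `(T, R)` where `T_min = T_max`}
#'   }
#' @export
niche_envelope <- function(cp, T_grid = seq(0, 40, by = 0.05)) {
  stopifnot(inherits(cp, "consumer_params"))
  rs <- rstar(T_grid, cp)
  if (all(is.na(rs)))
    stop("niche_envelope: no temperature on the grid permits consumer growth",
         call. = FALSE)
  if (!any(is.na(rs)))
    stop("niche_envelope: R*(T) has no boundary on this grid (growth feasible ",
         "at every grid temperature); widen T_grid or check parameters",
         call. = FALSE)
  feas <- which(!is.na(rs))
  # collapse point: minimize rstar inside the feasible bracket
  opt <- stats::optimize(function(T) rstar(T, cp),
                         range(T_grid[feas]), tol = 1e-10)
  collapse <- tibble::tibble(T = opt$minimum, R = opt$objective)
  boundary <- tibble::tibble(T = T_grid[feas], R_star = rs[feas])
  # Topt ridge over densities spanning collapse..saturation (log-spaced)
  R_ridge <- exp(seq(log(collapse$R * 1.001), log(100 * cp$R_0), length.out = 60))
  ridge <- tibble::tibble(R = R_ridge,
                          T_opt = optimal_temperature(R_ridge, cp,
                                                      T_range = range(T_grid)))
  structure(list(boundary = boundary, topt_ridge = ridge, collapse = collapse,
                 consumer = cp),
            class = "niche_envelope")
}

#' @export
print.niche_envelope <- function(x, ...) {
  cat("<niche_envelope>\n")
  cat(sprintf("  boundary: %d points on T in [%.2f, %.2f] C\n",
              nrow(x$boundary), min(x$boundary$T), max(x$boundary$T)))
  cat(sprintf("  collapse point: T* = %.3f C, R*_min = %.5f\n",
              x$collapse$T, x$collapse$R))
  invisible(x)
}

#' Realized thermal performance curve under resource feedback
#'
#' The consumer's invasion growth rate at the resource-only equilibrium of
#' the logistic model: `consumer_growth(max(K(T), 0), T)`. Where the resource
#' itself cannot persist (`K(T) <= 0`) the consumer sees no resource and the
#' curve equals `-m(T)`. The curve is positive exactly where `K(T) > R*(T)`,
#' i.e. where the consumer can invade.
#'
#' @param T_grid Temperatures (degrees C).
#' @inheritParams respiration
#' @param rt A [resource_traits()] object.
#' @return A tibble `(T, K, growth)`.
#' @export
realized_tpc <- function(T_grid, cp, rt) {
  stopifnot(inherits(cp, "consumer_params"), inherits(rt, "resource_traits"))
  K <- carrying_capacity(T_grid, rt, cp$T_I)
  tibble::tibble(T = T_grid, K = K,
                 growth = consumer_growth(pmax(K, 0), T_grid, cp))
}
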