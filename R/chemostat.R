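#' Right-hand side of the chemostat consumer-resource model
#'
#' Resource supplied abiotically at inflow density `S` and dilution rate `D`
#' (both temperature-independent), consumed through the type II functional
#' response; consumer grows by assimilation minus respiration:
#' `dR/dt = D (S - R) - f(R, T) C`, `dC/dt = C ((1 - delta) f(R, T) - m(T))`.
#'
#' @param state Numeric length-2 state `c(R, C)`, both `>= 0`.
#' @param T Temperature (degrees C).
#' @inheritParams respiration
#' @param chp A [chemostat_params()] object.
#' @return Named numeric vector `c(dR, dC)`.
#' @export
chemostat_rhs <- function(state, T, cp, chp) {
  stopifnot(inherits(chp, "chemostat_params"))
  if (any(state < 0)) stop("chemostat_rhs: state must be nonnegative", call. = FALSE)
  R <- state[1]; C <- state[2]
  f <- functional_response(R, T, cp)
  c(dR = chp$D * (chp$S - R) - f * C,
    dC = C * ((1 - cp$delta) * f - respiration(T, cp)))
}

# Analytic 2x2 Jacobian of the chemostat model at (R, C).
chemostat_jacobian <- function(R, C, T, cp, chp) {
  Imax <- max_ingestion(T, cp)
  f <- functional_response(R, T, cp)
  fR <- Imax * cp$R_0 / (R + cp$R_0)^2       # df/dR
  g <- (1 - cp$delta) * f - respiration(T, cp)
  matrix(c(-chp$D - fR * C, -f,
           (1 - cp$delta) * fR * C, g),
         nrow = 2, byrow = TRUE)
}

eig_summary <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  list(re_max = max(Re(ev)), im = max(abs(Im(ev))))
}

equilibrium_row <- function(T, label, R_hat, C_hat, J) {
  es <- eig_summary(J)
  tibble::tibble(T = T, equilibrium = label, R_hat = R_hat, C_hat = C_hat,
                 stable = es$re_max < 0, eig_re_max = es$re_max,
                 eig_im = es$im)
}

#' Equilibria of the chemostat model at one temperature
#'
#' Returns the resource-only equilibrium `(S, 0)` always, and the coexistence
#' equilibrium whenever it is feasible: `R_hat = R*(T)` (the zero-net-growth
#' isocline) with
#' `C_hat = D (S - R_hat)(R_hat + R_0) / (Imax(T) R_hat)`, reported when
#' `R*(T)` exists and `R_hat < S`. Stability comes from the eigenvalues of the
#' analytic Jacobian; at coexistence the trace is strictly negative and the
#' determinant positive, so the coexistence equilibrium of this model is
#' always stable where it exists.
#'
#' @inheritParams chemostat_rhs
#' @return A tibble with one row per equilibrium and columns `T`,
#'   `equilibrium` (`"resource_only"` or `"coexistence"`), `R_hat`, `C_hat`,
#'   `stable`, `eig_re_max`, `eig_im`.
#' @export
#' @examples
#' chemostat_equilibria(25, consumer_params(), chemostat_params())
chemostat_equilibria <- function(T, cp, chp) {
  stopifnot(inherits(cp, "consumer_params"), inherits(chp, "chemostat_params"))
  out <- equilibrium_row(T, "resource_only", chp$S, 0,
                         chemostat_jacobian(chp$S, 0, T, cp, chp))
  Rh <- rstar(T, cp)
  if (!is.na(Rh) && Rh < chp$S) {
    Ch <- chp$D * (chp$S - Rh) * (Rh + cp$R_0) / (max_ingestion(T, cp) * Rh)
    out <- dplyr::bind_rows(out,
      equilibrium_row(T, "coexistence", Rh, Ch,
                      chemostat_jacobian(Rh, Ch, T, cp, chp)))
  }
  out
}

# Consumer invasion growth at the chemostat resource-only equilibrium.
chemostat_invasion <- function(T, cp, chp) consumer_growth(chp$S, T, cp)

#' Equilibrium branch scan of the chemostat model over temperature
#'
#' Computes all equilibria on a monotone temperature grid and locates the
#' transcritical bifurcations — the consumer invasion/extinction boundaries —
#' as sign changes of the invasion growth rate `consumer_growth(S, T)`,
#' refined by bisection to `tol` degrees.
#'
#' @param T_grid Monotone temperature grid (degrees C).
#' @inheritParams chemostat_rhs
#' @param tol Bifurcation refinement tolerance (degrees C).
#' @return An `eq_branch` object: a tibble of equilibrium records (as in
#'   [chemostat_equilibria()]) with a `bifurcations` attribute, a tibble
#'   `(T, type)` with `type` `"transcritical"`.
#' @export
chemostat_branch_scan <- function(T_grid = seq(0, 40, by = 0.05), cp, chp,
                                  tol = 1e-6) {
  stopifnot(all(diff(T_grid) > 0))
  recs <- purrr::map_dfr(T_grid, chemostat_equilibria, cp = cp, chp = chp)
  bif <- scan_roots(function(T) chemostat_invasion(T, cp, chp), T_grid, tol = tol)
  new_eq_branch(recs,
                tibble::tibble(T = bif,
                               type = rep("transcritical", length(bif))),
                model = "chemostat")
}

new_eq_branch <- function(records, bifurcations, model) {
  structure(records, class = c("eq_branch", class(records)),
            bifurcations = bifurcations, model = model)
}

#' Bifurcation points detected along an equilibrium branch
#'
#' @param branch An `eq_branch` from [chemostat_branch_scan()] or
#'   [logistic_branch_scan()].
#' @return A tibble `(T, type)`; `type` is `"transcritical"` or `"hopf"`.
#' @export
bifurcations <- function(branch) {
  stopifnot(inherits(branch, "eq_branch"))
  attr(branch, "bifurcations")
}

#' @export
print.eq_branch <- function(x, ...) {
  cat(sprintf("<eq_branch: %s model> %d equilibrium records, T in [%.2f, %.2f] C\n",
              attr(x, "model"), nrow(x), min(x$T), max(x$T)))
  b <- attr(x, "bifurcations")
  if (nrow(b)) {
    cat("  bifurcations:\n")
    for (i in seq_len(nrow(b)))
      cat(sprintf("    %-13s at T = %.4f C\n", b$type[i], b$T[i]))
  } else cat("  bifurcations: none detected\n")
  NextMethod()
}
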