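#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an equilibrium branch
#'
#' @param x An `eq_branch`.
#' @param ... Unused.
#' @return A plain tibble of equilibrium records.
#' @export
tidy.eq_branch <- function(x, ...) {
  tibble::as_tibble(unclass_branch(x))
}

unclass_branch <- function(x) {
  attr(x, "bifurcations") <- NULL
  attr(x, "model") <- NULL
  class(x) <- setdiff(class(x), "eq_branch")
  x
}

#' One-row summary of an equilibrium branch
#'
#' @param x An `eq_branch`.
#' @param ... Unused.
#' @return A one-row tibble: model, temperature span of the coexistence
#'   branch, peak consumer biomass and its temperature, and counts of
#'   detected transcritical and Hopf bifurcations.
#' @export
glance.eq_branch <- function(x, ...) {
  co <- x[x$equilibrium == "coexistence", ]
  b <- attr(x, "bifurcations")
  tibble::tibble(
    model = attr(x, "model"),
    coexist_T_min = if (nrow(co)) min(co$T) else NA_real_,
    coexist_T_max = if (nrow(co)) max(co$T) else NA_real_,
    C_peak = if (nrow(co)) max(co$C_hat) else NA_real_,
    C_peak_T = if (nrow(co)) co$T[which.max(co$C_hat)] else NA_real_,
    n_transcritical = sum(b$type == "transcritical"),
    n_hopf = sum(b$type == "hopf"))
}

#' Tidy a niche envelope
#'
#' @param x A `niche_envelope`.
#' @param ... Unused.
#' @return A tibble `(T, R, part)` stacking the ZNGI boundary, the Topt
#'   ridge and the collapse point.
#' @export
tidy.niche_envelope <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(T = x$boundary$T, R = x$boundary$R_star, part = "zngi"),
    tibble::tibble(T = x$topt_ridge$T_opt, R = x$topt_ridge$R,
                   part = "topt_ridge"),
    tibble::tibble(T = x$collapse$T, R = x$collapse$R, part = "collapse"))
}

#' One-row summary of a niche envelope
#'
#' @param x A `niche_envelope`.
#' @param ... Unused.
#' @return A one-row tibble: collapse point, saturated thermal limits and
#'   saturated optimal temperature.
#' @export
glance.niche_envelope <- function(x, ...) {
  sat <- thermal_limits(Inf, x$consumer)
  tibble::tibble(collapse_T = x$collapse$T, R_star_min = x$collapse$R,
                 sat_T_min = sat$T_min, sat_T_max = sat$T_max,
                 sat_T_opt = optimal_temperature(Inf, x$consumer))
}

#' Plot an equilibrium branch diagram
#'
#' Equilibrium densities of resource and consumer against temperature, solid
#' where stable and dashed where unstable, with detected bifurcation
#' temperatures as vertical marks.
#'
#' @param object An `eq_branch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eq_branch <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("R_hat", "C_hat"), names_to = "species",
                        values_to = "density") |>
    dplyr::mutate(species = dplyr::recode(.data$species, R_hat = "resource",
                                          C_hat = "consumer"))
  b <- bifurcations(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$T, y = .data$density,
                                       colour = .data$equilibrium,
                                       linetype = .data$stable)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   name = "stable") +
    ggplot2::labs(x = "temperature (°C)", y = "equilibrium density",
                  colour = "branch")
  if (nrow(b))
    p <- p + ggplot2::geom_vline(data = b,
                                 ggplot2::aes(xintercept = .data$T),
                                 linetype = "dotted", colour = "grey40")
  p
}

#' Plot the realized thermal niche envelope
#'
#' The consumer's zero-net-growth isocline in the temperature-by-resource
#' plane (growth positive above the curve), the Topt ridge, and the collapse
#' point where the niche shrinks to a single temperature.
#'
#' @param object A `niche_envelope`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.niche_envelope <- function(object, ...) {
  ggplot2::ggplot(object$boundary, ggplot2::aes(x = .data$T, y = .data$R_star)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_path(data = object$topt_ridge,
                       ggplot2::aes(x = .data$T_opt, y = .data$R),
                       linetype = "dotted") +
    ggplot2::geom_point(data = object$collapse,
                        ggplot2::aes(x = .data$T, y = .data$R), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "temperature (°C)", y = "resource density",
                  title = "Zero-net-growth isocline R*(T) and Topt ridge")
}

#' Plot a regime diagram
#'
#' Stable dynamical outcome over the thermal-mismatch-by-temperature plane.
#'
#' @param object A `regime_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regime_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$delta_T, y = .data$T,
                               fill = .data$regime)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "thermal mismatch ΔT (°C)",
                  y = "temperature (°C)", fill = "regime")
}

#' Plot a family of realized thermal performance curves
#'
#' @param family A tibble from [tpc_family()].
#' @return A ggplot object.
#' @export
plot_tpc_family <- function(family) {
  ggplot2::ggplot(family, ggplot2::aes(x = .data$T, y = .data$growth,
                                       colour = factor(.data$delta_T),
                                       group = .data$delta_T)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = "per-capita consumer growth",
                  colour = "ΔT (°C)")
}

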