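config_keys <- c("model", "fixture",
                 "delta", "m_a", "m_b", "m_c", "T_I", "beta", "R_0",
                 "b_max", "delta_T", "beta_r", "d_0", "d_1", "d_2", "gamma",
                 "S", "D",
                 "T_from", "T_to", "T_step",
                 "delta_T_from", "delta_T_to", "delta_T_step")

#' Read a run configuration from a flat YAML or JSON file
#'
#' A configuration is a flat key-value map. Either name a shipped fixture
#' (`fixture: fig2a`) or give `model` (`chemostat` / `logistic`) together
#' with the parameter keys `delta, m_a, m_b, m_c, T_I, beta, R_0` (consumer),
#' `S, D` (chemostat) or `b_max, delta_T, beta_r, d_0, d_1, d_2, gamma`
#' (logistic resource); keys present override fixture values, missing ones
#' take the package defaults. Optional `T_from/T_to/T_step` and
#' `delta_T_from/to/step` define scan grids. Unknown keys are rejected, and
#' every parameter invariant is validated before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list with elements `model`, `consumer`, `resource`,
#'   `T_grid`, `delta_T_grid` and `fixture` (name or `NA`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path, call. = FALSE)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- if (!is.null(raw$fixture)) thermo_fixture(raw$fixture)
          else list(model = raw$model, consumer = NULL, resource = NULL)
  model <- base$model
  if (is.null(model))
    stop("config needs either 'fixture' or 'model'", call. = FALSE)
  model <- match.arg(model, c("chemostat", "logistic", "consumer_only"))

  pick <- function(keys, defaults) {
    vals <- defaults
    for (k in keys) if (!is.null(raw[[k]])) vals[[k]] <- raw[[k]]
    vals
  }
  cdef <- if (!is.null(base$consumer)) unclass(base$consumer)
          else formals(consumer_params)
  ckeys <- c("delta", "m_a", "m_b", "m_c", "T_I", "beta", "R_0")
  consumer <- do.call(consumer_params, lapply(pick(ckeys, cdef)[ckeys], eval))

  resource <- NULL
  if (model == "chemostat") {
    sdef <- if (!is.null(base$resource)) unclass(base$resource)
            else formals(chemostat_params)
    resource <- do.call(chemostat_params,
                        lapply(pick(c("S", "D"), sdef)[c("S", "D")], eval))
  } else if (model == "logistic") {
    rdef <- if (!is.null(base$resource)) unclass(base$resource)
            else formals(resource_traits)
    rkeys <- c("b_max", "delta_T", "beta_r", "d_0", "d_1", "d_2", "gamma")
    resource <- do.call(resource_traits, lapply(pick(rkeys, rdef)[rkeys], eval))
  }

  grid <- function(from, to, step, dfrom, dto, dstep) {
    seq(from %||% dfrom, to %||% dto, by = step %||% dstep)
  }
  structure(list(
    model = model, consumer = consumer, resource = resource,
    T_grid = grid(raw$T_from, raw$T_to, raw$T_step, 0, 40, 0.05),
    delta_T_grid = grid(raw$delta_T_from, raw$delta_T_to, raw$delta_T_step,
                        -25, 15, 1),
    fixture = raw$fixture %||% NA_character_),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to a flat YAML or JSON file
#'
#' Serializes a [run_config][read_run_config()] (or a fixture from
#' [thermo_fixture()]) back to the flat key-value dialect, so a read/write
#' round trip reproduces the same parameters.
#'
#' @param config A `run_config` or fixture list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flat <- c(list(model = config$model), unclass(config$consumer))
  if (!is.null(config$resource)) flat <- c(flat, unclass(config$resource))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(flat, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else stop("config must be .yaml/.yml or .json: ", path, call. = FALSE)
  invisible(path)
}

#' Write an equilibrium branch to CSV
#'
#' Deterministic column order `(T_C, branch, R_hat, C_hat, stable,
#' eig_re_max, bif_type)` plus `(r_T, K_T)` for the logistic model.
#' Bifurcation temperatures are flagged in the `bif_type` column on the
#' grid row nearest each detected bifurcation; other rows carry `""`.
#' A round-trip read reproduces the numeric values to full precision.
#'
#' @param branch An `eq_branch`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  stopifnot(inherits(branch, "eq_branch"))
  out <- tibble::as_tibble(branch)
  names(out)[names(out) == "T"] <- "T_C"
  names(out)[names(out) == "equilibrium"] <- "branch"
  out$bif_type <- ""
  b <- attr(branch, "bifurcations")
  if (!is.null(b) && nrow(b) && nrow(out)) {
    for (i in seq_len(nrow(b))) {
      j <- which.min(abs(out$T_C - b$T[i]))
      out$bif_type[j] <- paste(c(out$bif_type[j], b$type[i])[
        nzchar(c(out$bif_type[j], b$type[i]))], collapse = ";")
    }
  }
  cols <- c("T_C", "branch", "R_hat", "C_hat", "stable", "eig_re_max",
            "eig_im", intersect(c("r_T", "K_T"), names(out)), "bif_type")
  readr::write_csv(out[, cols], path)
  invisible(path)
}

#' Write a regime grid to long-format CSV
#'
#' Columns `(delta_T, T_C, label)`.
#'
#' @param grid A `regime_grid` from [regime_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regime_csv <- function(grid, path) {
  stopifnot(inherits(grid, "regime_grid"))
  out <- tibble::tibble(delta_T = grid$delta_T, T_C = grid$T,
                        label = grid$regime)
  readr::write_csv(out, path)
  invisible(path)
}
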