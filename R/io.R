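#' Read a time-temperature trace from CSV
#'
#' Expects a comma-separated file with header `time_s,temperature_K` (or
#' `temperature_C`, auto-converted to Kelvin) and an optional `field_on`
#' column (logical or 0/1). When `field_on` is absent the switch-off time may
#' be given via `t_off`; otherwise the field is assumed on throughout.
#'
#' @param path CSV file path.
#' @param t_off Optional switch-off time (s), used when the file has no
#'   `field_on` column.
#' @return A [temperature_trace()].
#' @export
read_trace <- function(path, t_off = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = TRUE)
  if (!"time_s" %in% names(d))
    stop("parse error: missing column 'time_s' in ", path, call. = FALSE)
  has_k <- "temperature_K" %in% names(d)
  has_c <- "temperature_C" %in% names(d)
  if (!has_k && !has_c)
    stop("parse error: need column 'temperature_K' or 'temperature_C' in ",
         path, call. = FALSE)
  temps <- if (has_k) d$temperature_K else d$temperature_C + 273.15
  tt <- as.numeric(d$time_s)
  bad <- which(!is.finite(tt) | !is.finite(temps))
  if (length(bad))
    stop(sprintf("parse error: non-finite value at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  nd <- which(diff(tt) <= 0)
  if (length(nd))
    stop(sprintf("parse error: time not strictly increasing at line %d of %s",
                 nd[1] + 2L, path), call. = FALSE)
  field_on <- if ("field_on" %in% names(d)) as.logical(d$field_on) else NULL
  temperature_trace(tt, temps, field_on = field_on, t_off = t_off)
}

#' Write a trace to CSV
#'
#' @param trace A [temperature_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  d <- as.data.frame(trace)
  d$field_on <- as.integer(d$field_on)
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  out <- unclass(fit)
  if (!is.null(out$covariance)) {
    out$covariance <- unname(as.matrix(out$covariance))
  }
  out
}

#' Write / read a fit result as JSON
#'
#' Serialises an `slp_fit` losslessly (full numeric precision,
#' `schema_version` "1"); `NaN`/`NA` standard errors are written as JSON
#' `null` and restored as `NA`.
#'
#' @param fit An `slp_fit` object.
#' @param path JSON file path.
#' @return `write_fit` returns `path` invisibly; `read_fit` the restored
#'   `slp_fit`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "slp_fit"))
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || !identical(as.character(x$schema_version), "1"))
    stop("schema error: unsupported or missing schema_version in ", path,
         call. = FALSE)
  if (is.null(x$model))
    stop("schema error: missing 'model' key in ", path, call. = FALSE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  cov <- if (!is.null(x$covariance)) {
    m <- x$covariance
    m[is.na(m)] <- NA_real_
    matrix(as.numeric(m), nrow = nrow(as.matrix(m)))
  } else NULL
  new_slp_fit(model = x$model,
              slp = num(x$slp), slp_se = num(x$slp_se),
              eps = num(x$eps), eps_se = num(x$eps_se),
              h_air = num(x$h_air), h_air_se = num(x$h_air_se),
              rss = num(x$rss), n_points = as.integer(x$n_points),
              converged = isTRUE(x$converged), covariance = cov,
              t_air = num(x$t_air), c_susp = num(x$c_susp),
              m_np = num(x$m_np), emissivity = num(x$emissivity),
              a_t = num(x$a_t))
}

CONFIG_SECTIONS <- c("schema_version", "suspension", "holder", "environment",
                     "fit", "scenario")

#' Read a run configuration (YAML or JSON)
#'
#' A configuration file holds up to four sections — `suspension`, `holder`,
#' `environment`, `scenario` — plus optional `fit` options, with units
#' encoded in the key names (e.g. `r_int_m`, `kappa_sh_w_per_mk`,
#' `t_air_k`). Unknown top-level sections are rejected. The format is chosen
#' by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path Config file path.
#' @return A named list with the validated sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), CONFIG_SECTIONS)
  if (length(unknown))
    stop("config error: unknown section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Build model objects from a configuration
#'
#' Translate the `holder`, `environment`, `suspension` and `scenario`
#' sections of a [read_config()] list into the corresponding package
#' objects.
#'
#' @param cfg A configuration list.
#' @return [config_holder()] a [holder_geometry()]; [config_environment()]
#'   an [environment_spec()]; [config_suspension()] a [suspension()];
#'   [config_scenario()] a [scenario_spec()].
#' @export
config_holder <- function(cfg) {
  h <- cfg$holder
  if (is.null(h)) stop("config error: missing 'holder' section", call. = FALSE)
  holder_geometry(r_int = h$r_int_m, r_ext = h$r_ext_m,
                  wall_thickness = h$wall_thickness_m,
                  kappa_sh = h$kappa_sh_w_per_mk,
                  fill_height = h$fill_height_m,
                  a_side = h$a_side_m2, a_bottom = h$a_bottom_m2,
                  a_sh_ext = h$a_sh_ext_m2, a_top = h$a_top_m2)
}

#' @rdname config_holder
#' @export
config_environment <- function(cfg) {
  e <- cfg$environment
  if (is.null(e)) stop("config error: missing 'environment' section",
                       call. = FALSE)
  environment_spec(t_air = e$t_air_k, h_air = e$h_air_w_per_m2k)
}

#' @rdname config_holder
#' @export
config_suspension <- function(cfg) {
  s <- cfg$suspension
  if (is.null(s)) stop("config error: missing 'suspension' section",
                       call. = FALSE)
  ks <- lapply(s$constituents, function(k)
    constituent(k$mass_g, k$specific_heat_j_per_gk,
                if (is.null(k$label)) "" else k$label))
  suspension(ks, m_np = s$m_np_g,
             emissivity = if (is.null(s$emissivity)) 0.9 else s$emissivity)
}

#' @rdname config_holder
#' @export
config_scenario <- function(cfg, seed = NULL) {
  sc <- cfg$scenario
  if (is.null(sc)) stop("config error: missing 'scenario' section",
                        call. = FALSE)
  pick <- function(key, default) if (is.null(sc[[key]])) default else sc[[key]]
  scenario_spec(slp = sc$slp_w_per_g, eps_eff = sc$eps_w_per_k,
                c_susp = pick("c_susp_j_per_k", 2.5786),
                m_np = pick("m_np_g", 0.1),
                emissivity = pick("emissivity", 0.9),
                a_t = pick("a_t_m2", 9.10e-4),
                t_air = pick("t_air_k", 298),
                t_on_s = pick("t_on_s", 600),
                t_off_s = pick("t_off_s", 600),
                sample_rate_hz = pick("sample_rate_hz", 1),
                noise_sd_k = pick("noise_sd_k", 0.1),
                quantization_k = pick("quantization_k", 0.1),
                drift_k_per_s = pick("drift_k_per_s", 0),
                seed = if (!is.null(seed)) seed else sc$seed,
                label = pick("label", ""))
}
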