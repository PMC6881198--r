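# File readers/writers and configuration handling. All tabular formats
# are plain CSV (UTF-8, header row, '.' decimal); reports are JSON; the
# pipeline configuration is a single YAML document.

trace_columns <- c("time_s", "pressure_pa", "po2_mmhg", "umax_um_s",
                   "replicate")

#' Read a velocity trace from CSV
#'
#' Required columns: `time_s`, `pressure_pa`, `po2_mmhg`, `umax_um_s`,
#' `replicate`. Unknown extra columns are preserved untouched. Malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A data frame of class `rheology_trace`.
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(trace_columns, names(d))
  if (length(miss))
    stop("trace file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(trace_columns, "replicate")
  bad <- which(Reduce(`|`, lapply(d[num_cols], function(x)
    !is.finite(suppressWarnings(as.numeric(x))))))
  if (length(bad))
    stop("trace file ", path, ": non-numeric or missing values on data ",
         "line(s) ", paste(utils::head(bad + 1, 10), collapse = ", "),
         call. = FALSE)
  for (cc in num_cols) d[[cc]] <- as.numeric(d[[cc]])
  if (any(d$pressure_pa <= 0))
    stop("trace file ", path, ": pressures must be positive",
         call. = FALSE)
  if (any(d$umax_um_s < 0))
    stop("trace file ", path, ": velocities must be >= 0", call. = FALSE)
  structure(d, class = c("rheology_trace", "data.frame"))
}

#' Write a velocity trace to CSV
#'
#' @param trace A trace data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a rheogram to CSV
#'
#' Columns: `po2_mmhg`, `shear_rate_per_s`, `viscosity_pa_s`,
#' `shear_stress_pa`, `sd_pa_s`.
#'
#' @param rheogram A `rheogram` from [infer_rheogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rheogram <- function(rheogram, path) {
  utils::write.csv(as.data.frame(rheogram), path, row.names = FALSE)
  invisible(path)
}

#' Read a rheogram from CSV
#'
#' @param path CSV path written by [write_rheogram()].
#' @return A data frame of class `rheogram`.
#' @export
read_rheogram <- function(path) {
  d <- utils::read.csv(path)
  need <- c("po2_mmhg", "shear_rate_per_s", "viscosity_pa_s",
            "shear_stress_pa")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rheogram file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(d, class = c("rheogram", "data.frame"))
}

#' Write power-law fit reports as JSON
#'
#' @param fits Data frame from [fit_rheogram()] or [cohort_fits()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config schema. Field names carry their
#' units (`*_um`, `*_pa`, `*_mmhg`, `*_cm2_s`). The device block may give
#' either channel geometries or explicit resistance constants
#' (`c1_per_m3` etc.) for the network.
#'
#' @param seed Integer seed recorded in the config; mandatory for any
#'   stochastic command.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = NULL) {
  list(
    device = list(
      channels = list(
        inlet_resistor = list(height_um = 15, width_um = 100,
                              length_mm = 40, shape = "rectangular"),
        bypass = list(height_um = 15, width_um = 15, length_mm = 20,
                      shape = "square"),
        experimental = list(height_um = 15, width_um = 15, length_mm = 20,
                            shape = "square")
      ),
      profile_factor = 0.4771,
      velocity_rule = "continuity"
    ),
    protocol = list(
      pressure_steps_pa = default_pressure_steps(),
      po2_levels_mmhg = c(92, 46, 0),
      dwell_s = 30
    ),
    layers = list(
      list(name = "blood", thickness_um = 15, d_cm2_s = 4e-5,
           material = "water"),
      list(name = "membrane_lower", thickness_um = 100, d_cm2_s = 3.3e-5,
           material = "pdms"),
      list(name = "hydration", thickness_um = 100, d_cm2_s = 4e-5,
           material = "water"),
      list(name = "membrane_upper", thickness_um = 100, d_cm2_s = 3.3e-5,
           material = "pdms")
    ),
    generator = list(
      seed = seed,
      n_patients = 9,
      replicates = 18,
      noise_cv = 0.05,
      between_sd = c(0.075, 0.049, 0.056),
      hbs = 0.95, hba = 0.02, hbf = 0.03,
      hct = 0.25, mchc_g_dl = 33
    ),
    solver = list(tol = 1e-8, max_iter = 100, dz_um = 1, dt_s = 0.05),
    stats = list(alpha = 0.05, posthoc = "sign_permutation")
  )
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML config path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write a pipeline configuration
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks the schema (required blocks, field types, value ranges) before
#' any computation. Stochastic runs require `generator$seed`.
#'
#' @param config Configuration list.
#' @param require_seed Fail when `generator$seed` is missing (default
#'   `TRUE`, the safe setting for synthetic runs).
#' @return The config, invisibly classed `oxyrheo_config`.
#' @export
validate_config <- function(config, require_seed = TRUE) {
  need <- c("device", "protocol", "layers", "generator", "solver", "stats")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dv <- config$device
  if (is.null(dv$channels) && is.null(dv$constants))
    stop("device block needs either 'channels' geometries or explicit ",
         "'constants' (c1_per_m3, c2_per_m3, c3_per_m3)", call. = FALSE)
  if (!is.null(dv$profile_factor) &&
      (dv$profile_factor <= 0 || dv$profile_factor > 1))
    stop("device$profile_factor must lie in (0, 1]", call. = FALSE)
  pr <- config$protocol
  if (!length(pr$pressure_steps_pa) || any(pr$pressure_steps_pa <= 0))
    stop("protocol$pressure_steps_pa must be a non-empty positive vector",
         call. = FALSE)
  if (require_seed &&
      (is.null(config$generator$seed) || !is.finite(config$generator$seed)))
    stop("generator$seed is mandatory for stochastic runs", call. = FALSE)
  if (!is.null(config$generator$noise_cv) && config$generator$noise_cv < 0)
    stop("generator$noise_cv must be >= 0", call. = FALSE)
  invisible(structure(config, class = "oxyrheo_config"))
}

#' Build the device network described by a configuration
#'
#' @param config Validated configuration list.
#' @return A [device_network()].
#' @export
network_from_config <- function(config) {
  dv <- config$device
  if (!is.null(dv$channels)) {
    ch <- function(role, spec) {
      hydraulic_resistor(role, channel_geometry(
        spec$height_um * 1e-6, spec$width_um * 1e-6,
        spec$length_mm * 1e-3, spec$shape))
    }
    device_network(ch("inlet_resistor", dv$channels$inlet_resistor),
                   ch("bypass", dv$channels$bypass),
                   ch("experimental", dv$channels$experimental))
  } else {
    cs <- dv$constants
    device_network(
      hydraulic_resistor("inlet_resistor", c_per_m3 = cs$c1_per_m3),
      hydraulic_resistor("bypass", c_per_m3 = cs$c2_per_m3),
      hydraulic_resistor("experimental", c_per_m3 = cs$c3_per_m3))
  }
}

#' Build the diffusion layer stack described by a configuration
#'
#' @param config Validated configuration list.
#' @return A [layer_stack()].
#' @export
stack_from_config <- function(config) {
  layer_stack(lapply(config$layers, function(l)
    diffusion_layer(l$name, l$thickness_um, l$d_cm2_s, l$material)))
}
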