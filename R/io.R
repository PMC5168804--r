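#' Load a run configuration from a YAML file
#'
#' Reads a structured configuration with blocks `constants`, `parameters`,
#' `conditions`, `solver` and optional `noise`. Every key is optional and
#' falls back to the package defaults (the historical parameter tables);
#' unknown blocks or keys are an error listing them. Internal-consistency
#' warnings (reciprocal thiosulfate-yield identity, H2-diffusivity
#' plausibility) are emitted during construction.
#'
#' @param path path to a YAML file, or `NULL` for the full default
#'   configuration.
#' @return object of class `run_config`: list with `constants`
#'   ([physical_constants()]), `parameters` ([model_parameters()]),
#'   `conditions` ([operating_conditions()]), `solver` (list `rtol`, `atol`,
#'   `dt`, `k_ab`), `noise` ([noise_spec()] or `NULL`) and `provenance`
#'   (path and MD5 hash).
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$parameters$mu_max  # 0.9
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else {
           if (!file.exists(path)) stop("config file not found: ", path)
           yaml::read_yaml(path)
         }
  if (is.null(raw)) raw <- list()
  known_blocks <- c("constants", "parameters", "conditions", "solver", "noise")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))

  take <- function(block, builder) {
    given <- raw[[block]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(formals(builder)))
    if (length(bad))
      stop("unknown key(s) in block '", block, "': ",
           paste(bad, collapse = ", "))
    do.call(builder, given)
  }
  constants <- take("constants", physical_constants)
  if (constants$d_h2 < constants$d_o2)
    warning("configured H2 diffusivity (", constants$d_h2, " cm2/s) is below ",
            "the O2 diffusivity; H2 diffuses faster than O2 in water, so a ",
            "tabulated 1.4e-5 is likely a power-of-ten slip for 1.4e-4")
  parameters <- take("parameters", model_parameters)
  conditions <- take("conditions", operating_conditions)

  solver_defaults <- list(rtol = 1e-8, atol = 1e-10, dt = 0.02, k_ab = 1000)
  sv <- raw$solver
  if (is.null(sv)) sv <- list()
  bad <- setdiff(names(sv), names(solver_defaults))
  if (length(bad))
    stop("unknown key(s) in block 'solver': ", paste(bad, collapse = ", "))
  solver <- utils::modifyList(solver_defaults, sv)

  noise <- if (!is.null(raw$noise)) take("noise", noise_spec) else NULL

  structure(list(constants = constants, parameters = parameters,
                 conditions = conditions, solver = solver, noise = noise,
                 provenance = list(
                   path = if (is.null(path)) NA_character_ else path,
                   md5 = if (is.null(path)) NA_character_
                         else unname(tools::md5sum(path)))),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Serialises a `run_config` so that `load_config(dump_config(cfg, f))`
#' reproduces it (lossless round trip of all numeric fields).
#'
#' @param cfg a [load_config()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  drop_derived <- function(obj, builder)
    unclass(obj)[intersect(names(formals(builder)), names(unclass(obj)))]
  out <- list(constants = drop_derived(cfg$constants, physical_constants),
              parameters = drop_derived(cfg$parameters, model_parameters),
              conditions = drop_derived(cfg$conditions, operating_conditions),
              solver = cfg$solver)
  if (!is.null(cfg$noise))
    out$noise <- drop_derived(cfg$noise, noise_spec)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run a configured batch simulation
#'
#' Convenience wrapper: executes [run_batch()] with a configuration's
#' constants, parameters, conditions and solver settings.
#'
#' @param cfg a [load_config()] result.
#' @param ... overrides passed on to [run_batch()].
#' @return a `batch_sim` object.
#' @export
simulate_config <- function(cfg, ...) {
  run_batch(cfg$parameters, cfg$constants, cfg$conditions,
            k_ab = cfg$solver$k_ab, rtol = cfg$solver$rtol,
            atol = cfg$solver$atol, dt = cfg$solver$dt, ...)
}

## Units of the trajectory columns, written as a comment line above the header
.column_units <- c(
  time = "h", X = "g/L", S1 = "mmol/L", Yeast = "g/L", S2 = "mmol/L",
  Act = "mmol/L", Lact = "mmol/L", H2l = "mmol/L", CO2l = "mmol/L",
  H2Sl = "mmol/L", HCO3 = "mmol/L", HS = "mmol/L", H2g = "mmol/L",
  CO2g = "mmol/L", H2Sg = "mmol/L", cumH2out = "mmol", cumCO2out = "mmol",
  cumH2Sout = "mmol", cumH2prod = "mmol/L", cumH2cons = "mmol/L",
  cumGluCons = "mmol/L", mu = "1/h", q_g = "L/h", r_h2_prod = "mmol/L/h",
  inhibition = "-", prod_h2_vol = "mmol/L/h", prod_h2_spec = "mmol/g/h",
  inhibition_ratio = "-", offgas_h2_frac = "-", offgas_co2_frac = "-")

#' Write a simulation trajectory as delimited text
#'
#' Writes the trajectory of a `batch_sim` (or any data frame) as CSV with a
#' leading `#`-comment line stating each column's unit. Values are written
#' with 17 significant digits so that [read_timeseries()] restores them
#' exactly.
#'
#' @param result a `batch_sim` from [run_batch()] or a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- if (inherits(result, "batch_sim")) result$trajectory else result
  if (!is.data.frame(df)) stop("'result' must be a batch_sim or data frame")
  con <- file(path, open = "wt")
  on.exit(close(con))
  units <- .column_units[names(df)]
  units[is.na(units)] <- "?"
  writeLines(paste0("# units: ",
                    paste(names(df), units, sep = "=", collapse = ",")), con)
  if (nrow(df) == 0) {
    warning("empty trajectory: writing header-only file")
    writeLines(paste(names(df), collapse = ","), con)
    return(invisible(path))
  }
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  writeLines(c(paste(names(df), collapse = ","),
               apply(fmt, 1, paste, collapse = ",")), con)
  invisible(path)
}

#' Read back a delimited-text time series
#'
#' @param path a file written by [write_timeseries()].
#' @return data frame with the original column names and values.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write simulation metrics as JSON
#'
#' Serialises the scalar metrics of a `batch_sim` (plus conditions and solver
#' settings for provenance) to a JSON summary file.
#'
#' @param result a `batch_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  if (!inherits(result, "batch_sim")) stop("'result' must be a batch_sim")
  jsonlite::write_json(
    list(metrics = result$metrics,
         conditions = unclass(result$conditions),
         kla = as.list(result$kla),
         solver = result$solver),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
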