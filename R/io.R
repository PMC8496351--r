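#' Read and write observed perfusion series
#'
#' The on-disk format is UTF-8 delimited text with columns
#' `experiment_id`, `dosing_side`, `sampled_reservoir`, `time_min`,
#' `conc_mg_per_L` — one row per sampled reservoir concentration. The
#' write/read round trip is lossless for the data columns.
#'
#' @param path File path.
#' @param data Observed-data tibble.
#' @return `read_observed()` returns a validated tibble;
#'   `write_observed()` returns `path` invisibly.
#' @export
read_observed <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            experiment_id = readr::col_character(),
                            dosing_side = readr::col_character(),
                            sampled_reservoir = readr::col_character(),
                            time_min = readr::col_double(),
                            conc_mg_per_L = readr::col_double()))
  .check_observed(data)
  data
}

#' @rdname read_observed
#' @export
write_observed <- function(data, path) {
  cols <- c("experiment_id", "dosing_side", "sampled_reservoir", "time_min",
            "conc_mg_per_L")
  if (nrow(data) > 0) .check_observed(data)
  readr::write_csv(data[, cols, drop = FALSE], path)
  invisible(path)
}

#' Write a simulation as tidy delimited text
#'
#' Columns: `experiment_id`, `compartment`, `time_min`, `conc_mg_per_L`.
#'
#' @param sim A [simulate_perfusion()] result.
#' @param path Output path.
#' @param experiment_id Identifier to stamp on every row.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, experiment_id = "sim") {
  out <- tibble(experiment_id = experiment_id,
                compartment = as.character(sim$compartment),
                time_min = sim$time_min,
                conc_mg_per_L = sim$conc_mg_per_L)
  readr::write_csv(out, path)
  invisible(path)
}

# -- structured config (YAML, explicit units on every numeric field) --------

.cfg_num <- function(cfg, key, quantity) {
  node <- cfg[[key]]
  if (is.null(node)) stop_config(paste0("config field '", key, "' is missing"))
  if (is.null(node$unit)) {
    stop_config(paste0("config field '", key, "' lacks a unit declaration"))
  }
  if (is.null(node$value)) stop_config(paste0("config field '", key, "' lacks a value"))
  to_canonical(as.numeric(node$value), node$unit, quantity)
}

#' Read / write a perfusion-system configuration file
#'
#' The configuration is a YAML file with a `drug` block and a `system`
#' block; every numeric field carries an explicit `value` and `unit`
#' (missing units are refused, not silently assumed). See
#' `system.yaml` under the package's `extdata` for the bundled
#' acetaminophen configuration.
#'
#' @param path YAML file path.
#' @param sys A [perfusion_system()] (for writing).
#' @return `read_system_config()` returns a `perfusion_system`;
#'   `write_system_config()` returns `path` invisibly.
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drug) || is.null(cfg$system)) {
    stop_config("config must contain 'drug' and 'system' blocks")
  }
  d <- cfg$drug
  drug <- drug_parameters(
    name = d$name %||% "drug",
    fu_adult = .cfg_num(d, "fu_adult", "dimensionless"),
    membrane_permeability = .cfg_num(d, "membrane_permeability", "permeability"),
    endothelial_permeability = .cfg_num(d, "endothelial_permeability", "permeability"),
    permeability_unit = "dm/min",
    pKa = if (!is.null(d$pKa)) as.numeric(d$pKa) else NA_real_,
    pka_type = d$pka_type %||% "neutral",
    logP = if (!is.null(d$logP)) as.numeric(d$logP) else NA_real_,
    molecular_weight = if (!is.null(d$molecular_weight)) as.numeric(d$molecular_weight) else NA_real_
  )
  s <- cfg$system
  perfusion_system(
    drug = drug,
    Q_M = .cfg_num(s, "Q_M", "flow"),
    Q_F = .cfg_num(s, "Q_F", "flow"),
    V_M_res = .cfg_num(s, "V_M_res", "volume"),
    V_F_res = .cfg_num(s, "V_F_res", "volume"),
    V_intervillous = .cfg_num(s, "V_intervillous", "volume"),
    V_intravillous = .cfg_num(s, "V_intravillous", "volume"),
    SA_villi = .cfg_num(s, "SA_villi", "area"),
    fu = .cfg_num(s, "fu", "dimensionless"),
    fu_fetus = .cfg_num(s, "fu_fetus", "dimensionless"),
    K_M_int_perf = .cfg_num(s, "K_M_int_perf", "dimensionless"),
    K_F_int_perf = .cfg_num(s, "K_F_int_perf", "dimensionless"),
    K_F_cell_perf = .cfg_num(s, "K_F_cell_perf", "dimensionless"),
    K_FM_cell_perf = .cfg_num(s, "K_FM_cell_perf", "dimensionless"),
    f_in = .cfg_num(s, "f_in", "dimensionless"),
    f_out = .cfg_num(s, "f_out", "dimensionless")
  )
}

#' @rdname read_system_config
#' @export
write_system_config <- function(sys, path) {
  stopifnot(inherits(sys, "perfusion_system"))
  vu <- function(value, unit) list(value = value, unit = unit)
  cfg <- list(
    drug = list(
      name = sys$drug$name,
      fu_adult = vu(sys$drug$fu_adult, "fraction"),
      membrane_permeability = vu(sys$drug$P, "dm/min"),
      endothelial_permeability = vu(sys$drug$P_endo, "dm/min"),
      pKa = sys$drug$pKa, pka_type = sys$drug$pka_type,
      logP = sys$drug$logP, molecular_weight = sys$drug$molecular_weight
    ),
    system = list(
      Q_M = vu(sys$Q_M, "L/min"), Q_F = vu(sys$Q_F, "L/min"),
      V_M_res = vu(sys$volumes[["M_res"]], "L"),
      V_F_res = vu(sys$volumes[["F_res"]], "L"),
      V_intervillous = vu(sys$V_intervillous, "L"),
      V_intravillous = vu(sys$V_intravillous, "L"),
      SA_villi = vu(sys$SA_villi, "dm^2"),
      fu = vu(sys$fu, "fraction"), fu_fetus = vu(sys$fu_fetus, "fraction"),
      K_M_int_perf = vu(sys$K_M_int_perf, "unitless"),
      K_F_int_perf = vu(sys$K_F_int_perf, "unitless"),
      K_F_cell_perf = vu(sys$K_F_cell_perf, "unitless"),
      K_FM_cell_perf = vu(sys$K_FM_cell_perf, "unitless"),
      f_in = vu(sys$f_in, "unitless"), f_out = vu(sys$f_out, "unitless")
    )
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
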