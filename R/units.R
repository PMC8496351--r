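# Minimal unit handling for the model's canonical unit system:
# amounts mg, volumes L, time min, lengths dm (so permeabilities dm/min,
# surface areas dm^2, flows L/min, concentrations mg/L, albumin g/L).

.unit_factors <- list(
  # factor converts FROM the named unit TO the canonical unit of its quantity
  flow = c("L/min" = 1, "mL/min" = 1e-3),
  volume = c("L" = 1, "mL" = 1e-3),
  permeability = c("dm/min" = 1, "cm/min" = 0.1, "m/min" = 10),
  area = c("dm^2" = 1, "dm2" = 1, "cm^2" = 0.01, "cm2" = 0.01, "m^2" = 100, "m2" = 100),
  concentration = c("mg/L" = 1, "ug/mL" = 1, "g/L" = 1e3),
  albumin = c("g/L" = 1, "mg/mL" = 1, "mg/L" = 1e-3),
  time = c("min" = 1, "h" = 60, "s" = 1 / 60),
  dimensionless = c("1" = 1, "unitless" = 1, "fraction" = 1)
)

#' Convert a value to the package's canonical unit
#'
#' The model works in mg, L, min and dm throughout. This helper converts
#' common laboratory units (mL/min flows, cm/min permeabilities, mg/mL
#' albumin, ...) onto that system and refuses unknown units rather than
#' guessing.
#'
#' @param value Numeric value(s).
#' @param unit Unit string the value is expressed in (e.g. `"cm/min"`).
#' @param quantity One of `"flow"`, `"volume"`, `"permeability"`, `"area"`,
#'   `"concentration"`, `"albumin"`, `"time"`, `"dimensionless"`.
#' @return Numeric value(s) in the canonical unit.
#' @examples
#' to_canonical(4.29e-2, "cm/min", "permeability") # dm/min
#' @export
to_canonical <- function(value, unit, quantity) {
  tab <- .unit_factors[[quantity]]
  if (is.null(tab)) stop_config(paste0("unknown quantity '", quantity, "'"))
  if (is.null(unit) || is.na(unit) || !nzchar(unit)) {
    if (quantity == "dimensionless") return(value)
    stop_config(paste0("missing unit for ", quantity, " value; declare one of: ",
                       paste(names(tab), collapse = ", ")))
  }
  if (!unit %in% names(tab)) {
    stop_config(paste0("unsupported unit '", unit, "' for ", quantity,
                       "; supported: ", paste(names(tab), collapse = ", ")))
  }
  value * unname(tab[unit])
}
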