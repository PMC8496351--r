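#' Export fitted cotyledon parameters for a whole-placenta PBPK model
#'
#' Collects the placental-transfer parameters estimated on the cotyledon
#' into the quantities a maternal-fetal PBPK model consumes: the four
#' partition coefficients, the effective directional apical permeabilities
#' `f_in * P` and `f_out * P`, the total villous surface area the transfer
#' rate scales with in the whole placenta, the per-cotyledon surface area
#' `total / n_cotyledons`, and the fetal fraction unbound at delivery
#' recomputed from the fetal plasma albumin concentration via
#' [scale_fraction_unbound()]. No parameter is exported for the maternal
#' intracellular (decidua) compartment: the decidua is shed at delivery and
#' has no counterpart in the cotyledon model (annotated in the output).
#'
#' @param fit A converged [fit_transfer()] result (its fitted system
#'   supplies parameters the scenario did not free).
#' @param drug A [drug_parameters()] object (membrane permeability,
#'   adult fu).
#' @param n_cotyledons Cotyledons per term placenta (default 35).
#' @param total_villi_SA Total villous surface area of the term placenta
#'   (dm^2, default 1178).
#' @param fetal_albumin Fetal plasma albumin at delivery (g/L, default 32).
#' @param reference_albumin Reference albumin for fu scaling (g/L).
#' @return An object of class `placenta_transfer` (named list of values in
#'   canonical units, with a `notes` field).
#' @examples
#' \donttest{
#' camp <- generate_campaign(campaign_spec(n_maternal = 2, n_fetal = 1), seed = 1)
#' fit <- fit_transfer(camp, acetaminophen_system(fitted = FALSE),
#'                     scenario = 4, n_restarts = 10, seed = 1)
#' export_parameters(fit, acetaminophen())
#' }
#' @export
export_parameters <- function(fit, drug, n_cotyledons = 35,
                              total_villi_SA = 1178, fetal_albumin = 32,
                              reference_albumin = 47) {
  if (!inherits(fit, "transfer_fit")) stop_invalid("fit must be a transfer_fit")
  if (!inherits(drug, "drug_parameters")) stop_invalid("drug must be a drug_parameters object")
  if (n_cotyledons <= 0 || total_villi_SA <= 0) {
    stop_invalid("n_cotyledons and total_villi_SA must be > 0")
  }
  sys <- fit$system
  needed <- c("K_FM_cell_perf", "K_F_cell_perf", "K_F_int_perf", "K_M_int_perf",
              "f_in", "f_out")
  for (nm in needed) {
    if (is.null(sys[[nm]]) || !is.finite(sys[[nm]])) {
      abort(paste0("export failed: parameter '", nm,
                   "' is not available from the fitted system"),
            class = "cotyledonsim_export_error")
    }
  }
  fu_fetus_delivery <- scale_fraction_unbound(
    drug$fu_adult, binding_context(fetal_albumin, reference_albumin))
  structure(
    list(
      drug = drug$name,
      scenario = fit$scenario$name,
      K_FM_cell_perf = sys$K_FM_cell_perf,
      K_F_cell_perf = sys$K_F_cell_perf,
      K_F_int_perf = sys$K_F_int_perf,
      K_M_int_perf = sys$K_M_int_perf,
      f_in = sys$f_in,
      f_out = sys$f_out,
      P_dm_per_min = drug$P,
      P_eff_in_dm_per_min = sys$f_in * drug$P,
      P_eff_out_dm_per_min = sys$f_out * drug$P,
      total_villi_SA_dm2 = total_villi_SA,
      n_cotyledons = n_cotyledons,
      SA_per_cotyledon_dm2 = total_villi_SA / n_cotyledons,
      fetal_albumin_g_per_L = fetal_albumin,
      fu_fetus_delivery = fu_fetus_delivery,
      notes = paste("No cotyledon-derived parameter exists for the maternal",
                    "intracellular (decidua) compartment; the decidua is shed",
                    "during childbirth and absent from the perfused cotyledon.")
    ),
    class = "placenta_transfer"
  )
}

#' @export
print.placenta_transfer <- function(x, ...) {
  cat("<placenta_transfer>", x$drug, "/", x$scenario, "\n")
  cat(sprintf("  K (FM_cell, F_cell, F_int, M_int): %.4g, %.4g, %.4g, %.4g\n",
              x$K_FM_cell_perf, x$K_F_cell_perf, x$K_F_int_perf, x$K_M_int_perf))
  cat(sprintf("  f_in/f_out: %.4g / %.4g -> effective P %.4g / %.4g dm/min\n",
              x$f_in, x$f_out, x$P_eff_in_dm_per_min, x$P_eff_out_dm_per_min))
  cat(sprintf("  villi SA %.4g dm^2 over %d cotyledons (%.4g dm^2 each); fetal fu %.3f\n",
              x$total_villi_SA_dm2, x$n_cotyledons, x$SA_per_cotyledon_dm2,
              x$fu_fetus_delivery))
  invisible(x)
}

#' Write / read exported placental-transfer parameters
#'
#' `write_placenta_parameters()` writes a flat key/value/unit TSV (readable
#' by any PBPK platform) and a machine-readable JSON twin at
#' `paste0(path, ".json")`. `read_placenta_parameters()` restores the
#' object from the JSON twin; the round trip is lossless.
#'
#' @param x A `placenta_transfer` object.
#' @param path Output TSV path.
#' @return `write_placenta_parameters()` returns `path` invisibly;
#'   `read_placenta_parameters()` returns a `placenta_transfer`.
#' @export
write_placenta_parameters <- function(x, path) {
  stopifnot(inherits(x, "placenta_transfer"))
  units <- c(K_FM_cell_perf = "", K_F_cell_perf = "", K_F_int_perf = "",
             K_M_int_perf = "", f_in = "", f_out = "",
             P_dm_per_min = "dm/min", P_eff_in_dm_per_min = "dm/min",
             P_eff_out_dm_per_min = "dm/min", total_villi_SA_dm2 = "dm^2",
             n_cotyledons = "", SA_per_cotyledon_dm2 = "dm^2",
             fetal_albumin_g_per_L = "g/L", fu_fetus_delivery = "")
  num <- x[names(units)]
  tab <- tibble(key = names(units),
                value = vapply(num, as.numeric, numeric(1)),
                unit = unname(units))
  readr::write_tsv(tab, path)
  jsonlite::write_json(unclass(x), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_placenta_parameters
#' @export
read_placenta_parameters <- function(path) {
  json <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  obj <- jsonlite::read_json(json, simplifyVector = TRUE)
  structure(obj, class = "placenta_transfer")
}
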