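#' Tissue composition for partition-coefficient calculation
#'
#' Holds the interstitial/perfusate water and protein fractions used by the
#' interstitial:perfusate coefficient, and the cell composition block
#' (fractional water, neutral lipids, phospholipids, acidic phospholipids,
#' intracellular and perfusate pH) used by the Rodgers-Rowland method.
#'
#' @param f_water_int Fractional water content of interstitial space.
#' @param f_water_perf Fractional water (volume) content of perfusate.
#' @param protein_ratio_int_over_perf Interstitial:perfusate protein ratio.
#' @param f_water_cell Intracellular fractional water.
#' @param f_neutral_lipids Intracellular neutral-lipid fraction.
#' @param f_phospholipids Intracellular (neutral) phospholipid fraction.
#' @param f_acidic_phospholipids Intracellular acidic-phospholipid fraction
#'   (only relevant for strongly basic drugs, whose branch is not
#'   implemented here).
#' @param pH_cell Intracellular pH.
#' @param pH_perf Perfusate pH.
#' @return An object of class `tissue_composition`.
#' @seealso [placenta_composition()] for the bundled placental preset.
#' @export
tissue_composition <- function(f_water_int,
                               f_water_perf,
                               protein_ratio_int_over_perf,
                               f_water_cell = NA_real_,
                               f_neutral_lipids = NA_real_,
                               f_phospholipids = NA_real_,
                               f_acidic_phospholipids = NA_real_,
                               pH_cell = 7.0,
                               pH_perf = 7.4) {
  fracs <- c(f_water_int, f_water_perf, f_water_cell, f_neutral_lipids,
             f_phospholipids, f_acidic_phospholipids)
  if (any(fracs < 0 | fracs > 1, na.rm = TRUE)) {
    stop_invalid("all composition fractions must lie in [0, 1]")
  }
  if (protein_ratio_int_over_perf < 0) stop_invalid("protein ratio must be >= 0")
  if (any(c(pH_cell, pH_perf) < 0 | c(pH_cell, pH_perf) > 14, na.rm = TRUE)) {
    stop_invalid("pH must lie in [0, 14]")
  }
  structure(
    list(f_water_int = f_water_int, f_water_perf = f_water_perf,
         protein_ratio_int_over_perf = protein_ratio_int_over_perf,
         f_water_cell = f_water_cell, f_neutral_lipids = f_neutral_lipids,
         f_phospholipids = f_phospholipids,
         f_acidic_phospholipids = f_acidic_phospholipids,
         pH_cell = pH_cell, pH_perf = pH_perf),
    class = "tissue_composition"
  )
}

#' Placental tissue-composition preset
#'
#' Interstitial water 0.935, perfusate water 0.926 and an
#' interstitial:perfusate protein ratio of 0.37 (adult-tissue value). The
#' cellular (trophoblast) block — water 0.85, neutral lipids 0.010,
#' phospholipids 0.006, acidic phospholipids 5e-4, intracellular pH 7.0,
#' perfusate pH 7.4 — is a synthetic best-effort set assembled from typical
#' soft-tissue values, since a placenta-specific composition table is not
#' bundled; every field is overridable through the arguments of
#' [tissue_composition()].
#'
#' @param ... Overrides passed on to [tissue_composition()].
#' @return A `tissue_composition` object.
#' @export
placenta_composition <- function(...) {
  defaults <- list(
    f_water_int = 0.935,
    f_water_perf = 0.926,
    protein_ratio_int_over_perf = 0.37,
    f_water_cell = 0.85,
    f_neutral_lipids = 0.010,
    f_phospholipids = 0.006,
    f_acidic_phospholipids = 5e-4,
    pH_cell = 7.0,
    pH_perf = 7.4
  )
  do.call(tissue_composition, modifyList(defaults, list(...)))
}

#' Interstitial:perfusate partition coefficient
#'
#' Protein-binding-corrected water partitioning between interstitial space
#' and perfusate:
#' \deqn{K = \left(f_{w,int} + r \left(\tfrac{1}{f_u} - f_{w,perf}\right)\right) f_u}
#' with `r` the interstitial:perfusate protein ratio. For the fetal side the
#' fetal fraction unbound is inserted; for the maternal side the maternal
#' one (an approximation: the general composition-based expression reduces
#' to this form for protein-and-water interstitial tissue).
#'
#' @param comp A [tissue_composition()].
#' @param fu Fraction unbound in the perfusate, (0, 1].
#' @return Partition coefficient (strictly positive).
#' @examples
#' partition_interstitial_perfusate(placenta_composition(), fu = 0.88) # ~0.891
#' @export
partition_interstitial_perfusate <- function(comp, fu) {
  if (!inherits(comp, "tissue_composition")) stop_invalid("comp must be a tissue_composition")
  if (!is.numeric(fu) || any(fu <= 0) || any(fu > 1)) stop_invalid("fu must lie in (0, 1]")
  r <- comp$protein_ratio_int_over_perf
  (comp$f_water_int + r * (1 / fu - comp$f_water_perf)) * fu
}

#' Cell:perfusate partition coefficient (Rodgers-Rowland method)
#'
#' Computes the trophoblast(cell):perfusate partition coefficient from the
#' cellular composition block using the Rodgers-Rowland tissue-composition
#' equations for neutral compounds and weak electrolytes:
#' unbound tissue:water partitioning
#' \deqn{K_{pu} = f_{IW}\frac{X}{Y} + \frac{P\,f_{NL} + (0.3P + 0.7)\,f_{PL}}{Y}}
#' where `P = 10^logP`, `f_IW`, `f_NL`, `f_PL` are the intracellular water,
#' neutral-lipid and phospholipid fractions, and `X`, `Y` are the ionization
#' terms `1 + 10^(pH - pKa)` (acids) or `1 + 10^(pKa - pH)` (weak bases)
#' evaluated at intracellular and perfusate pH respectively (both 1 for
#' neutrals). The total cell:perfusate coefficient is `K = Kpu * fu`.
#'
#' Moderate-to-strong bases (basic pKa >= 7), whose partitioning is
#' dominated by acidic-phospholipid association, are outside the implemented
#' branch and raise an error, as do partition methods other than
#' `"rodgers"` (slots reserved).
#'
#' @param drug A [drug_parameters()] object (logP required; pKa and
#'   `pka_type` select the ionization branch).
#' @param comp A [tissue_composition()] with the cell block populated.
#' @param fu Fraction unbound in the reference perfusate, (0, 1].
#' @param method Partition method; only `"rodgers"` is implemented.
#' @return Cell:perfusate partition coefficient (positive).
#' @examples
#' partition_cell_perfusate(acetaminophen(), placenta_composition(), fu = 0.84)
#' @export
partition_cell_perfusate <- function(drug, comp, fu,
                                     method = c("rodgers", "schmitt", "poulin", "pksim_standard")) {
  method <- match.arg(method)
  if (method != "rodgers") {
    abort(paste0("partition method '", method, "' is not implemented (interface slot reserved)"),
          class = "cotyledonsim_not_implemented")
  }
  if (!inherits(drug, "drug_parameters")) stop_invalid("drug must be a drug_parameters object")
  if (!inherits(comp, "tissue_composition")) stop_invalid("comp must be a tissue_composition")
  if (!is.numeric(fu) || fu <= 0 || fu > 1) stop_invalid("fu must lie in (0, 1]")
  needed <- c("f_water_cell", "f_neutral_lipids", "f_phospholipids")
  missing <- needed[vapply(comp[needed], is.na, logical(1))]
  if (length(missing)) {
    stop_config(paste0("cell composition block incomplete; missing: ",
                       paste(missing, collapse = ", ")))
  }
  if (is.na(drug$logP)) stop_config("drug logP is required for the Rodgers method")

  Pow <- 10^drug$logP
  type <- drug$pka_type
  if (is.na(drug$pKa)) type <- "neutral"
  if (type == "base" && drug$pKa >= 7) {
    abort("moderate-to-strong bases (basic pKa >= 7) require the acidic-phospholipid branch, which is not implemented",
          class = "cotyledonsim_not_implemented")
  }
  ion <- function(pH) {
    switch(type,
           neutral = 1,
           acid = 1 + 10^(pH - drug$pKa),
           base = 1 + 10^(drug$pKa - pH))
  }
  X <- ion(comp$pH_cell)
  Y <- ion(comp$pH_perf)
  Kpu <- comp$f_water_cell * X / Y +
    (Pow * comp$f_neutral_lipids + (0.3 * Pow + 0.7) * comp$f_phospholipids) / Y
  Kpu * fu
}
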