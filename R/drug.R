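#' Drug physicochemical and binding parameters
#'
#' Container for the compound-specific inputs of the perfusion model: the
#' adult fraction unbound, the transcellular membrane permeability `P`, and
#' the endothelial permeability `P_endo`. Optional descriptors (pKa and its
#' acid/base type, lipophilicity, molecular weight) feed the
#' partition-coefficient calculation.
#'
#' Permeabilities are stored in dm/min (the model's canonical length/time
#' unit); `permeability_unit` lets you supply them in cm/min as usually
#' tabulated.
#'
#' @param name Compound name.
#' @param fu_adult Adult plasma fraction unbound, in (0, 1].
#' @param membrane_permeability Transcellular membrane permeability `P`.
#' @param endothelial_permeability Endothelial permeability `P_endo`
#'   (assumed non-rate-limiting for most organs).
#' @param permeability_unit Unit both permeabilities are supplied in
#'   (`"dm/min"` or `"cm/min"`).
#' @param pKa Ionization constant (optional; needed for the ionized branches
#'   of the Rodgers partition method).
#' @param pka_type `"neutral"`, `"acid"` or `"base"`.
#' @param logP Octanol-water log partition coefficient (optional).
#' @param molecular_weight g/mol (optional, informational).
#' @return An object of class `drug_parameters`.
#' @seealso [acetaminophen()] for the bundled preset.
#' @export
drug_parameters <- function(name,
                            fu_adult,
                            membrane_permeability,
                            endothelial_permeability,
                            permeability_unit = "dm/min",
                            pKa = NA_real_,
                            pka_type = c("neutral", "acid", "base"),
                            logP = NA_real_,
                            molecular_weight = NA_real_) {
  pka_type <- match.arg(pka_type)
  if (!is.numeric(fu_adult) || length(fu_adult) != 1 || is.na(fu_adult) ||
      fu_adult <= 0 || fu_adult > 1) {
    stop_invalid("fu_adult must be a single value in (0, 1]")
  }
  P <- to_canonical(membrane_permeability, permeability_unit, "permeability")
  P_endo <- to_canonical(endothelial_permeability, permeability_unit, "permeability")
  if (P <= 0 || P_endo <= 0) stop_invalid("permeabilities must be > 0")
  if (!is.na(pKa) && (pKa < 0 || pKa > 14)) stop_invalid("pKa must lie in [0, 14]")
  structure(
    list(name = name, fu_adult = fu_adult, P = P, P_endo = P_endo,
         pKa = pKa, pka_type = pka_type, logP = logP,
         molecular_weight = molecular_weight),
    class = "drug_parameters"
  )
}

#' Acetaminophen parameter preset
#'
#' Adult fraction unbound 0.82, membrane permeability 4.29e-2 cm/min,
#' endothelial permeability 100 cm/min; weak acid (phenolic pKa 9.38),
#' logP 0.46, MW 151.16 g/mol.
#'
#' @return A [drug_parameters()] object.
#' @export
acetaminophen <- function() {
  drug_parameters(
    name = "acetaminophen",
    fu_adult = 0.82,
    membrane_permeability = 4.29e-2,
    endothelial_permeability = 100,
    permeability_unit = "cm/min",
    pKa = 9.38,
    pka_type = "acid",
    logP = 0.46,
    molecular_weight = 151.16
  )
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters> ", x$name, "\n", sep = "")
  cat("  fu (adult):       ", x$fu_adult, "\n", sep = "")
  cat("  P (membrane):     ", signif(x$P, 4), " dm/min\n", sep = "")
  cat("  P_endo:           ", signif(x$P_endo, 4), " dm/min\n", sep = "")
  if (!is.na(x$pKa)) cat("  pKa: ", x$pKa, " (", x$pka_type, ")\n", sep = "")
  invisible(x)
}

#' Albumin binding context
#'
#' Pairs a fluid's albumin concentration with the reference concentration at
#' which the adult fraction unbound was measured; both in g/L. Bovine serum
#' albumin in perfusate and human albumin are treated as equivalent binders.
#'
#' @param albumin Albumin concentration of the fluid of interest (g/L).
#' @param reference_albumin Albumin concentration the reference fu refers to
#'   (g/L, default 47).
#' @return An object of class `binding_context`.
#' @export
binding_context <- function(albumin, reference_albumin = 47) {
  if (!is.numeric(albumin) || albumin < 0 || !is.numeric(reference_albumin) ||
      reference_albumin < 0) {
    stop_invalid("albumin concentrations must be non-negative")
  }
  structure(list(albumin = albumin, reference_albumin = reference_albumin),
            class = "binding_context")
}

#' Scale the fraction unbound to a different albumin concentration
#'
#' Under linear (non-saturated) albumin binding the bound:free ratio is
#' proportional to the binder concentration, so
#' \deqn{f_u = \frac{1}{1 + (A/A_{ref}) \cdot (1 - f_{u,ref})/f_{u,ref}}.}
#' At `A = A_ref` the reference value is returned; at `A = 0` binding
#' vanishes and the result is 1; the function is strictly decreasing in `A`.
#'
#' For acetaminophen (adult fu 0.82, reference albumin 47 g/L) the maternal
#' and fetal perfusate albumin concentrations of 40 and 30 g/L give 0.84 and
#' 0.88 respectively.
#'
#' @param fu_ref Reference fraction unbound, in (0, 1].
#' @param ctx A [binding_context()].
#' @return The scaled fraction unbound.
#' @examples
#' scale_fraction_unbound(0.82, binding_context(40)) # ~0.84
#' scale_fraction_unbound(0.82, binding_context(30)) # ~0.88
#' @export
scale_fraction_unbound <- function(fu_ref, ctx) {
  if (!inherits(ctx, "binding_context")) stop_invalid("ctx must be a binding_context")
  if (!is.numeric(fu_ref) || any(is.na(fu_ref)) || any(fu_ref <= 0) || any(fu_ref > 1)) {
    stop_invalid("fu_ref must lie in (0, 1]")
  }
  if (ctx$reference_albumin == 0) {
    # reference fluid has no binder: fu_ref must be 1 and so is the result
    if (any(fu_ref < 1)) stop_invalid("fu_ref < 1 is inconsistent with a zero reference albumin")
    return(rep(1, length(fu_ref)))
  }
  ratio <- ctx$albumin / ctx$reference_albumin
  1 / (1 + ratio * (1 - fu_ref) / fu_ref)
}

#' Water-to-tissue partition coefficient
#'
#' The driving free-water concentration gradient across a membrane uses the
#' water:tissue coefficient `fu / K`, where `K` is the tissue:perfusate
#' partition coefficient and `fu` the fraction unbound in the perfusate the
#' coefficient is referenced to.
#'
#' @param fu Fraction unbound in the reference perfusate, (0, 1].
#' @param K Tissue:perfusate partition coefficient, > 0.
#' @return `fu / K`.
#' @export
water_partition <- function(fu, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop_invalid("K must be > 0")
  if (any(fu <= 0) || any(fu > 1)) stop_invalid("fu must lie in (0, 1]")
  fu / K
}
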