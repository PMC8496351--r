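#' Perfusion-system parameterization
#'
#' Assembles the full parameter set of the seven-compartment cotyledon
#' perfusion model: perfusate flows, reservoir and cotyledon volumes,
#' exchange surface areas, fractions unbound, partition coefficients and the
#' directional apical transfer factors `f_in` / `f_out`.
#'
#' Defaults reproduce the acetaminophen assay configuration: maternal /
#' fetal flows 14 / 6 mL/min, reservoir volumes 280 / 284 mL, intervillous /
#' intravillous cotyledon volumes 23 / 35 mL, villous surface area
#' 1178/35 dm^2 per cotyledon. The intervillous volume splits into maternal
#' perfusate and interstitial sub-compartments (default 0.80/0.20), the
#' intravillous volume into trophoblast, interstitial and fetal-capillary
#' perfusate (default 0.50/0.30/0.20); these splits shape the fast
#' transients only, not steady-state levels. Surface areas of the
#' perfusate:interstitial and interstitial:cell interfaces default to
#' `sa_density` (dm^2 per L) times the adjoining tissue sub-volume.
#'
#' Fractions unbound default to albumin-ratio scaling of the drug's adult
#' value at the perfusate albumin concentrations (40 g/L maternal, 30 g/L
#' fetal, reference 47 g/L). Interstitial partition coefficients default to
#' [partition_interstitial_perfusate()] with the side-specific fu; the
#' trophoblast coefficients default to the Rodgers method via
#' [partition_cell_perfusate()].
#'
#' @param drug A [drug_parameters()] object.
#' @param Q_M,Q_F Maternal/fetal perfusate flow (L/min).
#' @param V_M_res,V_F_res Reservoir volumes (L).
#' @param V_intervillous,V_intravillous Cotyledon side volumes (L).
#' @param intervillous_fractions Named fractions `c(perfusate=, interstitial=)`
#'   splitting the intervillous volume; must sum to 1, all > 0.
#' @param intravillous_fractions Named fractions
#'   `c(trophoblast=, interstitial=, perfusate=)`; must sum to 1, all > 0.
#' @param sa_density Surface-area density (dm^2 per L of tissue sub-volume)
#'   used for defaulted interface areas.
#' @param SA_Mperf_int,SA_Fperf_int,SA_Fint_cell,SA_villi Interface surface
#'   areas (dm^2); `NULL` means use the default rule.
#' @param albumin_maternal,albumin_fetal,reference_albumin Albumin
#'   concentrations (g/L) used when `fu`/`fu_fetus` are defaulted.
#' @param fu,fu_fetus Fractions unbound in maternal/fetal perfusate; `NULL`
#'   means scale from `drug$fu_adult`.
#' @param composition A [tissue_composition()] used for defaulted partition
#'   coefficients.
#' @param K_M_int_perf,K_F_int_perf Interstitial:perfusate coefficients.
#' @param K_F_cell_perf,K_FM_cell_perf Trophoblast:perfusate coefficients at
#'   the basolateral and apical membrane.
#' @param f_in,f_out Dimensionless factors scaling the apical permeability
#'   in the maternal-to-fetal and fetal-to-maternal direction.
#' @return An object of class `perfusion_system`.
#' @examples
#' sys <- perfusion_system()
#' compartment_volumes(sys)
#' @export
perfusion_system <- function(drug = acetaminophen(),
                             Q_M = 0.014, Q_F = 0.006,
                             V_M_res = 0.280, V_F_res = 0.284,
                             V_intervillous = 0.023, V_intravillous = 0.035,
                             intervillous_fractions = c(perfusate = 0.80, interstitial = 0.20),
                             intravillous_fractions = c(trophoblast = 0.50, interstitial = 0.30, perfusate = 0.20),
                             sa_density = 1000,
                             SA_Mperf_int = NULL, SA_Fperf_int = NULL,
                             SA_Fint_cell = NULL, SA_villi = 1178 / 35,
                             albumin_maternal = 40, albumin_fetal = 30,
                             reference_albumin = 47,
                             fu = NULL, fu_fetus = NULL,
                             composition = placenta_composition(),
                             K_M_int_perf = NULL, K_F_int_perf = NULL,
                             K_F_cell_perf = NULL, K_FM_cell_perf = NULL,
                             f_in = 1, f_out = 1) {
  if (!inherits(drug, "drug_parameters")) stop_invalid("drug must be a drug_parameters object")
  pos <- c(Q_M = Q_M, Q_F = Q_F, V_M_res = V_M_res, V_F_res = V_F_res,
           V_intervillous = V_intervillous, V_intravillous = V_intravillous,
           SA_villi = SA_villi)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop_invalid("flows, volumes and SA_villi must be strictly positive")
  }
  if (abs(sum(intervillous_fractions) - 1) > 1e-10 ||
      abs(sum(intravillous_fractions) - 1) > 1e-10) {
    stop_config("sub-volume fractions on each side must sum to 1")
  }
  if (any(intervillous_fractions <= 0) || any(intravillous_fractions <= 0)) {
    stop_config("sub-volume fractions must all be strictly positive (a zero sub-compartment is degenerate)")
  }
  if (f_in < 0 || f_out < 0) stop_invalid("f_in and f_out must be >= 0")

  if (is.null(fu)) {
    fu <- scale_fraction_unbound(drug$fu_adult, binding_context(albumin_maternal, reference_albumin))
  }
  if (is.null(fu_fetus)) {
    fu_fetus <- scale_fraction_unbound(drug$fu_adult, binding_context(albumin_fetal, reference_albumin))
  }
  if (fu <= 0 || fu > 1 || fu_fetus <= 0 || fu_fetus > 1) {
    stop_invalid("fu and fu_fetus must lie in (0, 1]")
  }

  if (is.null(K_M_int_perf)) K_M_int_perf <- partition_interstitial_perfusate(composition, fu)
  if (is.null(K_F_int_perf)) K_F_int_perf <- partition_interstitial_perfusate(composition, fu_fetus)
  if (is.null(K_F_cell_perf)) K_F_cell_perf <- partition_cell_perfusate(drug, composition, fu)
  if (is.null(K_FM_cell_perf)) K_FM_cell_perf <- K_F_cell_perf
  Ks <- c(K_M_int_perf, K_F_int_perf, K_F_cell_perf, K_FM_cell_perf)
  if (any(!is.finite(Ks)) || any(Ks <= 0)) stop_invalid("all partition coefficients must be > 0")

  V_M_perf <- V_intervillous * intervillous_fractions[["perfusate"]]
  V_M_int <- V_intervillous * intervillous_fractions[["interstitial"]]
  V_F_cell <- V_intravillous * intravillous_fractions[["trophoblast"]]
  V_F_int <- V_intravillous * intravillous_fractions[["interstitial"]]
  V_F_perf <- V_intravillous * intravillous_fractions[["perfusate"]]

  if (is.null(SA_Mperf_int)) SA_Mperf_int <- sa_density * V_M_int
  if (is.null(SA_Fperf_int)) SA_Fperf_int <- sa_density * V_F_int
  if (is.null(SA_Fint_cell)) SA_Fint_cell <- sa_density * V_F_cell
  SAs <- c(SA_Mperf_int, SA_Fperf_int, SA_Fint_cell)
  if (any(SAs <= 0)) stop_invalid("surface areas must be > 0")

  structure(
    list(drug = drug,
         Q_M = Q_M, Q_F = Q_F,
         volumes = setNames(c(V_M_res, V_M_perf, V_M_int, V_F_cell,
                              V_F_int, V_F_perf, V_F_res), COMPARTMENTS),
         V_intervillous = V_intervillous, V_intravillous = V_intravillous,
         intervillous_fractions = intervillous_fractions,
         intravillous_fractions = intravillous_fractions,
         SA_Mperf_int = SA_Mperf_int, SA_Fperf_int = SA_Fperf_int,
         SA_Fint_cell = SA_Fint_cell, SA_villi = SA_villi,
         fu = fu, fu_fetus = fu_fetus,
         K_M_int_perf = K_M_int_perf, K_F_int_perf = K_F_int_perf,
         K_F_cell_perf = K_F_cell_perf, K_FM_cell_perf = K_FM_cell_perf,
         f_in = f_in, f_out = f_out,
         albumin_maternal = albumin_maternal, albumin_fetal = albumin_fetal,
         reference_albumin = reference_albumin),
    class = "perfusion_system"
  )
}

#' Acetaminophen perfusion system
#'
#' Convenience constructor for the acetaminophen assay system, either with
#' the a-priori transfer parameters (`fitted = FALSE`: symmetric transfer
#' `f_in = f_out = 1` and Rodgers-method trophoblast partitioning) or with
#' the transfer parameter set estimated from the perfusion data
#' (`fitted = TRUE`: shared trophoblast partition coefficient 4.31,
#' `f_in = 0.060`, `f_out = 0.051`).
#'
#' @param fitted Use the fitted transfer parameter set?
#' @param ... Further overrides passed to [perfusion_system()].
#' @return A `perfusion_system`.
#' @export
acetaminophen_system <- function(fitted = TRUE, ...) {
  if (fitted) {
    perfusion_system(K_F_cell_perf = 4.31, K_FM_cell_perf = 4.31,
                     f_in = 0.060, f_out = 0.051, ...)
  } else {
    perfusion_system(...)
  }
}

#' Compartment volumes
#'
#' Reservoir volumes are passed through; the cotyledon sub-volumes are the
#' side volumes times their sub-volume fractions, so the five cotyledon
#' volumes sum to `V_intervillous + V_intravillous`.
#'
#' @param sys A [perfusion_system()].
#' @return A tibble with columns `compartment` and `volume_L`, in canonical
#'   compartment order.
#' @export
compartment_volumes <- function(sys) {
  stopifnot(inherits(sys, "perfusion_system"))
  tibble(compartment = factor(COMPARTMENTS, levels = COMPARTMENTS),
         volume_L = unname(sys$volumes))
}

#' @export
print.perfusion_system <- function(x, ...) {
  cat("<perfusion_system> drug:", x$drug$name, "\n")
  cat(sprintf("  flows Q_M/Q_F: %.3f / %.3f L/min; reservoirs %.3f / %.3f L\n",
              x$Q_M, x$Q_F, x$volumes[["M_res"]], x$volumes[["F_res"]]))
  cat(sprintf("  fu / fu_fetus: %.3f / %.3f\n", x$fu, x$fu_fetus))
  cat(sprintf("  K (M_int, F_int, F_cell, FM_cell): %.3f, %.3f, %.3f, %.3f\n",
              x$K_M_int_perf, x$K_F_int_perf, x$K_F_cell_perf, x$K_FM_cell_perf))
  cat(sprintf("  f_in / f_out: %.4g / %.4g; SA_villi %.2f dm^2\n",
              x$f_in, x$f_out, x$SA_villi))
  invisible(x)
}

#' Experiment design
#'
#' Dosing side, initial reservoir concentration, duration and the sampling
#' schedule of one perfusion experiment.
#'
#' @param dosing_side `"maternal"` or `"fetal"`.
#' @param initial_concentration Initial concentration in the dosed reservoir
#'   (mg/L, default 10).
#' @param duration Experiment duration (min).
#' @param sampling_times Strictly increasing times within `[0, duration]`
#'   (min); defaults to [default_schedule()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(dosing_side = c("maternal", "fetal"),
                              initial_concentration = 10,
                              duration = 180,
                              sampling_times = default_schedule()) {
  dosing_side <- match.arg(dosing_side)
  if (initial_concentration <= 0) stop_invalid("initial_concentration must be > 0")
  if (duration <= 0) stop_invalid("duration must be > 0")
  if (length(sampling_times) == 0 || any(diff(sampling_times) <= 0) ||
      min(sampling_times) < 0 || max(sampling_times) > duration) {
    stop_invalid("sampling_times must be strictly increasing within [0, duration]")
  }
  structure(list(dosing_side = dosing_side,
                 initial_concentration = initial_concentration,
                 duration = duration,
                 sampling_times = sampling_times),
            class = "experiment_design")
}

#' Default sampling schedule
#'
#' Fifteen sampling times over a 3-hour run, dense during wash-in and
#' sparser toward the plateau: 0, 2, 5, 10, 15, 20, 30, 45, 60, 75, 90,
#' 105, 120, 150, 180 min.
#'
#' @return Numeric vector of minutes.
#' @export
default_schedule <- function() {
  c(0, 2, 5, 10, 15, 20, 30, 45, 60, 75, 90, 105, 120, 150, 180)
}
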