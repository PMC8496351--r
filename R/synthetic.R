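#' Measurement-noise model
#'
#' Multiplicative lognormal noise with a given coefficient of variation, the
#' typical shape of bioanalytical assay error: an observation is the model
#' concentration times `exp(rnorm(1, 0, s))` with `s = sqrt(log(1 + cv^2))`
#' (the standard proportional-error model), so the noise multiplier has
#' median 1 and CV `cv`. `kind = "none"` returns the model output
#' unchanged.
#'
#' @param kind `"lognormal_multiplicative"` or `"none"`.
#' @param cv Coefficient of variation (fraction, default 0.10).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal_multiplicative", "none"), cv = 0.10) {
  kind <- match.arg(kind)
  if (cv < 0) stop_invalid("cv must be >= 0")
  structure(list(kind = kind, cv = cv), class = "noise_model")
}

.apply_noise <- function(conc, noise) {
  if (noise$kind == "none" || noise$cv == 0) return(conc)
  s <- sqrt(log(1 + noise$cv^2))
  conc * exp(stats::rnorm(length(conc), mean = 0, sd = s))
}

#' Campaign specification
#'
#' Describes a full synthetic perfusion campaign in the style of the
#' acetaminophen assay series: 14 experiments (10 dosed to the maternal
#' reservoir, 4 to the fetal reservoir), initial concentration 10 mg/L,
#' both reservoirs sampled on the default 15-point 0-180 min schedule
#' (28 series, 420 values), with 10% multiplicative lognormal noise. The
#' generating ("truth") system defaults to the fitted acetaminophen
#' parameter set ([acetaminophen_system()]).
#'
#' @param n_maternal,n_fetal Numbers of maternal-dosed and fetal-dosed
#'   experiments.
#' @param sampling_times Strictly increasing schedule (min).
#' @param initial_concentration Dose concentration (mg/L).
#' @param system Generating [perfusion_system()] (recorded as truth).
#' @param noise A [noise_model()].
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_maternal = 10, n_fetal = 4,
                          sampling_times = default_schedule(),
                          initial_concentration = 10,
                          system = acetaminophen_system(),
                          noise = noise_model()) {
  if (n_maternal < 0 || n_fetal < 0) stop_invalid("experiment counts must be >= 0")
  if (length(sampling_times) && any(diff(sampling_times) <= 0)) {
    stop_invalid("sampling_times must be strictly increasing")
  }
  if (initial_concentration <= 0) stop_invalid("initial_concentration must be > 0")
  stopifnot(inherits(system, "perfusion_system"), inherits(noise, "noise_model"))
  structure(list(n_maternal = n_maternal, n_fetal = n_fetal,
                 sampling_times = sampling_times,
                 initial_concentration = initial_concentration,
                 system = system, noise = noise),
            class = "campaign_spec")
}

#' Generate one synthetic perfusion experiment
#'
#' Simulates the truth system for the design, samples both reservoirs at
#' the schedule times and applies the noise model. With `noise = "none"`
#' the output equals the simulation exactly.
#'
#' @param design An [experiment_design()].
#' @param sys The generating [perfusion_system()].
#' @param noise A [noise_model()].
#' @param experiment_id Identifier written into the series.
#' @param seed Optional integer seed (global RNG is untouched).
#' @return A tibble with the observed-data columns (`experiment_id`,
#'   `dosing_side`, `sampled_reservoir`, `time_min`, `conc_mg_per_L`):
#'   one maternal and one fetal reservoir series.
#' @export
generate_experiment <- function(design, sys, noise = noise_model(),
                                experiment_id = "exp1", seed = NULL) {
  gen <- function() {
    sim <- simulate_perfusion(sys, design, method = "eigen")
    res <- dplyr::filter(sim, .data$compartment %in% c("M_res", "F_res"))
    tibble(
      experiment_id = experiment_id,
      dosing_side = design$dosing_side,
      sampled_reservoir = ifelse(res$compartment == "M_res", "maternal", "fetal"),
      time_min = res$time_min,
      conc_mg_per_L = .apply_noise(res$conc_mg_per_L, noise)
    ) |>
      dplyr::arrange(.data$sampled_reservoir, .data$time_min)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic perfusion campaign
#'
#' Generates every experiment of a [campaign_spec()] (maternal-dosed first,
#' ids `M01`, `M02`, ..., then fetal-dosed `F01`, ...), each contributing a
#' maternal and a fetal reservoir series. The generating parameters are
#' attached as the `truth` attribute (named list with the transfer
#' parameters and the full system) so recovery can be checked.
#'
#' @param spec A [campaign_spec()].
#' @param seed Optional integer seed for the noise draws.
#' @return A tibble of observed-data rows with attributes `truth` and
#'   `spec`.
#' @examples
#' camp <- generate_campaign(campaign_spec(n_maternal = 2, n_fetal = 1), seed = 7)
#' dplyr::count(camp, experiment_id, sampled_reservoir)
#' @export
generate_campaign <- function(spec = campaign_spec(), seed = NULL) {
  stopifnot(inherits(spec, "campaign_spec"))
  gen <- function() {
    designs <- c(
      rep("maternal", spec$n_maternal),
      rep("fetal", spec$n_fetal)
    )
    ids <- c(sprintf("M%02d", seq_len(spec$n_maternal)),
             sprintf("F%02d", seq_len(spec$n_fetal)))
    if (length(designs) == 0) {
      return(tibble(experiment_id = character(), dosing_side = character(),
                    sampled_reservoir = character(), time_min = numeric(),
                    conc_mg_per_L = numeric()))
    }
    purrr::map2(designs, ids, function(side, id) {
      design <- experiment_design(side, spec$initial_concentration,
                                  duration = max(spec$sampling_times, 1),
                                  sampling_times = spec$sampling_times)
      generate_experiment(design, spec$system, spec$noise, experiment_id = id)
    }) |>
      dplyr::bind_rows()
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  truth <- list(
    K_FM_cell_perf = spec$system$K_FM_cell_perf,
    K_F_cell_perf = spec$system$K_F_cell_perf,
    f_in = spec$system$f_in,
    f_out = spec$system$f_out,
    system = spec$system
  )
  structure(out, truth = truth, spec = spec, seed = seed)
}

#' Truth record of a synthetic campaign
#'
#' @param campaign A tibble returned by [generate_campaign()].
#' @return The generating-parameter list attached at generation time.
#' @export
campaign_truth <- function(campaign) {
  truth <- attr(campaign, "truth")
  if (is.null(truth)) stop_invalid("no truth record attached to this campaign")
  truth
}
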