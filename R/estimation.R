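#' Optimization scenarios
#'
#' Four nested parameterizations of placental transfer are supported, all
#' fitted to reservoir concentration-time data:
#' \describe{
#'   \item{1, `"S1_symmetric_f"`}{one shared factor `f = f_in = f_out`
#'     (symmetric apical transfer); partition coefficients fixed.}
#'   \item{2, `"S2_asymmetric_f"`}{`f_in` and `f_out` fitted separately;
#'     partition coefficients fixed.}
#'   \item{3, `"S3_symmetric_f_plus_K"`}{shared `f` plus a shared
#'     trophoblast partition coefficient `K = K_FM_cell:perf = K_F_cell:perf`
#'     (allows accumulation in the trophoblasts).}
#'   \item{4, `"S4_asymmetric_f_plus_K"`}{`f_in`, `f_out` and the shared
#'     trophoblast `K` all free.}
#' }
#'
#' @param scenario Integer 1-4 or one of the scenario names.
#' @return A list with elements `id`, `name`, `params` (free parameter
#'   names).
#' @export
fit_scenario <- function(scenario) {
  names <- c("S1_symmetric_f", "S2_asymmetric_f",
             "S3_symmetric_f_plus_K", "S4_asymmetric_f_plus_K")
  params <- list(c("f"), c("f_in", "f_out"), c("f", "K"), c("f_in", "f_out", "K"))
  if (is.numeric(scenario)) {
    if (!scenario %in% 1:4) stop_invalid("scenario must be 1, 2, 3 or 4")
    id <- as.integer(scenario)
  } else {
    id <- match(match.arg(scenario, names), names)
  }
  list(id = id, name = names[id], params = params[[id]])
}

.apply_scenario <- function(sys, params) {
  if ("f" %in% names(params)) {
    sys$f_in <- sys$f_out <- params[["f"]]
  }
  if ("f_in" %in% names(params)) sys$f_in <- params[["f_in"]]
  if ("f_out" %in% names(params)) sys$f_out <- params[["f_out"]]
  if ("K" %in% names(params)) {
    sys$K_FM_cell_perf <- sys$K_F_cell_perf <- params[["K"]]
  }
  sys
}

.check_observed <- function(data) {
  needed <- c("experiment_id", "dosing_side", "sampled_reservoir", "time_min",
              "conc_mg_per_L")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop_invalid(paste0("observed data lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) stop_invalid("observed data is empty")
  if (!all(data$dosing_side %in% c("maternal", "fetal")) ||
      !all(data$sampled_reservoir %in% c("maternal", "fetal"))) {
    stop_invalid("dosing_side and sampled_reservoir must be 'maternal' or 'fetal'")
  }
  if (any(data$conc_mg_per_L < 0)) stop_invalid("observed concentrations must be >= 0")
  invisible(data)
}

#' Model predictions at observed design points
#'
#' Simulates the model once per dosing side (the system is shared across
#' experiments) and returns the predicted reservoir concentration for every
#' row of an observed-data table.
#'
#' @param data Observed data tibble (columns `experiment_id`, `dosing_side`,
#'   `sampled_reservoir`, `time_min`, `conc_mg_per_L`).
#' @param sys A [perfusion_system()].
#' @param initial_concentration Dose concentration common to all
#'   experiments (mg/L).
#' @param method Solver passed to [simulate_perfusion()].
#' @return The input tibble with a `pred_mg_per_L` column appended.
#' @export
predict_observed <- function(data, sys, initial_concentration = 10,
                             method = "eigen") {
  .check_observed(data)
  A <- .ode_matrix(sys)
  pred <- numeric(nrow(data))
  for (side in unique(data$dosing_side)) {
    idx <- which(data$dosing_side == side)
    times <- sort(unique(data$time_min[idx]))
    design <- experiment_design(side, initial_concentration,
                                duration = max(times, 1), sampling_times = times)
    N0 <- .initial_state(sys, design)
    amounts <- if (method == "eigen") {
      .solve_eigen(A, N0, times)
    } else {
      .solve_lsoda(A, N0, times, 1e-8, 1e-10)
    }
    conc <- amounts / unname(sys$volumes)
    row_of <- c(maternal = 1L, fetal = 7L) # M_res / F_res
    ti <- match(data$time_min[idx], times)
    pred[idx] <- conc[cbind(row_of[data$sampled_reservoir[idx]], ti)]
  }
  data$pred_mg_per_L <- pred
  data
}

#' Relative-error objective
#'
#' Loss over all series and time points. Two residual conventions are
#' available: `"relative"`, `sum(((pred - obs)/obs)^2)`, and `"log_ratio"`,
#' `sum(log(pred/obs)^2)`, which is the least-squares form matching a
#' multiplicative lognormal error model and is what [fit_transfer()]
#' minimizes by default (the two agree to second order for small errors).
#' Either way, relative weighting keeps the washed-in and washing-in
#' reservoir, which differ by orders of magnitude early on, comparably
#' influential. Observations equal to zero (e.g. the t = 0 sample of the
#' un-dosed reservoir) carry no relative-error information and are
#' excluded; their count is reported via the `n_excluded` attribute. A
#' failed simulation scores a large penalty (1e10) with a warning rather
#' than aborting the search.
#'
#' @param params Named numeric vector of scenario parameters (`f`, `f_in`,
#'   `f_out`, `K` as applicable).
#' @param data Observed data tibble.
#' @param sys Base [perfusion_system()]; fixed parameters are taken from it.
#' @param initial_concentration Dose concentration (mg/L).
#' @param type Residual convention, `"relative"` or `"log_ratio"`.
#' @return Scalar loss (lower is better), with attributes `n` (points used)
#'   and `n_excluded`.
#' @export
transfer_objective <- function(params, data, sys, initial_concentration = 10,
                               type = c("relative", "log_ratio")) {
  type <- match.arg(type)
  r <- tryCatch(
    .fit_residuals(params, data, sys, initial_concentration, type),
    error = function(e) {
      warn(paste0("simulation failed during objective evaluation: ",
                  conditionMessage(e)))
      NULL
    })
  if (is.null(r) || any(!is.finite(r))) {
    return(structure(1e10, n = 0L, n_excluded = 0L))
  }
  n_excl <- sum(data$conc_mg_per_L <= 0)
  structure(sum(r^2), n = length(r), n_excluded = n_excl)
}

.default_bounds <- function(param_names) {
  lower <- c(f = 1e-4, f_in = 1e-4, f_out = 1e-4, K = 0.01)
  upper <- c(f = 10, f_in = 10, f_out = 10, K = 100)
  list(lower = lower[param_names], upper = upper[param_names])
}

#' Fit placental transfer parameters
#'
#' Multi-start stochastic estimation of the scenario's free parameters from
#' reservoir concentration-time data. Starting points are drawn log-uniform
#' within the bounds; the objective ([transfer_objective()]) is evaluated at
#' every start, the best `polish_top` starts are refined by bounded Levenberg-Marquardt
#' least squares on the log-parameter scale, and the winner receives one
#' further polish round. With a
#' fixed `seed` the result is bitwise reproducible.
#'
#' 95% confidence intervals are linearized: the Jacobian of the fit
#' residuals is computed by central finite differences at the optimum,
#' `cov = sigma^2 (J'J)^{-1}` with `sigma^2 = loss/(n - p)`, and half-widths
#' are `1.96 * se`. A singular Jacobian is flagged (`ci_ok = FALSE`, CIs
#' `NA`) rather than silently returned. The estimate correlation matrix is
#' reported and a warning is raised when any `|r| > 0.95` (weakly
#' identified pair, e.g. transfer factors vs. partition coefficient).
#'
#' @param data Observed data tibble (see [read_observed()] for the format).
#' @param sys Base [perfusion_system()] supplying all fixed parameters.
#' @param scenario Scenario id 1-4 or name (see [fit_scenario()]).
#' @param n_restarts Number of random multi-starts (default 50).
#' @param seed Integer seed; recorded in the result.
#' @param bounds Optional list with named `lower`/`upper` vectors.
#' @param initial_concentration Dose concentration (mg/L).
#' @param polish_top How many of the best starts to refine locally.
#' @param extra_starts Optional list of named parameter vectors added to the
#'   start set (e.g. the optimum of a nested scenario).
#' @param compute_ci Compute linearized confidence intervals?
#' @param loss Residual convention minimized (see [transfer_objective()]);
#'   the default `"log_ratio"` matches the lognormal error model of typical
#'   assay data and of the synthetic campaigns.
#' @return An object of class `transfer_fit`: scenario, `estimates`, `se`,
#'   `ci95` (half-widths), `correlation`, `objective`, `n_obs`,
#'   `n_excluded`, `n_restarts`, `seed`, `convergence`, and the fitted
#'   `system`.
#' @examples
#' \donttest{
#' camp <- generate_campaign(campaign_spec(n_maternal = 2, n_fetal = 1), seed = 1)
#' fit <- fit_transfer(camp, acetaminophen_system(fitted = FALSE),
#'                     scenario = 4, n_restarts = 10, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_transfer <- function(data, sys, scenario = 4, n_restarts = 50,
                         seed = NULL, bounds = NULL,
                         initial_concentration = 10, polish_top = 5,
                         extra_starts = NULL, compute_ci = TRUE,
                         loss = c("log_ratio", "relative")) {
  loss <- match.arg(loss)
  .check_observed(data)
  sc <- fit_scenario(scenario)
  p <- length(sc$params)
  b <- .default_bounds(sc$params)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  if (any(b$lower <= 0) || any(b$upper <= b$lower)) {
    stop_invalid("bounds must be positive with upper > lower")
  }

  obj <- function(theta) {
    as.numeric(transfer_objective(setNames(theta, sc$params), data, sys,
                                  initial_concentration, type = loss))
  }
  resid_log <- function(lt) {
    r <- tryCatch(
      .fit_residuals(setNames(exp(lt), sc$params), data, sys,
                     initial_concentration, loss),
      error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e5, nrow(data)) else r
  }

  run <- function() {
    starts <- matrix(exp(runif(n_restarts * p, rep(log(b$lower), each = n_restarts),
                               rep(log(b$upper), each = n_restarts))),
                     nrow = n_restarts, dimnames = list(NULL, sc$params))
    if (!is.null(extra_starts)) {
      extra <- do.call(rbind, lapply(extra_starts, function(s) s[sc$params]))
      starts <- rbind(starts, extra)
    }
    vals <- apply(starts, 1, obj)
    ord <- order(vals)
    best <- list(value = vals[ord[1]], par_log = log(starts[ord[1], ]),
                 convergence = 1L)
    for (i in head(ord, polish_top)) {
      res <- .polish(resid_log, log(starts[i, ]), log(b$lower), log(b$upper))
      if (res$value < best$value) best <- res
    }
    # one more polish round from the winner tightens the optimum
    res <- .polish(resid_log, best$par_log, log(b$lower), log(b$upper))
    if (res$value < best$value) best <- res
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (!is.finite(best$value) || best$value >= 1e10) {
    abort("all restarts failed to produce a finite objective",
          class = "cotyledonsim_fit_error")
  }
  estimates <- setNames(exp(best$par_log), sc$params)
  final <- transfer_objective(estimates, data, sys, initial_concentration,
                              type = loss)

  ci <- list(se = setNames(rep(NA_real_, p), sc$params),
             ci95 = setNames(rep(NA_real_, p), sc$params),
             correlation = NULL, ok = FALSE)
  if (compute_ci) {
    ci <- .linearized_ci(estimates, data, sys, initial_concentration, loss)
  }

  structure(
    list(scenario = sc,
         estimates = estimates,
         se = ci$se, ci95 = ci$ci95, correlation = ci$correlation,
         ci_ok = ci$ok,
         objective = as.numeric(final), loss = loss,
         n_obs = attr(final, "n"), n_excluded = attr(final, "n_excluded"),
         n_restarts = n_restarts, seed = seed,
         convergence = best$convergence,
         system = .apply_scenario(sys, estimates),
         initial_concentration = initial_concentration),
    class = "transfer_fit"
  )
}

# Local refinement: Levenberg-Marquardt on the relative-residual vector,
# parameters on the log scale within box bounds. The finite-difference step
# (epsfcn) is kept well above the linear-solver noise floor.
.polish <- function(resid_fn, start_log, lower_log, upper_log) {
  res <- minpack.lm::nls.lm(
    par = start_log, lower = lower_log, upper = upper_log, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300, epsfcn = 1e-6))
  list(value = res$deviance, par_log = res$par,
       convergence = if (res$info %in% 1:4) 0L else as.integer(res$info))
}

.fit_residuals <- function(params, data, sys, initial_concentration,
                           type = "log_ratio") {
  sys2 <- .apply_scenario(sys, params)
  pred <- predict_observed(data, sys2, initial_concentration)$pred_mg_per_L
  obs <- data$conc_mg_per_L
  keep <- obs > 0
  if (type == "log_ratio") {
    log(pmax(pred[keep], 1e-300) / obs[keep])
  } else {
    (pred[keep] - obs[keep]) / obs[keep]
  }
}

.linearized_ci <- function(estimates, data, sys, initial_concentration,
                           type = "log_ratio") {
  p <- length(estimates)
  r0 <- .fit_residuals(estimates, data, sys, initial_concentration, type)
  n <- length(r0)
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- pmax(abs(estimates[j]) * 1e-4, 1e-10)
    up <- dn <- estimates
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (.fit_residuals(up, data, sys, initial_concentration, type) -
               .fit_residuals(dn, data, sys, initial_concentration, type)) / (2 * h)
  }
  JtJ <- crossprod(J)
  sigma2 <- sum(r0^2) / max(n - p, 1)
  cov <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    warn("singular Jacobian: confidence intervals undefined")
    return(list(se = setNames(rep(NA_real_, p), names(estimates)),
                ci95 = setNames(rep(NA_real_, p), names(estimates)),
                correlation = NULL, ok = FALSE))
  }
  se <- sqrt(diag(cov))
  corr <- cov / outer(se, se)
  dimnames(corr) <- list(names(estimates), names(estimates))
  offdiag <- corr[upper.tri(corr)]
  if (length(offdiag) && any(abs(offdiag) > 0.95)) {
    warn("strong estimate correlation (|r| > 0.95): parameters may be weakly identified")
  }
  list(se = setNames(se, names(estimates)),
       ci95 = setNames(1.96 * se, names(estimates)),
       correlation = corr, ok = TRUE)
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat("<transfer_fit> scenario", x$scenario$id, paste0("(", x$scenario$name, ")"), "\n")
  est <- sprintf("  %-6s %.5g +/- %.3g (95%% CI)", names(x$estimates),
                 x$estimates, x$ci95)
  cat(est, sep = "\n")
  cat(sprintf("  objective %.6g on %d points (%d zero-obs excluded); %d restarts, seed %s\n",
              x$objective, x$n_obs, x$n_excluded, x$n_restarts,
              ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Mean (signed) prediction error
#'
#' `MPE = 100 * mean((pred - obs)/obs)` percent. Zero observations are
#' excluded with a warning reporting the count; opposite-signed errors
#' cancel (see [mape()] for the absolute version; `MAPE >= |MPE|` always).
#'
#' @param pred,obs Numeric vectors of equal length; `obs >= 0`.
#' @return Percent error (scalar).
#' @export
mpe <- function(pred, obs) {
  .pe_check(pred, obs)
  keep <- obs > 0
  if (any(!keep)) warn(sprintf("%d zero observation(s) excluded from MPE", sum(!keep)))
  100 * mean((pred[keep] - obs[keep]) / obs[keep])
}

#' Mean absolute prediction error
#'
#' `MAPE = 100 * mean(|pred - obs|/obs)` percent; zero observations
#' excluded with a warning.
#'
#' @inheritParams mpe
#' @return Percent error (scalar).
#' @export
mape <- function(pred, obs) {
  .pe_check(pred, obs)
  keep <- obs > 0
  if (any(!keep)) warn(sprintf("%d zero observation(s) excluded from MAPE", sum(!keep)))
  100 * mean(abs(pred[keep] - obs[keep]) / obs[keep])
}

.pe_check <- function(pred, obs) {
  if (length(pred) != length(obs)) stop_invalid("pred and obs must have equal length")
  if (any(obs < 0)) stop_invalid("observations must be >= 0")
  invisible(NULL)
}
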