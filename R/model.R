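# The compartment graph is a tree:
#   M_res -- M_perf -- M_int
#                 \
#                  F_cell -- F_int -- F_perf -- F_res
# with six exchange links. Each link flux has the bilinear form
# a * C_from - b * C_to, so the whole system is linear: dN/dt = E %*% C,
# C = N / V, i.e. dN/dt = A %*% N with A = E %*% diag(1/V).

.link_table <- function(sys) {
  P <- sys$drug$P
  P_endo <- sys$drug$P_endo
  # columns: from, to, a (coefficient on C_from), b (coefficient on C_to)
  tibble(
    link = c("M_res.M_perf", "F_res.F_perf", "M_perf.M_int",
             "F_perf.F_int", "F_int.F_cell", "M_perf.F_cell"),
    from = c("M_res", "F_res", "M_perf", "F_perf", "F_int", "M_perf"),
    to   = c("M_perf", "F_perf", "M_int", "F_int", "F_cell", "F_cell"),
    a = c(sys$Q_M,
          sys$Q_F,
          sys$fu * P_endo * sys$SA_Mperf_int,
          sys$fu_fetus * P_endo * sys$SA_Fperf_int,
          P * sys$SA_Fint_cell * sys$fu_fetus / sys$K_F_int_perf,
          P * sys$SA_villi * sys$fu * sys$f_in),
    b = c(sys$Q_M,
          sys$Q_F,
          sys$fu * P_endo * sys$SA_Mperf_int / sys$K_M_int_perf,
          sys$fu_fetus * P_endo * sys$SA_Fperf_int / sys$K_F_int_perf,
          P * sys$SA_Fint_cell * sys$fu / sys$K_F_cell_perf,
          P * sys$SA_villi * sys$fu * sys$f_out / sys$K_FM_cell_perf)
  )
}

#' Intercompartmental link fluxes
#'
#' Evaluates the six directed exchange fluxes of the model at a given state:
#' reservoir-to-cotyledon perfusate flow on each side, endothelial exchange
#' between perfusate and interstitial space on each side, the basolateral
#' trophoblast flux and the asymmetric apical trophoblast flux
#' `P * SA_villi * fu * (f_in * C_M_perf - f_out * C_F_cell / K_FM_cell:perf)`.
#' Positive flux means net transfer from `from` to `to`.
#'
#' @param state Numeric vector of 7 compartment amounts (mg), canonical
#'   order `M_res, M_perf, M_int, F_cell, F_int, F_perf, F_res`.
#' @param sys A [perfusion_system()].
#' @return A tibble with columns `link`, `from`, `to`, `flux_mg_per_min`.
#' @export
link_fluxes <- function(state, sys) {
  stopifnot(inherits(sys, "perfusion_system"))
  if (length(state) != 7 || any(!is.finite(state))) {
    stop_invalid("state must be a finite numeric vector of length 7")
  }
  conc <- setNames(as.numeric(state) / sys$volumes, COMPARTMENTS)
  lt <- .link_table(sys)
  lt$flux_mg_per_min <- unname(lt$a * conc[lt$from] - lt$b * conc[lt$to])
  lt[, c("link", "from", "to", "flux_mg_per_min")]
}

#' Exchange-rate matrix
#'
#' Assembles the 7x7 matrix `E` of the linear system `dN/dt = E C`: each of
#' the six link fluxes leaves one compartment and enters exactly one other,
#' so off-diagonal entries are non-negative and every column sums to zero
#' (mass conservation is structural).
#'
#' @param sys A [perfusion_system()].
#' @return A 7x7 matrix with compartment dimnames (units: L/min, since it
#'   multiplies concentrations in mg/L to give mg/min).
#' @export
exchange_matrix <- function(sys) {
  stopifnot(inherits(sys, "perfusion_system"))
  E <- matrix(0, 7, 7, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  lt <- .link_table(sys)
  for (i in seq_len(nrow(lt))) {
    f <- lt$from[i]; t <- lt$to[i]
    E[t, f] <- E[t, f] + lt$a[i]
    E[f, f] <- E[f, f] - lt$a[i]
    E[f, t] <- E[f, t] + lt$b[i]
    E[t, t] <- E[t, t] - lt$b[i]
  }
  E
}

.ode_matrix <- function(sys) {
  exchange_matrix(sys) %*% diag(1 / unname(sys$volumes))
}

.initial_state <- function(sys, design) {
  N0 <- setNames(numeric(7), COMPARTMENTS)
  res <- if (design$dosing_side == "maternal") "M_res" else "F_res"
  N0[res] <- design$initial_concentration * sys$volumes[[res]]
  N0
}

# Amounts at requested times via eigendecomposition of A (exact for the
# linear system; A is generically diagonalizable). Returns 7 x length(times).
.solve_eigen <- function(A, N0, times) {
  eg <- eigen(A)
  coef <- solve(eg$vectors, N0)
  out <- Re(eg$vectors %*% (coef * exp(outer(eg$values, times))))
  if (any(!is.finite(out))) stop("eigen solution non-finite")
  out
}

.solve_lsoda <- function(A, N0, times, rtol, atol) {
  t_ode <- times
  prepend <- FALSE
  if (t_ode[1] > 0) { t_ode <- c(0, t_ode); prepend <- TRUE }
  rhs <- function(t, y, parms) list(parms %*% y)
  jac <- function(t, y, parms) parms
  sol <- deSolve::lsoda(y = N0, times = t_ode, func = rhs, parms = A,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed (lsoda istate < 0)", class = "cotyledonsim_integration_error")
  }
  m <- t(unclass(sol)[, -1, drop = FALSE])
  if (prepend) m <- m[, -1, drop = FALSE]
  m
}

#' Simulate a perfusion experiment
#'
#' Integrates the seven-compartment system from a dose placed entirely in
#' the dosed reservoir (amount `C0 * V_res`, all other compartments empty)
#' and reports concentration-time trajectories for all compartments at the
#' design's sampling times.
#'
#' Two solution paths are available: `"lsoda"`, a stiff-capable integrator
#' (default tolerances rtol 1e-8, atol 1e-10 on amounts in mg), and
#' `"eigen"`, the exact solution of the linear system by eigendecomposition,
#' which is much faster and is used internally by the fitting loop; the two
#' agree to solver tolerance. The system is closed, so the total amount is
#' conserved; a relative drift above 1e-6 raises an error.
#'
#' @param sys A [perfusion_system()].
#' @param design An [experiment_design()].
#' @param method `"lsoda"` or `"eigen"`.
#' @param rtol,atol Integrator tolerances (lsoda path).
#' @return A tibble of class `perfusion_sim` with columns `time_min`,
#'   `compartment`, `conc_mg_per_L` and attributes `system`, `design`,
#'   `diagnostics` (method, max relative mass drift, min concentration).
#' @examples
#' sim <- simulate_perfusion(acetaminophen_system(), experiment_design("maternal"))
#' dplyr::filter(sim, compartment == "M_res", time_min == 180)
#' @export
simulate_perfusion <- function(sys, design = experiment_design(),
                               method = c("lsoda", "eigen"),
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sys, "perfusion_system"), inherits(design, "experiment_design"))
  method <- match.arg(method)
  A <- .ode_matrix(sys)
  N0 <- .initial_state(sys, design)
  times <- design$sampling_times
  amounts <- switch(method,
                    eigen = .solve_eigen(A, N0, times),
                    lsoda = .solve_lsoda(A, N0, times, rtol, atol))
  total0 <- sum(N0)
  drift <- max(abs(colSums(amounts) - total0)) / total0
  if (drift > 1e-6) {
    abort(sprintf("mass conservation violated: relative drift %.3g", drift),
          class = "cotyledonsim_numerical_error")
  }
  conc <- amounts / unname(sys$volumes)
  if (min(conc) < -1e-6) {
    abort(sprintf("negative concentrations beyond tolerance: %.3g", min(conc)),
          class = "cotyledonsim_numerical_error")
  }
  # zap numerical noise around exact zeros (e.g. the un-dosed reservoir at
  # t = 0) so downstream relative-error metrics see true zeros
  conc[abs(conc) < 1e-9 * max(conc)] <- 0
  out <- tibble(
    time_min = rep(times, each = 7),
    compartment = factor(rep(COMPARTMENTS, length(times)), levels = COMPARTMENTS),
    conc_mg_per_L = as.vector(conc)
  )
  structure(out,
            class = c("perfusion_sim", class(out)),
            system = sys, design = design,
            diagnostics = list(method = method, rtol = rtol, atol = atol,
                               max_rel_mass_drift = drift,
                               min_concentration = min(conc)))
}

#' Analytic steady state
#'
#' The compartment graph is a tree, so the steady state is characterized by
#' all six link fluxes being zero plus total-mass balance; this yields a
#' closed-form solution used as an independent oracle for the integrator.
#' The concentration ratios follow by back-substitution from the maternal
#' perfusate: `C_M_res = C_M_perf`, `C_M_int = K_M_int:perf * C_M_perf`,
#' `C_F_cell = K_FM_cell:perf * (f_in/f_out) * C_M_perf`,
#' `C_F_perf = C_F_cell * fu / (K_F_cell:perf * fu_fetus)`,
#' `C_F_int = K_F_int:perf * C_F_perf`, `C_F_res = C_F_perf`; the level is
#' set by `sum(C_i V_i) = total_amount`.
#'
#' With `f_out = 0` and `f_in > 0` the apical link is a one-way valve into
#' the trophoblast and no finite joint steady state exists; this is flagged
#' as an error. With `f_in = f_out = 0` the two sides are disconnected and
#' all mass stays on the dosing side.
#'
#' @param sys A [perfusion_system()].
#' @param total_amount Total drug amount in the system (mg).
#' @param dosing_side Side carrying the mass when the apical link is fully
#'   closed (`f_in = f_out = 0`); irrelevant otherwise.
#' @return A tibble with columns `compartment`, `conc_mg_per_L`, `amount_mg`.
#' @export
steady_state <- function(sys, total_amount, dosing_side = c("maternal", "fetal")) {
  stopifnot(inherits(sys, "perfusion_system"))
  dosing_side <- match.arg(dosing_side)
  if (total_amount < 0) stop_invalid("total_amount must be >= 0")
  if (sys$f_out == 0 && sys$f_in > 0) {
    abort("no finite steady state: f_out = 0 with f_in > 0 makes the apical link a one-way valve into the trophoblast",
          class = "cotyledonsim_invalid_parameter")
  }
  V <- sys$volumes
  r <- setNames(numeric(7), COMPARTMENTS)
  if (sys$f_in == 0 && sys$f_out == 0) {
    # disconnected sides: mass equilibrates within the dosing side only
    if (dosing_side == "maternal") {
      r[c("M_res", "M_perf")] <- 1
      r["M_int"] <- sys$K_M_int_perf
    } else {
      r[c("F_res", "F_perf")] <- 1
      r["F_int"] <- sys$K_F_int_perf
      r["F_cell"] <- sys$K_F_cell_perf * sys$fu_fetus / sys$fu
    }
  } else {
    r["M_res"] <- r["M_perf"] <- 1
    r["M_int"] <- sys$K_M_int_perf
    r["F_cell"] <- sys$K_FM_cell_perf * sys$f_in / sys$f_out
    r["F_perf"] <- r["F_res"] <- r["F_cell"] * sys$fu / (sys$K_F_cell_perf * sys$fu_fetus)
    r["F_int"] <- sys$K_F_int_perf * r["F_perf"]
  }
  C_ref <- total_amount / sum(r * V)
  conc <- r * C_ref
  tibble(compartment = factor(COMPARTMENTS, levels = COMPARTMENTS),
         conc_mg_per_L = unname(conc),
         amount_mg = unname(conc * V))
}

#' @export
#' @method autoplot perfusion_sim
#' @rdname simulate_perfusion
#' @param object,x A `perfusion_sim` object.
#' @param ... Unused.
autoplot.perfusion_sim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$conc_mg_per_L,
                                       colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time [min]", y = "Concentration [mg/L]",
                  colour = "Compartment") +
    ggplot2::theme_minimal()
}
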