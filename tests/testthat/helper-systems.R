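# Random valid perfusion systems for property-style tests.
random_system <- function() {
  f_iv <- runif(1, 0.5, 0.9)
  f_tr <- runif(1, 0.3, 0.6)
  f_int <- runif(1, 0.15, 1 - f_tr - 0.1)
  perfusion_system(
    Q_M = runif(1, 0.005, 0.03), Q_F = runif(1, 0.002, 0.02),
    V_M_res = runif(1, 0.1, 0.5), V_F_res = runif(1, 0.1, 0.5),
    V_intervillous = runif(1, 0.01, 0.05), V_intravillous = runif(1, 0.01, 0.06),
    intervillous_fractions = c(perfusate = f_iv, interstitial = 1 - f_iv),
    intravillous_fractions = c(trophoblast = f_tr, interstitial = f_int,
                               perfusate = 1 - f_tr - f_int),
    fu = runif(1, 0.4, 1), fu_fetus = runif(1, 0.4, 1),
    K_M_int_perf = exp(runif(1, log(0.3), log(3))),
    K_F_int_perf = exp(runif(1, log(0.3), log(3))),
    K_F_cell_perf = exp(runif(1, log(0.2), log(8))),
    K_FM_cell_perf = exp(runif(1, log(0.2), log(8))),
    f_in = exp(runif(1, log(0.02), log(2))),
    f_out = exp(runif(1, log(0.02), log(2)))
  )
}

# Long-horizon time for a system: several multiples of the slowest
# equilibration timescale (slowest non-zero eigenvalue of the rate matrix).
long_horizon <- function(sys) {
  A <- exchange_matrix(sys) %*% diag(1 / compartment_volumes(sys)$volume_L)
  rates <- sort(abs(Re(eigen(A, only.values = TRUE)$values)))
  slowest <- rates[rates > 1e-9][1]
  30 / slowest
}

small_noise_free_campaign <- function(system = acetaminophen_system()) {
  generate_campaign(campaign_spec(n_maternal = 3, n_fetal = 1,
                                  system = system,
                                  noise = noise_model("none")))
}
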