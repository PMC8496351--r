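test_that("link fluxes vanish at zero state and at equal reservoir/perfusate concentrations", {
  sys <- acetaminophen_system()
  fx <- link_fluxes(rep(0, 7), sys)
  expect_equal(fx$flux_mg_per_min, rep(0, 6))

  # equal concentrations in reservoir and perfusate null the flow links
  v <- compartment_volumes(sys)$volume_L
  state <- 5 * v # uniform 5 mg/L everywhere
  fx <- link_fluxes(state, sys)
  expect_equal(fx$flux_mg_per_min[fx$link == "M_res.M_perf"], 0)
  expect_equal(fx$flux_mg_per_min[fx$link == "F_res.F_perf"], 0)
})

test_that("the apical flux follows the asymmetric permeability law", {
  sys <- acetaminophen_system() # f_in = 0.060, f_out = 0.051, K = 4.31
  v <- compartment_volumes(sys)$volume_L
  state <- rep(0, 7)
  state[2] <- 10 * v[2] # C_M_perf = 10 mg/L, trophoblast empty
  fx <- link_fluxes(state, sys)
  expected <- sys$drug$P * sys$SA_villi * sys$fu * sys$f_in * 10
  expect_equal(fx$flux_mg_per_min[fx$link == "M_perf.F_cell"], expected)
})

test_that("exchange matrix conserves mass structurally", {
  sys <- acetaminophen_system()
  E <- exchange_matrix(sys)
  expect_equal(max(abs(colSums(E))), 0, tolerance = 1e-12)
  expect_equal(E["M_perf", "M_res"], 0.014) # Q_M in L/min
  offdiag <- E; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
})

test_that("symmetric apical settings make the apical matrix entries symmetric", {
  sys <- perfusion_system(f_in = 1, f_out = 1, K_FM_cell_perf = 1,
                          K_F_cell_perf = 1)
  E <- exchange_matrix(sys)
  expect_equal(E["F_cell", "M_perf"], E["M_perf", "F_cell"])
})

test_that("simulation conserves the dosed amount and is linear in the dose", {
  sys <- acetaminophen_system()
  design <- experiment_design("maternal", 10, duration = 600,
                              sampling_times = c(0, 60, 300, 600))
  for (method in c("lsoda", "eigen")) {
    sim <- simulate_perfusion(sys, design, method = method)
    v <- compartment_volumes(sys)$volume_L
    totals <- sim |>
      dplyr::mutate(amount = conc_mg_per_L * v[as.integer(compartment)]) |>
      dplyr::summarise(total = sum(amount), .by = time_min)
    expect_equal(totals$total, rep(2.8, 4), tolerance = 1e-6) # 10 mg/L x 0.280 L
    expect_true(all(sim$conc_mg_per_L >= -1e-10))
  }
  # linearity: doubling the dose doubles every trajectory point
  d2 <- experiment_design("maternal", 20, duration = 600,
                          sampling_times = c(0, 60, 300, 600))
  s1 <- simulate_perfusion(sys, design, method = "eigen")
  s2 <- simulate_perfusion(sys, d2, method = "eigen")
  expect_equal(s2$conc_mg_per_L, 2 * s1$conc_mg_per_L, tolerance = 1e-9)
})

test_that("eigen and lsoda solution paths agree", {
  sys <- acetaminophen_system()
  design <- experiment_design("fetal", 10, duration = 180)
  se <- simulate_perfusion(sys, design, method = "eigen")
  sl <- simulate_perfusion(sys, design, method = "lsoda")
  expect_equal(se$conc_mg_per_L, sl$conc_mg_per_L, tolerance = 1e-6)
})

test_that("long-time trophoblast accumulation matches the zero-flux ratio", {
  sys <- acetaminophen_system() # K 4.31, f_in 0.060, f_out 0.051
  sim <- simulate_perfusion(sys, experiment_design("maternal", 10, duration = 6000,
                                                   sampling_times = 6000),
                            method = "eigen")
  conc <- setNames(sim$conc_mg_per_L, as.character(sim$compartment))
  ratio <- conc[["F_cell"]] / conc[["M_perf"]]
  expect_equal(ratio, 4.31 * 0.060 / 0.051, tolerance = 1e-6)
})

test_that("steady state solves the zero-flux relations exactly", {
  sys <- acetaminophen_system()
  ss <- steady_state(sys, total_amount = 2.8)
  conc <- setNames(ss$conc_mg_per_L, as.character(ss$compartment))
  expect_equal(conc[["M_int"]], sys$K_M_int_perf * conc[["M_perf"]]) # dead-end link
  expect_equal(conc[["M_res"]], conc[["M_perf"]])
  expect_equal(sum(ss$amount_mg), 2.8)
  # all link fluxes vanish at the steady state
  fx <- link_fluxes(ss$amount_mg, sys)
  expect_equal(fx$flux_mg_per_min, rep(0, 6), tolerance = 1e-12)

  # fully symmetric settings equalize all concentrations
  symm <- perfusion_system(fu = 0.9, fu_fetus = 0.9, f_in = 1, f_out = 1,
                           K_M_int_perf = 1, K_F_int_perf = 1,
                           K_F_cell_perf = 1, K_FM_cell_perf = 1)
  ss2 <- steady_state(symm, 1)
  expect_equal(diff(range(ss2$conc_mg_per_L)), 0, tolerance = 1e-12)
})

test_that("one-way apical valve has no finite steady state", {
  sys <- perfusion_system(f_in = 0.1, f_out = 0)
  expect_error(steady_state(sys, 1), class = "cotyledonsim_invalid_parameter")
})

test_that("steady state matches long-horizon simulation for randomized systems", {
  withr::with_seed(2024, {
    for (i in 1:30) {
      sys <- random_system()
      t_long <- long_horizon(sys)
      side <- sample(c("maternal", "fetal"), 1)
      design <- experiment_design(side, 10, duration = t_long,
                                  sampling_times = t_long)
      sim <- simulate_perfusion(sys, design, method = "eigen")
      res <- if (side == "maternal") "M_res" else "F_res"
      total <- 10 * compartment_volumes(sys)$volume_L[match(res, levels(sim$compartment))]
      ss <- steady_state(sys, total, dosing_side = side)
      expect_equal(sim$conc_mg_per_L, ss$conc_mg_per_L, tolerance = 1e-3)
    }
  })
})

test_that("steady-state reservoir concentrations are non-increasing in the shared K", {
  sys <- acetaminophen_system()
  grid <- c(0.76, 2.5, 4.31)
  res <- sapply(grid, function(K) {
    s <- perfusion_system(K_F_cell_perf = K, K_FM_cell_perf = K,
                          f_in = 0.060, f_out = 0.051)
    conc <- steady_state(s, 2.8)$conc_mg_per_L
    conc[c(1, 7)] # the two reservoirs
  })
  expect_true(all(diff(res[1, ]) <= 0))
  expect_true(all(diff(res[2, ]) <= 0))
})
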