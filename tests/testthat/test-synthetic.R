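test_that("noise-free generation reproduces the simulation exactly", {
  sys <- acetaminophen_system()
  design <- experiment_design("maternal")
  obs <- generate_experiment(design, sys, noise_model("none"))
  sim <- simulate_perfusion(sys, design, method = "eigen")
  m_res <- sim$conc_mg_per_L[sim$compartment == "M_res"]
  got <- obs$conc_mg_per_L[obs$sampled_reservoir == "maternal"]
  expect_equal(got, m_res)
  expect_equal(got[1], 10) # dosed reservoir starts at the dose concentration
})

test_that("generation is reproducible under a fixed seed", {
  sys <- acetaminophen_system()
  design <- experiment_design("fetal")
  a <- generate_experiment(design, sys, noise_model(cv = 0.1), seed = 123)
  b <- generate_experiment(design, sys, noise_model(cv = 0.1), seed = 123)
  expect_identical(a, b)
  c <- generate_experiment(design, sys, noise_model(cv = 0.1), seed = 124)
  expect_false(identical(b$conc_mg_per_L, c$conc_mg_per_L))
})

test_that("noise multiplier has the nominal coefficient of variation", {
  withr::with_seed(77, {
    draws <- cotyledonsim:::.apply_noise(rep(1, 1000), noise_model(cv = 0.10))
    expect_equal(sd(draws) / mean(draws), 0.10, tolerance = 0.01 / 0.10)
  })
})

test_that("the default campaign mirrors the assay structure", {
  camp <- generate_campaign(seed = 1)
  series <- dplyr::distinct(camp, experiment_id, sampled_reservoir)
  expect_equal(nrow(series), 28) # 14 experiments x 2 reservoirs
  expect_equal(nrow(camp), 28 * length(default_schedule()))
  expect_gte(nrow(camp), 400)
  counts <- dplyr::count(dplyr::distinct(camp, experiment_id, dosing_side), dosing_side)
  expect_equal(counts$n[counts$dosing_side == "maternal"], 10)
  expect_equal(counts$n[counts$dosing_side == "fetal"], 4)
  truth <- campaign_truth(camp)
  expect_equal(truth$K_FM_cell_perf, 4.31)
  expect_equal(truth$f_in, 0.060)
})

test_that("an empty campaign yields a valid empty table", {
  camp <- generate_campaign(campaign_spec(n_maternal = 0, n_fetal = 0))
  expect_equal(nrow(camp), 0)
  expect_named(camp, c("experiment_id", "dosing_side", "sampled_reservoir",
                       "time_min", "conc_mg_per_L"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed(camp, path)
  expect_true(file.exists(path))
})

test_that("campaign write/read round trip is lossless", {
  camp <- generate_campaign(campaign_spec(n_maternal = 2, n_fetal = 1), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed(camp, path)
  back <- read_observed(path)
  expect_equal(as.data.frame(back), as.data.frame(camp[, names(back)]),
               ignore_attr = TRUE)
})

test_that("parameter recovery holds in the median across noisy replicates", {
  base <- acetaminophen_system(fitted = FALSE)
  est <- sapply(1:20, function(sd) {
    camp <- generate_campaign(campaign_spec(n_maternal = 4, n_fetal = 2), seed = sd)
    fit <- suppressWarnings(
      fit_transfer(camp, base, 4, n_restarts = 10, seed = sd, compute_ci = FALSE))
    fit$estimates
  })
  med <- apply(est, 1, median)
  expect_equal(med[["K"]], 4.31, tolerance = 0.10)
  expect_equal(med[["f_in"]], 0.060, tolerance = 0.10)
  expect_equal(med[["f_out"]], 0.051, tolerance = 0.10)
})
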