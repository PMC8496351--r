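test_that("objective is zero at the generating truth and counts excluded zeros", {
  camp <- small_noise_free_campaign()
  base <- acetaminophen_system(fitted = FALSE)
  truth <- c(f_in = 0.060, f_out = 0.051, K = 4.31)
  for (type in c("relative", "log_ratio")) {
    loss <- transfer_objective(truth, camp, base, type = type)
    expect_lt(as.numeric(loss), 1e-10)
    expect_equal(attr(loss, "n") + attr(loss, "n_excluded"), nrow(camp))
  }
  # the un-dosed reservoir's t = 0 sample is the only exact zero per series
  expect_equal(attr(transfer_objective(truth, camp, base), "n_excluded"), 4L)
})

test_that("relative objective equals the hand-computed residual sum", {
  camp <- small_noise_free_campaign()
  base <- acetaminophen_system(fitted = FALSE)
  truth <- c(f_in = 0.060, f_out = 0.051, K = 4.31)
  # scale observations so residuals are known exactly: obs = pred / 2
  halved <- camp
  halved$conc_mg_per_L <- camp$conc_mg_per_L / 2
  n <- sum(halved$conc_mg_per_L > 0)
  expect_equal(as.numeric(transfer_objective(truth, halved, base, type = "relative")),
               n) # each term ((p - p/2)/(p/2))^2 = 1
  # three-point hand example with mixed residuals
  one <- camp[camp$experiment_id == "M01" & camp$sampled_reservoir == "maternal", ][2:4, ]
  scale <- c(1, 2, 0.5)
  one$conc_mg_per_L <- one$conc_mg_per_L * scale
  hand <- sum(((1 - scale) / scale)^2) # 0 + 0.25 + 1
  expect_equal(as.numeric(transfer_objective(truth, one, base, type = "relative")),
               hand, tolerance = 1e-10)
})

test_that("scenario definitions tie parameters as documented", {
  expect_equal(fit_scenario(1)$params, "f")
  expect_equal(fit_scenario("S2_asymmetric_f")$params, c("f_in", "f_out"))
  expect_equal(fit_scenario(4)$params, c("f_in", "f_out", "K"))
  expect_error(fit_scenario(5), class = "cotyledonsim_invalid_parameter")
})

test_that("noise-free scenario-4 fit recovers the generating parameters within 1%", {
  camp <- small_noise_free_campaign()
  fit <- suppressWarnings(
    fit_transfer(camp, acetaminophen_system(fitted = FALSE), scenario = 4,
                 n_restarts = 15, seed = 11))
  truth <- campaign_truth(camp)
  expect_equal(fit$estimates[["K"]], truth$K_FM_cell_perf, tolerance = 0.01)
  expect_equal(fit$estimates[["f_in"]], truth$f_in, tolerance = 0.01)
  expect_equal(fit$estimates[["f_out"]], truth$f_out, tolerance = 0.01)
  # noise-free confidence intervals collapse
  expect_true(all(fit$ci95 < 1e-4))
})

test_that("symmetric-transfer data is recovered by the single-factor scenario", {
  sys_truth <- perfusion_system(f_in = 0.05, f_out = 0.05)
  camp <- small_noise_free_campaign(system = sys_truth)
  fit <- fit_transfer(camp, perfusion_system(), scenario = 1,
                      n_restarts = 10, seed = 3)
  expect_equal(fit$estimates[["f"]], 0.05, tolerance = 0.01)
})

test_that("fits are bitwise reproducible for a fixed seed", {
  camp <- generate_campaign(campaign_spec(n_maternal = 2, n_fetal = 1), seed = 5)
  base <- acetaminophen_system(fitted = FALSE)
  f1 <- suppressWarnings(fit_transfer(camp, base, 4, n_restarts = 8, seed = 9, compute_ci = FALSE))
  f2 <- suppressWarnings(fit_transfer(camp, base, 4, n_restarts = 8, seed = 9, compute_ci = FALSE))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("confidence intervals scale with the noise level and are symmetric", {
  base <- acetaminophen_system(fitted = FALSE)
  ci <- sapply(c(0.05, 0.10), function(cv) {
    camp <- generate_campaign(
      campaign_spec(n_maternal = 4, n_fetal = 2, noise = noise_model(cv = cv)),
      seed = 31)
    fit <- suppressWarnings(fit_transfer(camp, base, 4, n_restarts = 10, seed = 31))
    td <- tidy(fit)
    # symmetric by construction
    expect_equal(td$conf.high - td$estimate, td$estimate - td$conf.low)
    fit$ci95
  })
  ratio <- ci[, 2] / ci[, 1]
  expect_true(all(ratio > 1.4 & ratio < 2.9))
})

test_that("richer scenarios achieve no worse objectives (S4 <= S2 <= S1)", {
  camp <- generate_campaign(campaign_spec(n_maternal = 3, n_fetal = 1), seed = 17)
  base <- acetaminophen_system(fitted = FALSE)
  f1 <- suppressWarnings(fit_transfer(camp, base, 1, n_restarts = 10, seed = 17, compute_ci = FALSE))
  f2 <- suppressWarnings(fit_transfer(camp, base, 2, n_restarts = 10, seed = 17, compute_ci = FALSE,
                      extra_starts = list(c(f_in = f1$estimates[["f"]],
                                            f_out = f1$estimates[["f"]]))))
  f4 <- suppressWarnings(fit_transfer(camp, base, 4, n_restarts = 10, seed = 17, compute_ci = FALSE,
                      extra_starts = list(c(f_in = f2$estimates[["f_in"]],
                                            f_out = f2$estimates[["f_out"]],
                                            K = base$K_FM_cell_perf))))
  expect_lte(f4$objective, f2$objective + 1e-9)
  expect_lte(f2$objective, f1$objective + 1e-9)
})

test_that("prediction-error metrics follow their definitions", {
  expect_equal(mpe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mpe(2 * c(1, 5), c(1, 5)), 100)
  expect_equal(mape(2 * c(1, 5), c(1, 5)), 100)
  # signed errors cancel in MPE but not MAPE
  expect_equal(mpe(c(1, 3), c(2, 2)), 0)
  expect_equal(mape(c(1, 3), c(2, 2)), 50)
  expect_warning(mpe(c(1, 2), c(0, 2)), "excluded")
  expect_error(mpe(1:3, 1:2), class = "cotyledonsim_invalid_parameter")
})

test_that("MAPE dominates the absolute MPE on arbitrary inputs", {
  withr::with_seed(8, {
    for (i in 1:50) {
      n <- sample(2:30, 1)
      obs <- runif(n, 0.1, 10)
      pred <- obs * exp(rnorm(n, 0, 0.5))
      expect_gte(mape(pred, obs), abs(mpe(pred, obs)))
    }
  })
})

test_that("tidy and glance summarize fits in broom conventions", {
  camp <- small_noise_free_campaign()
  fit <- suppressWarnings(
    fit_transfer(camp, acetaminophen_system(fitted = FALSE), 4,
                 n_restarts = 8, seed = 2))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("f_in", "f_out", "K"))
  gl <- glance(fit)
  expect_equal(gl$scenario, "S4_asymmetric_f_plus_K")
  expect_true(gl$converged)
})
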