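test_that("fraction unbound scales with albumin as the binding model predicts", {
  # printed perfusate values from the adult reference
  expect_equal(round(scale_fraction_unbound(0.82, binding_context(40)), 2), 0.84)
  expect_equal(round(scale_fraction_unbound(0.82, binding_context(30)), 2), 0.88)
  # identity at the reference concentration
  expect_equal(scale_fraction_unbound(0.82, binding_context(47)), 0.82)
  # no binder present, or a drug that does not bind at all
  expect_equal(scale_fraction_unbound(0.82, binding_context(0)), 1)
  expect_equal(scale_fraction_unbound(1.0, binding_context(55)), 1)
})

test_that("fraction unbound is strictly decreasing in albumin concentration", {
  A <- seq(0, 80, by = 5)
  fu <- vapply(A, function(a) scale_fraction_unbound(0.82, binding_context(a)),
               numeric(1))
  expect_true(all(diff(fu) < 0))
  expect_true(all(fu > 0 & fu <= 1))
})

test_that("invalid binding inputs are rejected", {
  expect_error(scale_fraction_unbound(0, binding_context(40)), class = "cotyledonsim_invalid_parameter")
  expect_error(scale_fraction_unbound(1.2, binding_context(40)), class = "cotyledonsim_invalid_parameter")
  expect_error(binding_context(-1), class = "cotyledonsim_invalid_parameter")
})

test_that("interstitial:perfusate partition follows the protein-corrected water model", {
  comp <- placenta_composition()
  # frozen hand evaluations of (f_w_int + r*(1/fu - f_w_perf))*fu
  expect_equal(partition_interstitial_perfusate(comp, fu = 0.88), 0.8913, tolerance = 1e-4)
  expect_equal(partition_interstitial_perfusate(comp, fu = 0.5), 0.6662, tolerance = 1e-4)
  # pure water both sides, no protein, no binding
  pure <- tissue_composition(f_water_int = 1, f_water_perf = 1,
                             protein_ratio_int_over_perf = 0.37)
  expect_equal(partition_interstitial_perfusate(pure, fu = 1), 1)
  # with the protein term removed the coefficient is the water fraction
  noprot <- tissue_composition(f_water_int = 0.935, f_water_perf = 0.926,
                               protein_ratio_int_over_perf = 0)
  expect_equal(partition_interstitial_perfusate(noprot, fu = 1), 0.935)
  expect_error(partition_interstitial_perfusate(comp, fu = 0),
               class = "cotyledonsim_invalid_parameter")
})

test_that("partition coefficients are strictly positive for valid inputs", {
  comp <- placenta_composition()
  for (fu in runif(25, 0.05, 1)) {
    expect_gt(partition_interstitial_perfusate(comp, fu), 0)
    expect_gt(partition_cell_perfusate(acetaminophen(), comp, fu), 0)
  }
})

test_that("water partition is the quotient of fu and K", {
  expect_equal(water_partition(0.88, 0.88), 1)
  expect_equal(water_partition(0.88, 0.8913), 0.9873, tolerance = 1e-4)
  expect_equal(water_partition(1, 1), 1)
  expect_error(water_partition(0.88, 0), class = "cotyledonsim_invalid_parameter")
  expect_error(water_partition(0.88, -2), class = "cotyledonsim_invalid_parameter")
})

test_that("drug parameters validate and convert units", {
  d <- acetaminophen()
  expect_equal(d$P, 4.29e-3)   # 4.29e-2 cm/min in dm/min
  expect_equal(d$P_endo, 10)   # 100 cm/min in dm/min
  expect_error(drug_parameters("x", fu_adult = 0, membrane_permeability = 1,
                               endothelial_permeability = 1),
               class = "cotyledonsim_invalid_parameter")
  expect_error(drug_parameters("x", fu_adult = 0.5, membrane_permeability = -1,
                               endothelial_permeability = 1),
               class = "cotyledonsim_invalid_parameter")
})
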