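test_that("flow-through mass balance reproduces its worked values", {
  # r = 5e-7 mol m-2 s-1, SA = 1e-4 m2, flow = 0.004 mL/s -> 0.5 ppm
  expect_equal(outlet_ca_ppm(5e-7, 1e-4, 0.004), 0.5)
  expect_equal(outlet_ca_ppm(0, 1e-4, 0.004), 0)
  expect_equal(outlet_ca_ppm(9e-7, 1e-4, 0.004), 0.9)
  expect_error(outlet_ca_ppm(1e-7, 1e-4, 0), "flow")
})

test_that("mass balance is linear in rate, area and inverse flow", {
  base <- outlet_ca_ppm(3e-7, 2e-4, 0.01)
  expect_equal(outlet_ca_ppm(6e-7, 2e-4, 0.01), 2 * base)
  expect_equal(outlet_ca_ppm(3e-7, 6e-4, 0.01), 3 * base)
  expect_equal(outlet_ca_ppm(3e-7, 2e-4, 0.005), 2 * base)
})

test_that("constant set matches the standard 25 C compilation", {
  tc <- thermo_constants(25)
  expect_equal(log10(tc$K1), -6.352, tolerance = 1e-3)
  expect_equal(log10(tc$K2), -10.329, tolerance = 1e-3)
  expect_equal(log10(tc$KH), -1.468, tolerance = 1e-3)
  expect_equal(log10(tc$Ksp), -8.48, tolerance = 1e-3)
  expect_equal(log10(tc$Kw), -13.996, tolerance = 1e-2)
})

test_that("saturation index behaves physically", {
  st <- solution_state(Ca_total_mM = 0.1425, pH = 7.9)
  expect_equal(saturation_index(solution_state(Ca_total_mM = 0, pH = 8)), 0)
  # strictly increasing in pH at fixed Ca and pCO2
  om <- suppressWarnings(vapply(seq(6, 10, by = 0.25),
               function(p) saturation_index(st, pH = p), numeric(1)))
  expect_true(all(diff(om) > 0))
  expect_error(saturation_index(solution_state(Ca_total_mM = 0.1)), "pH")
})

test_that("pH inversion is consistent with the forward speciation", {
  st <- solution_state(Ca_total_mM = 0.1425)
  for (target in c(0.05, 0.1, 0.3, 0.9)) {
    ph <- solve_ph_for_omega(st, target)
    expect_equal(saturation_index(st, pH = ph), target, tolerance = 1e-6)
    # pH round-trip: re-inverting the computed omega returns the same pH
    expect_equal(solve_ph_for_omega(st, saturation_index(st, pH = ph)), ph,
                 tolerance = 1e-3)
  }
  expect_error(solve_ph_for_omega(st, 0), "> 0")
})

test_that("interfacial pH under a 10x-undersaturated film is near 8.6-8.7", {
  # 500 ppb Ca = 1.25e-5 molal, pCO2 550 ppm, omega 0.1, NaCl/NaHCO3 medium
  ph500 <- solve_ph_for_omega(solution_state(Ca_total_mM = 0.0125), 0.1)
  expect_equal(ph500, 8.7, tolerance = 0.15 / 8.7)
  ph800 <- solve_ph_for_omega(solution_state(Ca_total_mM = 0.02), 0.1)
  expect_equal(ph800, 8.6, tolerance = 0.15 / 8.6)
  expect_gt(ph500, ph800)  # less Ca needs a higher pH for the same omega
})

test_that("ideal-solution limit shifts the computed pH by less than 0.5", {
  st <- solution_state(Ca_total_mM = 0.0125)
  tc <- thermo_constants(20)
  tc0 <- tc; tc0$A_davies <- 0
  ph <- solve_ph_for_omega(st, 0.1, constants = tc)
  ph0 <- solve_ph_for_omega(st, 0.1, constants = tc0)
  expect_lt(abs(ph - ph0), 0.5)
})

test_that("rate-reduction inversion follows the rate law", {
  expect_equal(omega_from_rate_reduction(0), 0)
  expect_equal(omega_from_rate_reduction(0.2, rate_law_power(n = 1)), 0.2,
               tolerance = 1e-6)
  # calibrated default: 20% reduction maps to omega = 0.1
  expect_equal(omega_from_rate_reduction(0.2), 0.1, tolerance = 1e-6)
  expect_error(omega_from_rate_reduction(1.2), "fraction")
  bad_law <- function(om) sin(6 * om) + 1.5
  expect_error(omega_from_rate_reduction(0.2, bad_law), "non-increasing")
  # any power law vanishes at equilibrium
  expect_equal(rate_law_power(k = 3e-7)(1), 0)
  # table-driven law inverts too
  tab <- rate_law_table(seq(0, 1, 0.1), 2e-7 * (1 - seq(0, 1, 0.1))^2)
  expect_equal(omega_from_rate_reduction(1 - 0.81, tab), 0.1,
               tolerance = 1e-3)
})

test_that("warnings flag out-of-range conditions", {
  expect_warning(davies_log_gamma(2, 0.8), "Davies")
  st <- solution_state(Ca_total_mM = 0.0125, temperature_C = 20)
  expect_warning(saturation_index(st, constants = thermo_constants(37),
                                  pH = 8), "temperature")
})

test_that("speciation report and what-if helper are self-consistent", {
  st <- solution_state(Ca_total_mM = 0.1425, pH = 7.9)
  sp <- speciate(st)
  expect_equal(sp$value[sp$quantity == "omega_calcite"],
               saturation_index(st))
  # a positive interfacial pH shift raises the local saturation state
  om0 <- interface_omega_whatif(st, 0)
  om_up <- interface_omega_whatif(st, 0.7)
  expect_gt(om_up, om0)
  expect_equal(om0, saturation_index(st))
})
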