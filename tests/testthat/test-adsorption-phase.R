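# Sauerbrey adsorption, phase-separation criticals and rheological
# classification.

test_that("Sauerbrey mass is linear in the shift and scales with overtone", {
  t <- seq(0, 100, by = 1)
  tr <- qcm_trace(t, rep(-10, length(t)))
  expect_equal(sauerbrey_mass(tr), 17.7 * 10)   # 177 ng/cm^2

  # zero shift, zero mass
  expect_equal(sauerbrey_mass(qcm_trace(t, rep(0, length(t)))), 0)

  # linearity in delta_f
  tr2 <- qcm_trace(t, rep(-20, length(t)))
  expect_equal(sauerbrey_mass(tr2), 2 * sauerbrey_mass(tr), tolerance = 1e-12)

  # inverse proportionality to the overtone order
  tr3 <- qcm_trace(t, rep(-10, length(t)), overtone = 3L)
  expect_equal(sauerbrey_mass(tr3), sauerbrey_mass(tr) / 3, tolerance = 1e-12)

  expect_error(sauerbrey_mass(tr, equilibrium_window = c(500, 600)),
               "outside the trace")
})

test_that("specific adsorption converts areal to per-coating mass", {
  # the COS plateau: 676 ng/cm^2 over the inferred CNC coating -> 87 mg/g
  expect_equal(specific_adsorption(676, 7.77), 87.0, tolerance = 5e-4)
  # the PAAS residual: 76 ng/cm^2 -> ~10 mg/g (9.78 before rounding)
  expect_equal(round(specific_adsorption(76, 7.77)), 10)

  expect_equal(specific_adsorption(0, 5), 0)
  # scale invariance
  expect_equal(specific_adsorption(2 * 676, 2 * 7.77),
               specific_adsorption(676, 7.77), tolerance = 1e-12)
  expect_error(specific_adsorption(100, 0), "> 0")
})

test_that("anisotropic fraction is a bounded height ratio", {
  expect_equal(anisotropic_fraction(phase_record(7.5, 3, 10)), 0.30)
  expect_equal(anisotropic_fraction(phase_record(6.0, 0, 10)), 0)
  expect_equal(anisotropic_fraction(phase_record(9.0, 10, 10)), 1)
  expect_error(phase_record(7.5, 11, 10), "within")
  expect_error(phase_record(7.5, -1, 10), "within")
})

test_that("critical concentrations bracket the biphasic window", {
  # onset at 7.5 wt%: zero at 6.0, positive at 7.5, larger at 9.0
  recs <- gen_phase_series(7.5, 10, c(6, 7.5, 9), noise_sd = 0, seed = 1)
  cc <- critical_concentrations(recs)
  expect_equal(cc$c_a, 7.5)
  expect_identical(cc$c_a_bound, "exact")
  expect_identical(cc$c_i_bound, "above_range")
  expect_true(all(diff(cc$fraction) >= 0))

  # fully birefringent at every tested concentration: C_i below the range
  all_one <- lapply(c(4.5, 6, 7.5), function(c) phase_record(c, 10, 10))
  cc1 <- critical_concentrations(all_one)
  expect_identical(cc1$c_i_bound, "below_range")
  expect_equal(cc1$c_i, 4.5)

  # never birefringent: C_a above the range
  all_zero <- lapply(c(3, 4.5, 6), function(c) phase_record(c, 0, 10))
  cc0 <- critical_concentrations(all_zero)
  expect_identical(cc0$c_a_bound, "above_range")
  expect_equal(cc0$c_a, 6)

  # C_a <= C_i whenever both are bracketed
  recs2 <- gen_phase_series(5, 8, seq(4, 10, by = 0.5), noise_sd = 0, seed = 1)
  cc2 <- critical_concentrations(recs2)
  expect_lte(cc2$c_a, cc2$c_i)

  expect_error(critical_concentrations(rev(recs)), "sorted")
})

test_that("gel classification needs G' above G'' everywhere", {
  omega <- 10^seq(-1, 2, length.out = 20)
  gel <- rheo_sweep(omega = omega, g_prime = 2 * omega^0.1,
                    g_double_prime = omega^0.1)
  expect_identical(classify_gel(gel)$state, "gel")
  expect_true(is.na(classify_gel(gel)$crossover_omega))

  # viscous at low frequency, elastic at high: liquid-like with crossover
  liq <- rheo_sweep(omega = omega, g_prime = 0.8 * omega^1.6,
                    g_double_prime = 4 * omega^0.9)
  out <- classify_gel(liq)
  expect_identical(out$state, "liquid_like")
  expect_equal(out$crossover_omega, (4 / 0.8)^(1 / 0.7), tolerance = 0.05)

  # common rescaling of both moduli changes nothing
  liq2 <- rheo_sweep(omega = omega, g_prime = 37 * 0.8 * omega^1.6,
                     g_double_prime = 37 * 4 * omega^0.9)
  expect_identical(classify_gel(liq2)$state, "liquid_like")
  expect_equal(classify_gel(liq2)$crossover_omega, out$crossover_omega,
               tolerance = 1e-9)

  expect_error(classify_gel(rheo_sweep(omega = 1, g_prime = 2,
                                       g_double_prime = 1)),
               "too narrow")
  expect_error(classify_gel(gen_rheo_sweep("simple", seed = 1)),
               "oscillatory")
})

test_that("viscosity-profile segmentation recognises the three regimes", {
  rate <- 10^seq(-2, 3, length.out = 30)

  # constructed three-region curve, slopes (-0.8, -0.1, -0.6)
  lc <- gen_rheo_sweep("lc_three_region", seed = 5, noise_sd = 0)
  out <- lc_viscosity_regions(lc)
  expect_identical(out$label, "lc_three_region")
  expect_equal(out$slopes, c(-0.8, -0.1, -0.6), tolerance = 0.05)

  # plateau then a single power law
  eta_nt <- ifelse(rate < 1, 5, 5 * rate^-0.7)
  nt <- lc_viscosity_regions(rheo_sweep(shear_rate = rate, viscosity = eta_nt))
  expect_identical(nt$label, "newtonian_then_thinning")

  # pure power law
  pp <- lc_viscosity_regions(rheo_sweep(shear_rate = rate,
                                        viscosity = 2 * rate^-0.5))
  expect_identical(pp$label, "simple_shear_thinning")

  # vertical scaling of viscosity cannot change the label
  lc_scaled <- rheo_sweep(shear_rate = lc$shear_rate,
                          viscosity = 1e3 * lc$viscosity)
  expect_identical(lc_viscosity_regions(lc_scaled)$label, "lc_three_region")

  narrow <- rheo_sweep(shear_rate = 10^seq(0, 1, length.out = 15),
                       viscosity = 2 * 10^seq(0, 1, length.out = 15)^-0.5)
  expect_error(lc_viscosity_regions(narrow), "too narrow")
  expect_error(lc_viscosity_regions(gen_rheo_sweep("gel", seed = 1)),
               "steady")
})

test_that("kinetic arrest flags colour-suppressing formulations", {
  # gelation at or below C_a freezes the isotropic structure
  expect_true(kinetic_arrest_flag(c(9.0, 7.5), c_a = 7.5)$suppressing)
  expect_false(kinetic_arrest_flag(9.0, c_a = 7.5)$suppressing)
  expect_false(kinetic_arrest_flag(numeric(0), c_a = 7.5)$suppressing)
})
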