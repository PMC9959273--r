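# Forward DLVO model and the physical-constant calculators.

cnc_params <- dlvo_params(kappa = 0.04125, z_const = 9.305e-3)

test_that("double-layer force matches direct evaluation and decays", {
  # direct arithmetic evaluation at the pure-CNC parameter set
  expect_equal(edl_force(cnc_params, 94.43),
               0.04125 * 5000 * 9.305e-3 * exp(-0.04125 * 94.43),
               tolerance = 1e-12)
  expect_equal(edl_force(cnc_params, 94.43), 0.0390, tolerance = 1e-4 / 0.039)

  # zero interaction constant kills the force at every distance
  p0 <- dlvo_params(0.04125, 0)
  expect_equal(edl_force(p0, c(1, 10, 100)), rep(0, 3))

  # exponential decay: strictly decreasing, asymptotically zero
  D <- seq(1, 500, by = 1)
  f <- edl_force(cnc_params, D)
  expect_true(all(diff(f) < 0))
  expect_lt(edl_force(cnc_params, 2000), 1e-30)

  expect_error(edl_force(cnc_params, 0), "positive")
  expect_error(edl_force(cnc_params, -5), "positive")
})

test_that("ln(EDL force) is affine in D with slope -kappa", {
  D <- seq(20, 180, length.out = 64)
  lf <- log(edl_force(cnc_params, D))
  fit <- lm(lf ~ D)
  expect_equal(unname(coef(fit)[2]), -cnc_params$kappa, tolerance = 1e-12)
  expect_lt(max(abs(resid(fit))), 1e-12)
})

test_that("van der Waals force has inverse-square attraction", {
  expect_equal(vdw_force(cnc_params, 10), -0.030, tolerance = 1e-9)
  # 100x distance -> 1e-4x magnitude
  expect_equal(vdw_force(cnc_params, 100), -3.0e-4, tolerance = 1e-9)
  expect_equal(vdw_force(cnc_params, 100) / vdw_force(cnc_params, 10), 1e-2,
               tolerance = 1e-12)

  pA0 <- dlvo_params(0.04125, 9.305e-3, hamaker = 0)
  expect_equal(vdw_force(pA0, c(1, 50)), c(0, 0))

  D <- seq(1, 200, by = 0.5)
  expect_true(all(vdw_force(cnc_params, D) <= 0))
  expect_true(all(diff(abs(vdw_force(cnc_params, D))) < 0))
})

test_that("net DLVO force is exactly the sum of its components", {
  D <- exp(seq(log(0.5), log(500), length.out = 200))
  expect_identical(dlvo_force(cnc_params, D),
                   edl_force(cnc_params, D) + vdw_force(cnc_params, D))
  # VDW at 94.43 nm: 3.6e-21 * 5000 / (6 * 94.43^2) * 1e18 = 3.365e-4 nN
  expect_equal(dlvo_force(cnc_params, 94.43), 0.03903 - 3.365e-4,
               tolerance = 2e-4)

  # pure attraction when the double layer is switched off
  pZ0 <- dlvo_params(0.04125, 0)
  expect_lt(dlvo_force(pZ0, 5), 0)
  p00 <- dlvo_params(0.04125, 0, hamaker = 0)
  expect_equal(dlvo_force(p00, D), rep(0, length(D)))
})

test_that("Debye parameter reproduces the textbook screening length", {
  # 1 mol/m^3 = 1 mM: lambda_D ~ 9.6 nm
  k1 <- kappa_from_ionic_strength(medium(ionic_strength = 1))
  expect_equal(1 / k1, debye_length_textbook(1e-3), tolerance = 5e-3)
  # 100 mol/m^3: lambda_D ~ 0.96 nm
  k100 <- kappa_from_ionic_strength(medium(ionic_strength = 100))
  expect_equal(1 / k100, debye_length_textbook(0.1), tolerance = 5e-3)
  # square-root scaling: 4x concentration doubles kappa
  k4 <- kappa_from_ionic_strength(medium(ionic_strength = 4))
  expect_equal(k4 / k1, 2, tolerance = 1e-12)

  expect_error(kappa_from_ionic_strength(medium(ionic_strength = 0)),
               "infinite screening length")
})

test_that("interaction constant is even in the Stern potential and saturates", {
  med <- medium()
  expect_equal(z_from_stern_potential(med, 0), 0)

  # hand evaluation: at psi = RT/F = 25.69 mV the tanh argument is 1/4
  cst <- physical_constants()
  RT_F <- cst$gas_constant * 298.15 / cst$faraday
  z_hand <- 64 * pi * 78.5 * cst$vacuum_permittivity * RT_F^2 *
    tanh(0.25)^2 * 1e9
  expect_equal(z_from_stern_potential(med, RT_F), z_hand, tolerance = 1e-12)
  expect_equal(z_hand, 5.5e-3, tolerance = 0.01)
  # same order as the fitted pair values (6.3-11.2 x 1e-3 nN)
  expect_gt(z_hand, 1e-3); expect_lt(z_hand, 2e-2)

  # even function, monotone increasing in |psi|
  psi <- seq(0.005, 0.2, by = 0.005)
  zp <- z_from_stern_potential(med, psi)
  zm <- z_from_stern_potential(med, -psi)
  expect_equal(zp, zm, tolerance = 1e-14)
  expect_true(all(diff(zp) > 0))

  # saturation at 64 pi eps eps0 (RT/F)^2
  z_sat <- 64 * pi * 78.5 * cst$vacuum_permittivity * RT_F^2 * 1e9
  expect_equal(z_from_stern_potential(med, 5), z_sat, tolerance = 1e-9)
})

test_that("Hamaker constant is symmetric and vanishes for matched media", {
  # index- and dielectric-matched media: exactly zero
  matched <- hamaker_inputs(80.1, 80.1, 80.1, 1.333, 1.333, 1.333)
  expect_equal(hamaker_constant(matched), 0)

  # symmetric media across a different solvent: positive
  sym <- hamaker_inputs(6, 6, 80.1, 1.56, 1.56, 1.333)
  expect_gt(hamaker_constant(sym), 0)

  # symmetry under swapping media 1 and 2
  a12 <- hamaker_constant(hamaker_inputs(6, 3, 80.1, 1.56, 1.45, 1.333))
  a21 <- hamaker_constant(hamaker_inputs(3, 6, 80.1, 1.45, 1.56, 1.333))
  expect_equal(a12, a21, tolerance = 1e-15)

  # cellulose-water-cellulose: same order of magnitude as the literature
  # 3.6e-21 J (within a factor of ten; the two-term form is an estimate)
  a_cwc <- hamaker_constant(sym)
  expect_gt(a_cwc, 3.6e-22)
  expect_lt(a_cwc, 3.6e-20)

  # symmetric-media reduction equals the closed-form special case
  cst <- physical_constants()
  n1 <- 1.56; n3 <- 1.333
  a_closed <- 0.75 * cst$boltzmann * 298.15 * ((6 - 80.1) / (6 + 80.1))^2 +
    (3 * cst$planck * 3e15 / (16 * sqrt(2))) *
    (n1^2 - n3^2)^2 / (n1^2 + n3^2)^1.5
  expect_equal(a_cwc, a_closed, tolerance = 1e-12)
})

test_that("limit distance agrees with the EDL-only closed form", {
  ld <- limit_distance(cnc_params, 1.8e-3)
  oracle <- edl_only_limit_distance(0.04125, 9.305e-3, 5000, 1.8e-3)
  expect_equal(oracle, 91.70, tolerance = 1e-3)
  # VDW slope at the solution is ~0.4% of the threshold: <0.5% agreement
  expect_equal(ld, oracle, tolerance = 5e-3)

  # halving the threshold moves the limit distance outward
  expect_gt(limit_distance(cnc_params, 0.9e-3), ld)

  # doubling Z shifts the EDL-only solution by exactly ln(2)/kappa
  p2 <- dlvo_params(0.04125, 2 * 9.305e-3)
  expect_equal(
    edl_only_limit_distance(0.04125, 2 * 9.305e-3, 5000, 1.8e-3) - oracle,
    log(2) / 0.04125, tolerance = 1e-12)
  # root-finder includes the VDW slope, so agreement is to the sub-percent
  # level rather than exact
  expect_equal(limit_distance(p2, 1.8e-3) - ld, log(2) / 0.04125,
               tolerance = 5e-3)

  expect_error(limit_distance(dlvo_params(0.04125, 0), 1.8e-3), "z_const")
  expect_error(limit_distance(cnc_params, 1e6, d_range = c(50, 100)),
               "\\[50, 100\\]")
})
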