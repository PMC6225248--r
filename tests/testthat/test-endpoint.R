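# Endpoint estimators: ensemble averaging, Gas-PBSA, and the LIE family.

test_that("ensemble averages respect the cluster frame mask", {
  tab <- energy_table(tibble::tibble(
    frame = rep(1:4, 2),
    moiety = rep(c("PP", "complex"), each = 4),
    term = rep(c("sol_es", "int_es"), each = 4),
    value = c(10, 10, 20, 20, -5, -5, -5, -5)))
  full <- ensemble_average(tab)
  expect_equal(full$mean[full$moiety == "PP"], 15)
  half <- ensemble_average(tab, frames = 1:2)
  expect_equal(half$mean[half$moiety == "PP"], 10)
  expect_equal(half$n_frames, c(2L, 2L))
  expect_error(ensemble_average(tab, frames = 99), "no frames")
})

test_that("ensemble average of an AR(1) column converges to the spec mean", {
  tab <- gen_energy_table(tibble::tibble(moiety = "PP", term = "sol_es",
                                         mean = -150),
                          sd = 4, phi = 0.6, n_frames = 1e5, seed = 12)
  dec <- ensemble_average(tab)
  n_eff <- 1e5 / ((1 + 0.6) / (1 - 0.6))
  expect_lt(abs(dec$mean + 150), 3 * 4 / sqrt(n_eff))
  # block-averaged sigma is consistent with the same closed form
  expect_equal(dec$sigma, 4 / sqrt(n_eff), tolerance = 0.3)
})

test_that("Gas-PBSA assembles the endpoint difference and checks inputs", {
  mk <- function(cx, pp, ab, scx, spp, sab)
    energy_decomposition(tibble::tibble(
      moiety = rep(c("complex", "PP", "Abeta"), each = 3),
      term = rep(c("gas_es", "gas_vdw", "pbsa"), 3),
      mean = c(cx, 0, scx, pp, 0, spp, ab, 0, sab)))
  # complex terms exactly the sum of unbound -> zero binding
  expect_equal(gas_pbsa_dg(mk(80, 30, 50, -15, -5, -10))$dg, 0)
  # hand-built: 100 - 20 - 30 + 5 - 50 + 10 = 15
  expect_equal(gas_pbsa_dg(mk(100, 30, 50, -20, -5, -10))$dg, 15)
  # missing PBSA directs to the pluggable interface
  nog <- energy_decomposition(tibble::tibble(
    moiety = c("complex", "PP", "Abeta"), term = "gas_es", mean = 0))
  expect_error(gas_pbsa_dg(nog), "pluggable")
})

test_that("printed gas-phase components sum to the reference total", {
  # electrostatic + van der Waals gas terms of the unbound receptor
  dec <- energy_decomposition(tibble::tibble(
    moiety = "Abeta", term = c("gas_es", "gas_vdw"), mean = c(5239, -863)))
  g_gas <- sum(dec$mean)
  expect_equal(g_gas, 4376)
})

test_that("LIE-S reproduces hand arithmetic and is linear", {
  expect_equal(lie_s_dg(delta_decomp(0, 0))$dg, 0)
  expect_equal(lie_s_dg(delta_decomp(-100, -50))$dg, -58.05)
  d1 <- delta_decomp(-37, 22); d2 <- delta_decomp(-74, 44)
  expect_equal(2 * lie_s_dg(d1)$dg, lie_s_dg(d2)$dg)
})

test_that("LIE-D matches the worked example and its offset algebra", {
  e <- lie_d_dg(delta_decomp(-100, -50))
  expect_equal(e$D, -34)                        # 0.43(-100) - 0.18(-50)
  expect_equal(e$dg, -43 - 9 + (-0.95 * -34 - 2.06 * 4.184))
  expect_equal(e$dg, -28.31904, tolerance = 1e-8)

  z <- lie_d_dg(delta_decomp(0, 0))
  expect_equal(z$dg, -2.06 * 4.184)             # gamma = g exactly
  expect_equal(z$D, 0)

  # partial derivative: d dG / d dvdw = alpha (1 - f)... with gamma = fD + g,
  # dG = b(1+f) des + a(1-f) dvdw + g; here a(1-f) = 0.18 * 1.95
  base <- lie_d_dg(delta_decomp(-100, -50))$dg
  pert <- lie_d_dg(delta_decomp(-100, -40))$dg
  expect_equal(pert - base, 0.18 * (1 - (-0.95)) * 10, tolerance = 1e-10)
})

test_that("LIE-DR is the exact role reversal of LIE-D", {
  er <- lie_dr_dg(delta_decomp(-200, -100, role = "Abeta"))
  expect_equal(er$D, 0.43 * -200 - 0.18 * -100)
  expect_equal(er$dg, -86 - 18 + (0.95 * 68 - 2.06 * 4.184))
  expect_equal(er$dg, -48.01904, tolerance = 1e-8)
  expect_equal(lie_dr_dg(delta_decomp(0, 0, role = "Abeta"))$dg, -8.61904)

  # role-swap symmetry: identical numbers under both roles
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(1, 0, 80); b <- stats::rnorm(1, 0, 40)
    expect_identical(lie_d_dg(delta_decomp(a, b))$dg,
                     lie_dr_dg(delta_decomp(a, b, role = "Abeta"))$dg)
  }
  # missing receptor terms are named
  expect_error(lie_dr_dg(delta_decomp(1, 1)), "Abeta")
})

test_that("LIE-D with LIE-S constants and zero intraligand terms is bit-identical to LIE-S", {
  set.seed(77)
  ps <- lie_params("D", alpha = 0.161, beta = 0.5, gamma_mode = "fixed",
                   gamma = 0)
  for (i in 1:200) {
    d <- make_lie_decomp(int_es = stats::rnorm(1, 0, 100),
                         sol_es_c = stats::rnorm(1, 0, 50),
                         sol_es_u = stats::rnorm(1, 0, 50),
                         int_vdw = stats::rnorm(1, 0, 40),
                         sol_vdw_c = stats::rnorm(1, 0, 20),
                         sol_vdw_u = stats::rnorm(1, 0, 20))
    expect_identical(lie_s_dg(d)$dg, lie_d_dg(d, ps)$dg)
  }
})

test_that("solvation linear response scales its two terms", {
  expect_equal(solvation_linear_response(-100, -40, 0.18, 0.43), -50.2)
  expect_equal(solvation_linear_response(0, 0), 0)
  expect_equal(solvation_linear_response(-7, -3, 1, 1), -10)
})

test_that("uncertainty propagates in quadrature through the estimators", {
  d <- make_lie_decomp(int_es = -50, int_vdw = -20, sigma = 2)
  ps_fixed <- lie_params("D", gamma_mode = "fixed", gamma = 0)
  got <- lie_d_dg(d, ps_fixed)$sigma
  # es bundle: 5 terms of sigma 2; vdw bundle: 3 terms of sigma 2
  expect_equal(got, sqrt((0.43 * 2 * sqrt(5))^2 + (0.18 * 2 * sqrt(3))^2))
  # with gamma = fD + g the effective scalings become b(1+f), a(1-f)
  got2 <- lie_d_dg(d)$sigma
  expect_equal(got2, sqrt((0.43 * 0.05 * 2 * sqrt(5))^2 +
                            (0.18 * 1.95 * 2 * sqrt(3))^2))
})

test_that("estimator consistency: sampled decompositions approach analytic values", {
  means <- tibble::tibble(
    moiety = c("complex", "PP_complex", "PP", "complex", "PP_complex", "PP",
               "PP_complex", "PP"),
    term = c("int_es", "sol_es", "sol_es", "int_vdw", "sol_vdw", "sol_vdw",
             "gas_es", "gas_es"),
    mean = c(-120, -300, -260, -60, -40, -25, 900, 880))
  tab <- gen_energy_table(means, sd = 5, phi = 0.3, n_frames = 4e4, seed = 9)
  dec <- ensemble_average(tab)
  exact <- lie_d_dg(energy_decomposition(means))
  est <- lie_d_dg(dec)
  expect_equal(est$dg, exact$dg, tolerance = 0.05)
  expect_lt(abs(est$dg - exact$dg), 6 * est$sigma + 0.2)
})

test_that("the Born/SASA stand-in returns finite, charge-dependent values", {
  sh <- gen_beta_sheet_pair(5, "antiparallel")
  g <- born_sasa_gsol(combine_conformers(sh$strand_A, sh$strand_B))
  expect_true(is.finite(g))
  g2 <- born_sasa_gsol(sh$strand_A, charges = rep(0, nrow(sh$strand_A)))
  expect_gt(g2, -1)   # no charges -> no Born term, small apolar only
})
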