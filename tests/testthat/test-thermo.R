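test_that("area_at_pressure reads the first upward crossing", {
  br <- volmer_branch()
  # closed form: A(10) = 40 + 428.2/15.7
  r <- area_at_pressure(br, 10)
  expect_true(r$attained)
  expect_equal(r$area, 40 + 428.2 / 15.7, tolerance = 1e-6)
  expect_equal(r$area, 67.27, tolerance = 1e-3)
  # exact grid hit: the tabulated point itself, no interpolation
  hit <- area_at_pressure(br, br$pressure[51])
  expect_identical(hit$area, br$area[51])
  # non-spreading film never attains the target
  flat <- isotherm(area = seq(130, 20, length.out = 50),
                   pressure = rep(0, 50))
  r0 <- area_at_pressure(flat, 10)
  expect_false(r0$attained)
  expect_identical(r0$area, 0)
  # a noisy plateau re-crossing resolves to the largest-area crossing
  wig <- isotherm(area = c(100, 90, 80, 70, 60, 50),
                  pressure = c(1, 5, 11, 9, 12, 20))
  expect_equal(area_at_pressure(wig, 10)$area, 90 - 10 * (10 - 5) / 6)
  # unsorted branch is a precondition error
  expect_error(area_at_pressure(isotherm(area = c(1, 2, 3, 4),
                                         pressure = c(1, 2, 3, 4)), 10),
               "compression branch")
})

test_that("ideal mixing line and excess area are exact arithmetic", {
  expect_identical(ideal_mixing_area(80, 40, 0.5), 60)
  expect_identical(ideal_mixing_area(80, 40, 0), 80)
  # unattained component 2 recorded as 0 pulls the line to (1-x2)*a1
  expect_identical(ideal_mixing_area(80, 0, 0.25), 0.75 * 80)
  expect_identical(excess_area(70, 80, 40, 0.5), 10)
  expect_identical(excess_area(80, 80, 40, 0), 0)
  # generator ground truth at pi = 0.5 via readouts
  ex <- excess_params(5, 20)
  p1 <- fix_p1
  pB <- pure_eos_params(A0 = 20, pi_c = 8, kT_term = 428.2, id = "B")
  m <- generate_mixture_isotherm(p1, pB, 0.25, ex, noise_sigma = 0,
                                 seed = 1)
  a12 <- area_at_pressure(m, 0.5)$area
  a1 <- area_at_pressure(generate_pure_isotherm(p1, noise_sigma = 0,
                                                seed = 1), 0.5)$area
  a2 <- area_at_pressure(generate_pure_isotherm(pB, noise_sigma = 0,
                                                seed = 1), 0.5)$area
  expect_equal(excess_area(a12, a1, a2, 0.25),
               excess_area_model(ex, 0.5, 0.25), tolerance = 1e-6)
})

test_that("excess Gibbs energy recovers the closed forms (noiseless)", {
  grid <- pressure_grid()
  i1 <- generate_pure_isotherm(fix_p1, grid, 0, 1)
  i2 <- generate_pure_isotherm(fix_p2, grid, 0, 2)
  # ideal mixture: 0 within +-1 J/mol, both methods
  m0 <- generate_mixture_isotherm(fix_p1, fix_p2, 0.25, excess_params(0),
                                  grid, 0, 3)
  for (meth in c("parts", "grid")) {
    dg0 <- excess_gibbs_energy(m0, i1, i2, 0.25, c(10, 20, 30),
                               method = meth)
    expect_lt(max(abs(dg0)), 1)
  }
  # a_ex = 5, pi_s = 20, x2 = 0.25, pi* = 30 -> 350.9 J/mol within 1%
  ex <- excess_params(5, 20)
  m <- generate_mixture_isotherm(fix_p1, fix_p2, 0.25, ex, grid, 0, 3)
  dg <- excess_gibbs_energy(m, i1, i2, 0.25, 30)
  expect_equal(as.numeric(dg), 350.9, tolerance = 0.01)
  # unattained pure component is reported
  expect_identical(attr(dg, "unattained"), 2L)
  # constant excess (pi_s = Inf), A_ex = 5 at x2 = 0.5, pi* = 20 -> 602.2
  mc <- generate_mixture_isotherm(fix_p1, fix_p2, 0.5,
                                  excess_params(5, Inf), grid, 0, 4)
  dgc <- excess_gibbs_energy(mc, i1, i2, 0.5, 20)
  expect_equal(as.numeric(dgc), 602.2, tolerance = 0.01)
  # pi_star beyond the mixture record is a domain error
  expect_error(excess_gibbs_energy(m, i1, i2, 0.25, 50), "not attained")
})

test_that("endpoint exactness: pure compositions give exactly zero", {
  grid <- pressure_grid()
  i1 <- generate_pure_isotherm(fix_p1, grid, 0, 1)
  i2 <- generate_pure_isotherm(fix_p2, grid, 0, 2)
  for (meth in c("parts", "grid")) {
    dg <- excess_gibbs_energy(i1, i1, i2, 0, c(10, 20, 30), method = meth)
    expect_identical(max(abs(dg)), 0)
  }
})

test_that("grid quadrature converges: step 0.1 vs 10x finer within 0.5%", {
  grid <- pressure_grid()
  i1 <- generate_pure_isotherm(fix_p1, grid, 0, 1)
  i2 <- generate_pure_isotherm(fix_p2, grid, 0, 2)
  ex <- excess_params(5, 20)
  for (x2 in fix_fractions) {
    m <- generate_mixture_isotherm(fix_p1, fix_p2, x2, ex, grid, 0, 3)
    coarse <- excess_gibbs_energy(m, i1, i2, x2, c(10, 20, 30),
                                  grid_step = 0.1, method = "grid")
    fine <- excess_gibbs_energy(m, i1, i2, x2, c(10, 20, 30),
                                grid_step = 0.01, method = "grid")
    expect_equal(as.numeric(coarse), as.numeric(fine), tolerance = 5e-3)
    # and the parts estimator agrees with the fine grid too
    parts <- excess_gibbs_energy(m, i1, i2, x2, c(10, 20, 30))
    expect_equal(as.numeric(parts), as.numeric(fine), tolerance = 5e-3)
  }
})

test_that("fundamental theorem: d(dG_ex)/dpi* tracks 6.022 * A_ex(pi*)", {
  grid <- pressure_grid()
  i1 <- generate_pure_isotherm(fix_p1, grid, 0, 1)
  i2 <- generate_pure_isotherm(fix_p2, grid, 0, 2)
  ex <- excess_params(5, 20)
  m <- generate_mixture_isotherm(fix_p1, fix_p2, 0.25, ex, grid, 0, 3)
  h <- 0.5
  for (pi_star in c(10, 20, 30)) {
    dg <- excess_gibbs_energy(m, i1, i2, 0.25, c(pi_star - h, pi_star + h))
    deriv <- diff(dg) / (2 * h)
    expect_equal(deriv,
                 MNM_A2_PER_MOL_TO_J * excess_area_model(ex, pi_star, 0.25),
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("noisy recovery is unbiased at the few-percent level", {
  # scaled-down spot check (full 100-seed sweep lives in the acceptance
  # suite): 30 seeds, one fraction, one pressure
  grid <- pressure_grid()
  ex <- excess_params(5, 20)
  dg <- vapply(1:30, function(s) {
    i1 <- extract_compression_branch(
      generate_pure_isotherm(fix_p1, grid, 0.1, s * 100 + 1))
    i2 <- extract_compression_branch(
      generate_pure_isotherm(fix_p2, grid, 0.1, s * 100 + 2))
    m <- extract_compression_branch(
      generate_mixture_isotherm(fix_p1, fix_p2, 0.25, ex, grid, 0.1,
                                s * 100 + 3))
    as.numeric(excess_gibbs_energy(m, i1, i2, 0.25, 20))
  }, numeric(1L))
  expect_equal(mean(dg), dgex_closed_form(ex, 0.25, 20), tolerance = 0.05)
})
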