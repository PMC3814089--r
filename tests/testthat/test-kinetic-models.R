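test_that("eigen-rates match the quadratic solution and the system matrix", {
  p <- ref_params()
  a <- alpha_constants(p)
  # frozen values from the closed-form quadratic for the reference set
  expect_equal(a[["alpha1"]], 0.07396014, tolerance = 1e-6)
  expect_equal(a[["alpha2"]], 0.67603986, tolerance = 1e-6)

  # independent oracle: eigenvalues of the 2x2 tissue system matrix
  for (pp in list(p, pet_params(0.1, 1.0, 0.05, 0.2),
                  pet_params(0.5, 0.1, 0.3, 0.01))) {
    M <- matrix(c(-(pp$k2 + pp$k3), pp$k3, pp$k4, -pp$k4), 2, 2)
    ev <- sort(-Re(eigen(M)$values))
    aa <- alpha_constants(pp)
    expect_equal(unname(aa), ev, tolerance = 1e-12)
    expect_lte(aa[["alpha1"]], aa[["alpha2"]])
    # Vieta: product and sum of the roots
    expect_equal(aa[["alpha1"]] * aa[["alpha2"]], pp$k2 * pp$k4,
                 tolerance = 1e-12)
    expect_equal(aa[["alpha1"]] + aa[["alpha2"]], pp$k2 + pp$k3 + pp$k4,
                 tolerance = 1e-12)
  }
})

test_that("near-zero k3 sends the eigen-rates to k2 and k4", {
  a <- alpha_constants(pet_params(0.3, 0.5, 1e-9, 0.1))
  expect_equal(a[["alpha1"]], 0.1, tolerance = 1e-6)
  expect_equal(a[["alpha2"]], 0.5, tolerance = 1e-6)
})

test_that("invalid rate constants are rejected", {
  expect_error(pet_params(0, 0.5, 0.15, 0.1), "positive")
  expect_error(pet_params(0.3, -0.5, 0.15, 0.1), "positive")
  expect_error(pet_params(0.3, 0.5, Inf, 0.1), "positive")
})

test_that("impulse responses have the analytic boundary values", {
  tt <- test_grid(10, 0.1)
  for (pp in list(ref_params(), pet_params(0.2, 0.9, 0.05, 0.18))) {
    h <- compartment_impulse_responses(pp, tt)
    expect_equal(h$h_EES$value[1], pp$K1)   # h_EES(0) = K1
    expect_equal(h$h_EIS$value[1], 0)       # h_EIS(0) = 0
    expect_true(all(h$h_EES$value >= 0) && all(h$h_EIS$value >= 0))
  }
})

test_that("analytic convolution matches a stiff ODE integration of the system", {
  skip_if_not_installed("deSolve")
  tt <- test_grid(60, 1 / 60)  # 1 s sampling
  cp <- test_aif(tt)
  for (pp in list(ref_params(), pet_params(0.4, 0.25, 0.2, 0.1))) {
    cc <- simulate_compartments(pp, cp)
    ode <- ode_compartments(pp, cp)
    expect_lt(max(abs(cc$C_EES$value - ode$ees)) / max(ode$ees), 1e-3)
    expect_lt(max(abs(cc$C_EIS$value - ode$eis)) / max(ode$eis), 1e-3)
  }
})

test_that("simulated compartments are linear in the input and in K1", {
  tt <- test_grid()
  cp <- test_aif(tt)
  p <- ref_params()
  base <- simulate_compartments(p, cp)
  scaled <- simulate_compartments(p, tac(tt, 3.5 * cp$value))
  expect_equal(scaled$C_EES$value, 3.5 * base$C_EES$value, tolerance = 1e-12)
  expect_equal(scaled$C_EIS$value, 3.5 * base$C_EIS$value, tolerance = 1e-12)

  tiny <- simulate_compartments(pet_params(1e-12, p$k2, p$k3, p$k4), cp)
  expect_lt(max(tiny$C_EES$value), 1e-5)

  zero <- simulate_compartments(p, tac(tt, rep(0, length(tt))))
  expect_true(all(zero$C_EES$value == 0) && all(zero$C_EIS$value == 0))
})

test_that("constant input drives the compartments to the analytic steady state", {
  p <- ref_params()
  a <- alpha_constants(p)
  t_end <- 20 / a[["alpha1"]]
  tt <- seq(0, t_end, length.out = 2000)
  cst <- 7.5
  cc <- simulate_compartments(p, tac(tt, rep(cst, length(tt))))
  n <- length(tt)
  expect_equal(cc$C_EES$value[n], p$K1 / p$k2 * cst, tolerance = 0.01)
  expect_equal(cc$C_EIS$value[n], p$K1 * p$k3 / (p$k2 * p$k4) * cst,
               tolerance = 0.01)
})

test_that("near-degenerate eigen-rates use the limit kernels smoothly", {
  # k3 -> 0 with k2 = k4 collapses alpha1 and alpha2; the limit-kernel
  # branch must agree with the two-exponential branch just outside it
  tt <- test_grid(30, 0.25)
  cp <- test_aif(tt)
  near <- simulate_compartments(pet_params(0.3, 0.2, 1e-8, 0.2), cp)
  nearer <- simulate_compartments(pet_params(0.3, 0.2, 1e-12, 0.2), cp)
  expect_equal(near$C_EES$value, nearer$C_EES$value, tolerance = 1e-6)
  h <- compartment_impulse_responses(pet_params(0.3, 0.2, 1e-12, 0.2), tt)
  expect_equal(h$h_EES$value[1], 0.3)
})

test_that("whole-tissue mixture is the volume-weighted sum", {
  tt <- test_grid(5, 0.5)
  cb <- tac(tt, rep(10, length(tt)))
  cees <- tac(tt, rep(4, length(tt)))
  ceis <- tac(tt, rep(2, length(tt)))
  vf <- volume_fractions(0.08, 0.35, 0.57)
  out <- whole_tissue(vf, cb, cees, ceis)
  expect_equal(out$value, rep(3.34, length(tt)))  # 0.8 + 1.4 + 1.14

  expect_equal(whole_tissue(volume_fractions(1, 0, 0), cb, cees, ceis)$value,
               cb$value)
  expect_equal(whole_tissue(volume_fractions(0, 0.5, 0.5), cb, cees, cees)$value,
               cees$value)
  expect_error(whole_tissue(vf, cb, cees, tac(tt + 1, rep(2, length(tt)))),
               "grid")
})

test_that("extended Tofts model reduces correctly and matches the ODE", {
  tt <- test_grid()
  cp <- test_aif(tt)

  # Ktrans = 0: pure plasma component
  out0 <- dce_tissue(dce_params(0, 0.35, 0.05), cp)
  expect_equal(out0$value, 0.05 * cp$value)

  # vp = 0 gives the plain Tofts model, bit-identical
  p_plain <- dce_params(0.25, 0.35, 0)
  p_ext <- dce_params(0.25, 0.35, 0.05)
  plain <- dce_tissue(p_plain, cp)
  ext <- dce_tissue(p_ext, cp)
  expect_identical(plain$value + 0.05 * cp$value, ext$value)

  expect_error(dce_tissue(dce_params(0.25, 0, 0.05), cp), "vEES")

  skip_if_not_installed("deSolve")
  cp_fun <- stats::approxfun(tt, cp$value, rule = 2)
  rhs <- function(t, y, p) {
    list(p$Ktrans * cp_fun(t) - p$Ktrans / p$vEES * y[1])
  }
  ode <- deSolve::lsoda(0, tt, rhs, list(Ktrans = 0.25, vEES = 0.35),
                        rtol = 1e-10, atol = 1e-10)
  model <- ode[, 2] + 0.05 * cp$value
  expect_lt(max(abs(ext$value - model)) / max(model), 1e-3)
})

test_that("constant input drives the plain Tofts model to vEES * Cp", {
  tt <- seq(0, 400, length.out = 4000)
  cst <- 3
  out <- dce_tissue(dce_params(0.25, 0.35, 0), tac(tt, rep(cst, length(tt))))
  expect_equal(out$value[length(tt)], 0.35 * cst, tolerance = 1e-6)
})

test_that("blood/plasma conversion is consistent and invertible", {
  tt <- test_grid(5, 0.5)
  cp <- tac(tt, rep(100, length(tt)))
  expect_equal(blood_from_plasma(cp, 0)$value, cp$value)
  expect_equal(blood_from_plasma(cp, 0.45)$value, rep(55, length(tt)))
  round <- plasma_from_blood(blood_from_plasma(cp, 0.37), 0.37)
  expect_identical(round$value, cp$value)
  expect_error(blood_from_plasma(cp, 1), "hematocrit")

  # v_b * C_b = v_p * C_p under the adopted convention
  vf <- volume_fractions(0.1, 0.4, 0.5, hematocrit = 0.45)
  cb <- blood_from_plasma(cp, 0.45)
  expect_equal(vf$vb * cb$value, vf$vp * cp$value)
})

test_that("TAC and volume-fraction validation catches malformed input", {
  expect_error(tac(c(0, 1), c(1, 2, 3)), "length")
  expect_error(tac(c(1, 0), c(1, 2)), "increasing")
  expect_error(tac(c(0, 1), c(1, NA)), "finite")
  expect_error(volume_fractions(0.5, 0.6, 0.4), "sum to 1")
  expect_error(volume_fractions(0.2, 0.3, 0.5, hematocrit = 1), "hematocrit")
  vf <- volume_fractions(0.08, 0.35, 0.57, hematocrit = 0.45)
  expect_equal(vf$vp, 0.08 * 0.55)
})
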