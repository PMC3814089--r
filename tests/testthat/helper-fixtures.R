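# shared fixtures: the reference parameter set, a short test grid, and a
# deterministic bolus-like input small enough to keep the suite fast

ref_params <- function() pet_params(K1 = 0.3, k2 = 0.5, k3 = 0.15, k4 = 0.1)

test_grid <- function(t_end = 60, dt = 0.25) seq(0, t_end, by = dt)

test_aif <- function(time = test_grid()) generate_aif(aif_params(), time)

# small consistent window: shared truth, per-voxel fractions, no noise
make_consistent_window <- function(params = ref_params(), n = 25, seed = 1,
                                   time = test_grid()) {
  cp <- test_aif(time)
  cb <- blood_from_plasma(cp)
  cc <- simulate_compartments(params, cp)
  vfs <- sample_volume_fractions(n, seed = seed)
  A <- build_design_matrix(vfs)
  list(cp = cp, cb = cb, C_EES = cc$C_EES, C_EIS = cc$C_EIS, vfs = vfs, A = A,
       mixed = mix_window(A, cb, cc$C_EES, cc$C_EIS), time = time)
}

# independent ODE oracle for the three-compartment system driven by an
# interpolated plasma input (requires deSolve)
ode_compartments <- function(params, cp) {
  cp_fun <- stats::approxfun(cp$time, cp$value, rule = 2)
  rhs <- function(t, y, p) {
    list(c(
      p$K1 * cp_fun(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
      p$k3 * y[1] - p$k4 * y[2]))
  }
  out <- deSolve::lsoda(c(0, 0), cp$time, rhs, params,
                        rtol = 1e-10, atol = 1e-10)
  list(ees = out[, 2], eis = out[, 3])
}
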