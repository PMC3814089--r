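#' Parametric arterial input function
#'
#' A smooth stand-in for a measured small-animal left-ventricle input
#' function: a gamma-variate first-pass bolus plus a biexponential washout
#' tail that ramps in with the bolus,
#' \deqn{C_p(t) = A \left(\frac{\Delta}{t_p}\right)^{s} e^{s(1-\Delta/t_p)}
#'   + \left(w_1 e^{-r_1 \Delta} + w_2 e^{-r_2 \Delta}\right)
#'     \left(1 - e^{-\Delta/\tau}\right), \quad \Delta = t - t_0,}
#' zero before arrival \eqn{t_0}. The defaults give a bolus arriving at
#' 0.5 min, peaking near 1 min at roughly 3.9e5 Bq/mL, and washout
#' half-lives of about 2 and 40 min, so that the curve at 0 and 60 min is
#' well under 10% of the peak -- the shape of a typical decay-corrected
#' thymidine-tracer mouse input function.
#'
#' @param t0 Bolus arrival time (min).
#' @param bolus_amp Gamma-variate peak amplitude (concentration units).
#' @param bolus_shape Dimensionless gamma shape.
#' @param bolus_scale Gamma scale (min); the bolus peaks at
#'   `t0 + bolus_shape * bolus_scale`.
#' @param washout_amp1,washout_amp2 Washout amplitudes.
#' @param washout_rate1,washout_rate2 Washout decay rates (1/min).
#' @param ramp Washout ramp-in time constant (min).
#' @return Object of class `"aif_params"`.
#' @export
aif_params <- function(t0 = 0.5,
                       bolus_amp = 3e5, bolus_shape = 3, bolus_scale = 1 / 6,
                       washout_amp1 = 7e4, washout_rate1 = log(2) / 2,
                       washout_amp2 = 4.2e4, washout_rate2 = log(2) / 40,
                       ramp = 0.25) {
  p <- list(t0 = t0, bolus_amp = bolus_amp, bolus_shape = bolus_shape,
            bolus_scale = bolus_scale,
            washout_amp1 = washout_amp1, washout_rate1 = washout_rate1,
            washout_amp2 = washout_amp2, washout_rate2 = washout_rate2,
            ramp = ramp)
  if (!all(vapply(p, is.finite, logical(1)))) {
    stop("AIF parameters must be finite", call. = FALSE)
  }
  if (t0 < 0 || bolus_amp < 0 || washout_amp1 < 0 || washout_amp2 < 0 ||
      bolus_shape <= 0 || bolus_scale <= 0 || ramp <= 0 ||
      washout_rate1 < 0 || washout_rate2 < 0) {
    stop("AIF parameters would produce a negative or ill-defined curve",
         call. = FALSE)
  }
  structure(p, class = "aif_params")
}

#' Evaluate the parametric AIF on a time grid
#'
#' @param p An [aif_params()] object.
#' @param time Time grid (minutes).
#' @return Plasma-input [tac()]; deterministic in `p`.
#' @examples
#' cp <- generate_aif(aif_params(), default_time_grid())
#' @export
generate_aif <- function(p, time) {
  stopifnot(inherits(p, "aif_params"))
  validate_time_grid(time)
  d <- pmax(time - p$t0, 0)
  tp <- p$bolus_shape * p$bolus_scale
  bolus <- p$bolus_amp * (d / tp)^p$bolus_shape * exp(p$bolus_shape * (1 - d / tp))
  washout <- (p$washout_amp1 * exp(-p$washout_rate1 * d) +
              p$washout_amp2 * exp(-p$washout_rate2 * d)) *
             (1 - exp(-d / p$ramp))
  tac(time, bolus + washout)
}

#' Sample per-voxel volume fractions for a window
#'
#' Draws `vb ~ U[0.04, 0.12]` and `vEES ~ U[0.25, 0.45]` independently for
#' each voxel -- the physiological ranges for tumour tissue -- and closes
#' the partition with `vEIS = 1 - (vb + vEES)`.
#'
#' @param n Number of voxels (>= 3).
#' @param vb_range,vees_range Length-2 uniform sampling ranges.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @return Data frame with columns `vb`, `vEES`, `vEIS`; rows sum to 1
#'   exactly by construction.
#' @export
sample_volume_fractions <- function(n, vb_range = c(0.04, 0.12),
                                    vees_range = c(0.25, 0.45), seed = NULL) {
  if (n < 3) stop("need at least 3 voxels", call. = FALSE)
  check_range01(vb_range); check_range01(vees_range)
  if (vb_range[2] + vees_range[2] >= 1) {
    stop("ranges allow vb + vEES >= 1; vEIS would be negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vb <- stats::runif(n, vb_range[1], vb_range[2])
  vees <- stats::runif(n, vees_range[1], vees_range[2])
  data.frame(vb = vb, vEES = vees, vEIS = 1 - (vb + vees))
}

check_range01 <- function(r) {
  if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2] || r[1] < 0 || r[2] > 1) {
    stop("range must be an increasing sub-interval of [0, 1]", call. = FALSE)
  }
  invisible(r)
}

#' Add square-root-scaled Gaussian noise to a tissue curve
#'
#' PET counting noise is emulated by adding, at each time point (and each
#' voxel, when applied to a window matrix), an independent Gaussian
#' perturbation with standard deviation `multiplier * sqrt(value)` -- the
#' noise SD scales with the square root of the local tissue concentration.
#' Zero-concentration samples are left unchanged; negative noisy values are
#' retained (clipping would bias the unbiased least-squares separation).
#'
#' @param x A non-negative [tac()], or a non-negative numeric matrix
#'   (time points x voxels).
#' @param multiplier Noise multiplier `m >= 0`; `m = 0` returns the input
#'   unchanged.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @return Same shape as the input, with noise added.
#' @export
add_tissue_noise <- function(x, multiplier, seed = NULL) {
  if (!is.finite(multiplier) || multiplier < 0) {
    stop("noise multiplier must be >= 0", call. = FALSE)
  }
  if (is_tac(x)) {
    if (any(x$value < 0)) stop("noise model requires a non-negative TAC", call. = FALSE)
    if (multiplier == 0) return(x)
    if (!is.null(seed)) set.seed(seed)
    return(tac(x$time, x$value + stats::rnorm(length(x$value),
                                              sd = multiplier * sqrt(x$value))))
  }
  x <- as.matrix(x)
  if (any(x < 0)) stop("noise model requires non-negative values", call. = FALSE)
  if (multiplier == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  x + stats::rnorm(length(x), sd = multiplier * sqrt(as.vector(x)))
}

#' Perturb MRI-derived volume fractions by a stated 95% confidence interval
#'
#' Emulates measurement error in the DCE-MRI estimates: `vb` and `vEES` are
#' each multiplied by `(1 + delta)` with independent
#' `delta ~ N(0, sigma^2)`, `1.96 * sigma = error_pct / 100`, so that 95%
#' of draws lie within `error_pct` percent of the assigned value. `vEIS` is
#' recomputed as `1 - (vb + vEES)` (the closure keeps rows summing to 1).
#' Rows whose perturbation leaves the physical region (`vb + vEES >= 1` or
#' a non-positive fraction) are redrawn, up to `max_retries` times.
#'
#' @param vfs Data frame with columns `vb`, `vEES` (and optionally `vEIS`).
#' @param error_pct 95% CI half-width as percent of the mean, in \[0, 100).
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @param max_retries Redraw limit per row before erroring.
#' @return Data frame of the same shape; `error_pct = 0` returns the input
#'   unchanged.
#' @export
perturb_volume_fractions <- function(vfs, error_pct, seed = NULL,
                                     max_retries = 100) {
  if (!is.finite(error_pct) || error_pct < 0 || error_pct >= 100) {
    stop("error_pct must lie in [0, 100)", call. = FALSE)
  }
  vfs <- as.data.frame(vfs)
  if (error_pct == 0) {
    vfs$vEIS <- 1 - (vfs$vb + vfs$vEES)
    return(vfs)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- (error_pct / 100) / 1.96
  n <- nrow(vfs)
  vb <- vfs$vb * (1 + stats::rnorm(n, sd = sigma))
  vees <- vfs$vEES * (1 + stats::rnorm(n, sd = sigma))
  bad <- which(vb <= 0 | vees <= 0 | vb + vees >= 1)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_retries) {
      stop("could not draw physical volume fractions after ", max_retries,
           " retries at error_pct = ", error_pct, call. = FALSE)
    }
    vb[bad] <- vfs$vb[bad] * (1 + stats::rnorm(length(bad), sd = sigma))
    vees[bad] <- vfs$vEES[bad] * (1 + stats::rnorm(length(bad), sd = sigma))
    bad <- bad[vb[bad] <= 0 | vees[bad] <= 0 | vb[bad] + vees[bad] >= 1]
  }
  data.frame(vb = vb, vEES = vees, vEIS = 1 - (vb + vees))
}

#' Monte-Carlo study configuration
#'
#' Collects every knob of the simulation study: the experimental conditions
#' (noise multipliers, DCE-error levels), the number of realizations, the
#' window geometry, the physiological sampling ranges, the time grid, the
#' AIF, the haematocrit, the fitting controls and the master seed. The
#' defaults are the study conditions: noise-SD multipliers
#' \{0, 1, 10, 20, 30, 40, 50\}, DCE 95%-CI error levels \{0, 5, 10, 15\}%,
#' 1000 realizations, a 25-voxel (5x5) window, `vb` in \[0.04, 0.12\] and
#' `vEES` in \[0.25, 0.45\], and rate constants drawn uniformly from
#' literature-order ranges (`K1` 0.1-0.5 mL/min/g, `k2` 0.1-1.0, `k3`
#' 0.05-0.3, `k4` 0.01-0.2 1/min).
#'
#' @param noise_multipliers Noise multipliers for [run_noise_sweep()].
#' @param dce_error_levels DCE 95%-CI error levels (%) for
#'   [run_dce_error_sweep()].
#' @param n_realizations Realizations per condition.
#' @param window_size Voxels per window.
#' @param vb_range,vees_range Volume-fraction sampling ranges.
#' @param K1_range,k2_range,k3_range,k4_range Kinetic-parameter sampling
#'   ranges (uniform).
#' @param kinetic_params Optional fixed [pet_params()]; when supplied the
#'   rate constants are held at these values instead of being redrawn each
#'   realization.
#' @param t_end,dt Time grid: 0 to `t_end` minutes in steps of `dt`.
#' @param hematocrit Haematocrit used throughout.
#' @param aif [aif_params()] driving all simulations.
#' @param noise_multiplier_fixed Tissue-noise multiplier used by the
#'   DCE-error sweep.
#' @param fit Logical: fit the rate constants per realization? (Separation
#'   and CCC are computed regardless.)
#' @param n_starts Multi-start count for the per-realization fits.
#' @param seed Master seed; every random stream in a sweep derives from it.
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(noise_multipliers = c(0, 1, 10, 20, 30, 40, 50),
                         dce_error_levels = c(0, 5, 10, 15),
                         n_realizations = 1000,
                         window_size = 25,
                         vb_range = c(0.04, 0.12),
                         vees_range = c(0.25, 0.45),
                         K1_range = c(0.1, 0.5),
                         k2_range = c(0.1, 1.0),
                         k3_range = c(0.05, 0.3),
                         k4_range = c(0.01, 0.2),
                         kinetic_params = NULL,
                         t_end = 60, dt = 1 / 6,
                         hematocrit = 0.45,
                         aif = aif_params(),
                         noise_multiplier_fixed = 1,
                         fit = TRUE,
                         n_starts = 8,
                         seed = 1L) {
  stopifnot(n_realizations >= 1, window_size >= 3,
            inherits(aif, "aif_params"),
            is.null(kinetic_params) || inherits(kinetic_params, "pet_params"))
  check_range01(vb_range); check_range01(vees_range)
  check_hct(hematocrit)
  structure(list(
    noise_multipliers = noise_multipliers,
    dce_error_levels = dce_error_levels,
    n_realizations = as.integer(n_realizations),
    window_size = as.integer(window_size),
    vb_range = vb_range, vees_range = vees_range,
    K1_range = K1_range, k2_range = k2_range,
    k3_range = k3_range, k4_range = k4_range,
    kinetic_params = kinetic_params,
    t_end = t_end, dt = dt,
    hematocrit = hematocrit,
    aif = aif,
    noise_multiplier_fixed = noise_multiplier_fixed,
    fit = isTRUE(fit),
    n_starts = as.integer(n_starts),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' The eight reference kinetic-parameter combinations
#'
#' A documented 2^3 factorial of low/high `K1` (0.15/0.4 mL/min/g),
#' `k2` (0.25/0.75 1/min) and `k3` (0.08/0.2 1/min) with `k4` fixed at
#' 0.1 1/min -- eight combinations bracketing the reference parameter set
#' `(K1, k2, k3, k4) = (0.3, 0.5, 0.15, 0.1)` used in single-realization
#' illustrations.
#'
#' @return Data frame with 8 rows and columns `K1`, `k2`, `k3`, `k4`.
#' @export
param_combinations <- function() {
  g <- expand.grid(K1 = c(0.15, 0.4), k2 = c(0.25, 0.75), k3 = c(0.08, 0.2),
                   KEEP.OUT.ATTRS = FALSE)
  g$k4 <- 0.1
  g
}

# deterministic ground truth for one realization: rate constants, true
# compartment curves, window fractions and the noiseless voxel mixtures
realize_truth <- function(config, cp, cb, r_seed) {
  set.seed(r_seed)
  params <- if (is.null(config$kinetic_params)) {
    pet_params(K1 = stats::runif(1, config$K1_range[1], config$K1_range[2]),
               k2 = stats::runif(1, config$k2_range[1], config$k2_range[2]),
               k3 = stats::runif(1, config$k3_range[1], config$k3_range[2]),
               k4 = stats::runif(1, config$k4_range[1], config$k4_range[2]))
  } else {
    config$kinetic_params
  }
  vfs <- sample_volume_fractions(config$window_size, config$vb_range,
                                 config$vees_range)
  fit_seed <- sample.int(.Machine$integer.max - 1L, 1)
  cc <- simulate_compartments(params, cp)
  A <- build_design_matrix(vfs)
  list(params = params, vfs = vfs, A = A,
       C_EES = cc$C_EES, C_EIS = cc$C_EIS, cb = cb,
       mixed = mix_window(A, cb, cc$C_EES, cc$C_EIS),
       fit_seed = fit_seed)
}

# noise + separation + metrics + (optional) fit for one condition cell;
# A_sep is the design matrix used for separation (perturbed in the DCE sweep)
measure_cell <- function(truth, config, multiplier, A_sep, time) {
  noisy <- add_tissue_noise(truth$mixed, multiplier)
  sep <- separate_tacs(A_sep, window_observation(time, noisy))
  row <- list(
    ccc_cb = concordance_correlation(truth$cb$value, sep$Cb$value),
    ccc_cees = concordance_correlation(truth$C_EES$value, sep$C_EES$value),
    ccc_ceis = concordance_correlation(truth$C_EIS$value, sep$C_EIS$value),
    K1_true = truth$params$K1, k2_true = truth$params$k2,
    k3_true = truth$params$k3, k4_true = truth$params$k4,
    K1_fit = NA_real_, k2_fit = NA_real_, k3_fit = NA_real_, k4_fit = NA_real_,
    err_K1_pct = NA_real_, err_k2_pct = NA_real_,
    err_k3_pct = NA_real_, err_k4_pct = NA_real_,
    converged = NA)
  if (config$fit) {
    cp_est <- plasma_from_blood(sep$Cb, config$hematocrit)
    fit <- fit_pet_kinetics(cp_est, sep$C_EES, sep$C_EIS,
                            n_starts = config$n_starts,
                            seed = truth$fit_seed,
                            truth = truth$params)
    row$K1_fit <- fit$params$K1; row$k2_fit <- fit$params$k2
    row$k3_fit <- fit$params$k3; row$k4_fit <- fit$params$k4
    e <- fit$per_parameter_relative_error
    row$err_K1_pct <- e[["K1"]]; row$err_k2_pct <- e[["k2"]]
    row$err_k3_pct <- e[["k3"]]; row$err_k4_pct <- e[["k4"]]
    row$converged <- fit$converged
  }
  row
}

# seed tables derived from the master seed; the realization stream (truth)
# is shared across conditions so conditions are compared on the same draws
derive_seeds <- function(master, n_cond, n_real) {
  set.seed(master)
  list(realization = sample.int(.Machine$integer.max - 1L, n_real),
       cell = matrix(sample.int(.Machine$integer.max - 1L, n_cond * n_real),
                     nrow = n_cond))
}

run_sweep <- function(config, conditions, condition_label, sep_design) {
  time <- default_time_grid(config$t_end, config$dt)
  cp <- generate_aif(config$aif, time)
  cb <- blood_from_plasma(cp, config$hematocrit)
  n_cond <- length(conditions)
  n_real <- config$n_realizations
  seeds <- derive_seeds(config$seed, n_cond, n_real)
  rows <- vector("list", n_cond * n_real)
  k <- 0L
  for (r in seq_len(n_real)) {
    truth <- realize_truth(config, cp, cb, seeds$realization[r])
    for (ci in seq_len(n_cond)) {
      set.seed(seeds$cell[ci, r])
      cell <- sep_design(truth, config, conditions[ci], time)
      k <- k + 1L
      rows[[k]] <- c(list(condition = conditions[ci], realization = r,
                          seed = seeds$cell[ci, r]), cell)
    }
  }
  out <- do.call(rbind, lapply(rows, function(x) as.data.frame(x)))
  names(out)[names(out) == "condition"] <- condition_label
  attr(out, "config") <- config
  class(out) <- c("study_result", class(out))
  out
}

#' Monte-Carlo sweep over tissue-noise levels
#'
#' For each noise multiplier and each realization: draw rate constants and
#' window volume fractions, simulate the true compartment curves from the
#' AIF, mix them into 25 per-voxel whole-tissue curves, add independent
#' sqrt-scaled noise per voxel and time point, separate with the *exact*
#' design matrix, score each separated curve against truth with the
#' concordance correlation coefficient, and (optionally) refit the four
#' rate constants from the separated curves. Fully reproducible: the same
#' config and master seed give a bit-identical result table, and the truth
#' stream is shared across noise levels so levels differ only in noise.
#'
#' @param config A [study_config()].
#' @return A `"study_result"` data frame with one row per
#'   (noise multiplier, realization): CCC per compartment, true and fitted
#'   rate constants, per-parameter relative errors (%), and the cell seed.
#' @export
run_noise_sweep <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  run_sweep(config, config$noise_multipliers, "noise_multiplier",
            function(truth, cfg, m, time) {
              measure_cell(truth, cfg, m, truth$A, time)
            })
}

#' Monte-Carlo sweep over DCE-MRI parameter error
#'
#' As [run_noise_sweep()], but the tissue-noise multiplier is held at
#' `config$noise_multiplier_fixed` (default 1) and the volume fractions
#' used for *separation* are perturbed at each DCE error level (the voxel
#' mixtures are always formed with the true fractions): `vb` and `vEES`
#' acquire multiplicative Gaussian error whose 95% CI is the stated
#' percentage of the assigned value.
#'
#' @param config A [study_config()].
#' @return A `"study_result"` data frame with one row per
#'   (DCE error level %, realization).
#' @export
run_dce_error_sweep <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  run_sweep(config, config$dce_error_levels, "dce_error_pct",
            function(truth, cfg, err, time) {
              vfs_sep <- perturb_volume_fractions(truth$vfs, err)
              A_sep <- build_design_matrix(vfs_sep)
              measure_cell(truth, cfg, cfg$noise_multiplier_fixed, A_sep, time)
            })
}

#' Simulate, separate and fit a single window realization
#'
#' Convenience wrapper running the full chain once at a chosen noise
#' multiplier and DCE error level; useful for plots and for inspecting the
#' pipeline the sweeps aggregate over.
#'
#' @param config A [study_config()].
#' @param noise_multiplier Tissue-noise multiplier.
#' @param dce_error_pct DCE 95%-CI error level (%).
#' @param seed Realization seed.
#' @return List with the ground truth (`params`, `vfs`, true TACs), the
#'   noisy window observation, the separated `"compartment_tacs"`, the
#'   per-compartment CCCs and (when `config$fit`) the `"fit_result"`.
#' @export
run_single_realization <- function(config = study_config(),
                                   noise_multiplier = 1,
                                   dce_error_pct = 0,
                                   seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  time <- default_time_grid(config$t_end, config$dt)
  cp <- generate_aif(config$aif, time)
  cb <- blood_from_plasma(cp, config$hematocrit)
  seeds <- derive_seeds(seed, 1L, 1L)
  truth <- realize_truth(config, cp, cb, seeds$realization[1])
  set.seed(seeds$cell[1, 1])
  vfs_sep <- perturb_volume_fractions(truth$vfs, dce_error_pct)
  A_sep <- build_design_matrix(vfs_sep)
  noisy <- add_tissue_noise(truth$mixed, noise_multiplier)
  obs <- window_observation(time, noisy)
  sep <- separate_tacs(A_sep, obs)
  res <- list(
    cp = cp,
    truth = truth,
    observation = obs,
    separated = sep,
    ccc = c(Cb = concordance_correlation(truth$cb$value, sep$Cb$value),
            C_EES = concordance_correlation(truth$C_EES$value, sep$C_EES$value),
            C_EIS = concordance_correlation(truth$C_EIS$value, sep$C_EIS$value)))
  if (config$fit) {
    res$fit <- fit_pet_kinetics(plasma_from_blood(sep$Cb, config$hematocrit),
                                sep$C_EES, sep$C_EIS,
                                n_starts = config$n_starts,
                                seed = truth$fit_seed, truth = truth$params)
  }
  res
}
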