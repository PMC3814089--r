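#' Simultaneous two-curve fit of the PET rate constants
#'
#' Recovers `(K1, k2, k3, k4)` from separated EES and EIS curves by
#' minimising the joint sum of squares
#' \deqn{\|C_{EES}^{obs} - C_p \otimes h_{EES}\|^2 + \|C_{EIS}^{obs} - C_p \otimes h_{EIS}\|^2}
#' over the four rate constants: both residual vectors are stacked into one
#' and optimised simultaneously with equal weight by bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]). Given both
#' tissue curves and the input, the model is structurally identifiable, so
#' noiseless data are recovered to optimiser precision.
#'
#' Multi-start initialisation guards against local minima: one start at the
#' centre of the bounds plus `n_starts - 1` seeded Latin-hypercube draws;
#' the start with the lowest residual wins (ties: first found).
#'
#' @param cp Plasma input [tac()] (typically `plasma_from_blood()` of the
#'   separated blood curve; may contain negative noise excursions).
#' @param c_ees_obs,c_eis_obs Observed (separated) EES and EIS [tac()]s.
#' @param bounds List with numeric `lower`/`upper` vectors of length 4
#'   (order K1, k2, k3, k4).
#' @param init_strategy `"multistart"` (default) or `"center"` (single
#'   start, no random draws).
#' @param n_starts Number of starts when `init_strategy = "multistart"`.
#' @param seed Integer seed for the Latin-hypercube draws; fitting is
#'   deterministic given inputs, bounds, strategy and seed.
#' @param truth Optional [pet_params()]; when given, per-parameter relative
#'   errors (%) are included in the result.
#' @return Object of class `"fit_result"`: list with `params`
#'   ([pet_params()]), `residual_norm` (sum of squared residuals),
#'   `converged`, `n_iterations`, `start_used` and (optionally)
#'   `per_parameter_relative_error`.
#' @examples
#' tt <- default_time_grid()
#' cp <- generate_aif(aif_params(), tt)
#' truth <- pet_params(0.3, 0.5, 0.15, 0.1)
#' cc <- simulate_compartments(truth, cp)
#' fit <- fit_pet_kinetics(cp, cc$C_EES, cc$C_EIS, truth = truth)
#' fit$per_parameter_relative_error
#' @export
fit_pet_kinetics <- function(cp, c_ees_obs, c_eis_obs,
                             bounds = pet_fit_bounds(),
                             init_strategy = c("multistart", "center"),
                             n_starts = 8, seed = 1L, truth = NULL) {
  stopifnot(is_tac(cp), is_tac(c_ees_obs), is_tac(c_eis_obs))
  init_strategy <- match.arg(init_strategy)
  stopifnot_same_grid(cp, c_ees_obs, c_eis_obs)
  check_bounds(bounds, 4)
  time <- cp$time
  x <- cp$value
  obs <- c(c_ees_obs$value, c_eis_obs$value)

  residual <- function(par) {
    cv <- pet_curves_raw(par[1], par[2], par[3], par[4], time, x)
    c(cv$ees, cv$eis) - obs
  }
  out <- run_multistart(residual, bounds, init_strategy, n_starts, seed)
  res <- list(params = pet_params(out$par[1], out$par[2], out$par[3], out$par[4]),
              residual_norm = out$deviance,
              converged = out$converged,
              n_iterations = out$niter,
              start_used = out$start_used)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "pet_params"))
    res$per_parameter_relative_error <- c(
      K1 = relative_error_pct(out$par[1], truth$K1),
      k2 = relative_error_pct(out$par[2], truth$k2),
      k3 = relative_error_pct(out$par[3], truth$k3),
      k4 = relative_error_pct(out$par[4], truth$k4))
  }
  structure(res, class = "fit_result")
}

#' Default box bounds for the PET rate-constant fit
#'
#' Broad boxes spanning well beyond the physiological sampling ranges:
#' `K1` in \[1e-4, 2\] mL/min/g and `k2, k3, k4` in \[1e-4, 3\] 1/min.
#'
#' @return List with `lower` and `upper` named numeric vectors.
#' @export
pet_fit_bounds <- function() {
  list(lower = c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, k4 = 1e-4),
       upper = c(K1 = 2,    k2 = 3,    k3 = 3,    k4 = 3))
}

#' Fit the extended Tofts model to a DCE-MRI tissue curve
#'
#' Least-squares estimation of `(Ktrans, vEES, vp)` from a tissue curve and
#' plasma input, with the same bounded multi-start Levenberg-Marquardt
#' machinery as [fit_pet_kinetics()]. The fitted fractions map onto the PET
#' separation inputs via [dce_to_volume_fractions()].
#'
#' @param c_tissue Observed tissue [tac()].
#' @param cp Plasma input [tac()] on the same grid.
#' @param bounds List with `lower`/`upper` vectors of length 3 (order
#'   Ktrans, vEES, vp).
#' @param init_strategy,n_starts,seed As in [fit_pet_kinetics()].
#' @param truth Optional [dce_params()] for relative-error reporting.
#' @return `"fit_result"` whose `params` is a [dce_params()].
#' @export
fit_dce_tofts <- function(c_tissue, cp,
                          bounds = dce_fit_bounds(),
                          init_strategy = c("multistart", "center"),
                          n_starts = 8, seed = 1L, truth = NULL) {
  stopifnot(is_tac(c_tissue), is_tac(cp))
  init_strategy <- match.arg(init_strategy)
  stopifnot_same_grid(c_tissue, cp)
  check_bounds(bounds, 3)
  time <- cp$time
  x <- cp$value
  obs <- c_tissue$value

  residual <- function(par) {
    model <- if (par[1] <= 0) {
      par[3] * x
    } else {
      par[1] * conv_exp(x, time, par[1] / par[2]) + par[3] * x
    }
    model - obs
  }
  out <- run_multistart(residual, bounds, init_strategy, n_starts, seed)
  res <- list(params = dce_params(out$par[1], out$par[2], out$par[3]),
              residual_norm = out$deviance,
              converged = out$converged,
              n_iterations = out$niter,
              start_used = out$start_used)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "dce_params"))
    err <- c(Ktrans = if (truth$Ktrans != 0)
               relative_error_pct(out$par[1], truth$Ktrans) else NA_real_,
             vEES = relative_error_pct(out$par[2], truth$vEES),
             vp = if (truth$vp != 0)
               relative_error_pct(out$par[3], truth$vp) else NA_real_)
    res$per_parameter_relative_error <- err
  }
  structure(res, class = "fit_result")
}

#' Default box bounds for the extended Tofts fit
#' @return List with `lower` and `upper` named numeric vectors.
#' @export
dce_fit_bounds <- function() {
  list(lower = c(Ktrans = 0,   vEES = 1e-3, vp = 0),
       upper = c(Ktrans = 2,   vEES = 1,    vp = 0.5))
}

#' @rdname fit_pet_kinetics
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      sprintf("after %d iterations (start %d), SSR = %.6g\n",
              x$n_iterations, x$start_used, x$residual_norm))
  print(x$params)
  if (!is.null(x$per_parameter_relative_error)) {
    cat("  relative error (%):",
        paste(names(x$per_parameter_relative_error),
              sprintf("%.3g", x$per_parameter_relative_error),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

check_bounds <- function(bounds, k) {
  if (!is.list(bounds) || !all(c("lower", "upper") %in% names(bounds)) ||
      length(bounds$lower) != k || length(bounds$upper) != k ||
      any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)) ||
      any(bounds$upper <= bounds$lower)) {
    stop("`bounds` must be a list with finite `lower` < `upper` vectors of length ",
         k, call. = FALSE)
  }
  invisible(bounds)
}

# shared multi-start driver around minpack.lm::nls.lm
run_multistart <- function(residual, bounds, init_strategy, n_starts, seed) {
  lo <- as.numeric(bounds$lower)
  hi <- as.numeric(bounds$upper)
  k <- length(lo)
  starts <- matrix((lo + hi) / 2, nrow = 1)
  if (init_strategy == "multistart" && n_starts > 1) {
    # local RNG scope: the fit must not perturb the caller's stream
    rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1, k)
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8, maxiter = 500)
  best <- NULL
  best_i <- 0L
  failures <- character(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = residual, control = ctrl),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best_i <- i
    }
  }
  if (is.null(best)) {
    stop("all ", nrow(starts), " optimisation starts failed: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }
  list(par = best$par,
       deviance = best$deviance,
       converged = best$info %in% 1:3,
       niter = best$niter,
       start_used = best_i)
}
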