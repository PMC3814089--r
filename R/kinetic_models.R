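#' Eigen-rates of the two-tissue subsystem
#'
#' The EES and EIS mass-balance equations form a linear 2x2 system whose
#' impulse response is biexponential with decay rates
#' \deqn{\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}}{2}.}
#' The discriminant equals \eqn{(k_2+k_3-k_4)^2 + 4 k_3 k_4} and is
#' therefore positive for any positive rates; both roots are real with
#' \eqn{0 < \alpha_1 \le \alpha_2}.
#'
#' @param params A [pet_params()] object.
#' @return Named numeric vector `c(alpha1, alpha2)` in 1/min, `alpha1 <= alpha2`.
#' @examples
#' alpha_constants(pet_params(0.3, 0.5, 0.15, 0.1))
#' @export
alpha_constants <- function(params) {
  stopifnot(inherits(params, "pet_params"))
  s <- params$k2 + params$k3 + params$k4
  disc <- s^2 - 4 * params$k2 * params$k4
  sq <- sqrt(max(disc, 0))
  alpha2 <- (s + sq) / 2
  # small root via the product alpha1*alpha2 = k2*k4 (avoids cancellation)
  alpha1 <- params$k2 * params$k4 / alpha2
  c(alpha1 = alpha1, alpha2 = alpha2)
}

# relative gap below which the repeated-root (t e^(-at)) kernels are used
.degenerate_tol <- 1e-10

#' Compartment impulse responses
#'
#' Analytic responses of the EES and EIS compartments to a unit plasma
#' impulse:
#' \deqn{h_{EES}(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_4-\alpha_1)e^{-\alpha_1 t} + (\alpha_2-k_4)e^{-\alpha_2 t}\right]}
#' \deqn{h_{EIS}(t) = \frac{K_1 k_3}{\alpha_2-\alpha_1}\left[e^{-\alpha_1 t} - e^{-\alpha_2 t}\right]}
#' When \eqn{\alpha_1 = \alpha_2 = \alpha} (repeated root, e.g. k3 -> 0 with
#' k2 = k4) the analytic limits
#' \eqn{h_{EES} = K_1 e^{-\alpha t}(1 + (k_4-\alpha) t)} and
#' \eqn{h_{EIS} = K_1 k_3\, t e^{-\alpha t}} are used instead of the 0/0 form.
#'
#' @param params A [pet_params()] object.
#' @param time Time grid (minutes).
#' @return List with elements `h_EES` and `h_EIS`, both [tac()] objects
#'   (units 1/min).
#' @export
compartment_impulse_responses <- function(params, time) {
  stopifnot(inherits(params, "pet_params"))
  validate_time_grid(time)
  a <- alpha_constants(params)
  a1 <- a[["alpha1"]]; a2 <- a[["alpha2"]]
  if ((a2 - a1) < .degenerate_tol * (a1 + a2)) {
    al <- (a1 + a2) / 2
    h_ees <- params$K1 * exp(-al * time) * (1 + (params$k4 - al) * time)
    h_eis <- params$K1 * params$k3 * time * exp(-al * time)
  } else {
    e1 <- exp(-a1 * time); e2 <- exp(-a2 * time)
    h_ees <- params$K1 / (a2 - a1) * ((params$k4 - a1) * e1 + (a2 - params$k4) * e2)
    h_eis <- params$K1 * params$k3 / (a2 - a1) * (e1 - e2)
  }
  list(h_EES = tac(time, h_ees), h_EIS = tac(time, h_eis))
}

#' Simulate EES and EIS concentration curves from a plasma input
#'
#' Convolves the plasma input with the analytic impulse responses,
#' \eqn{C_{EES} = C_p \otimes h_{EES}} and \eqn{C_{EIS} = C_p \otimes h_{EIS}},
#' using the exact piecewise-linear exponential-convolution recursion.
#'
#' @param params A [pet_params()] object.
#' @param cp Plasma input [tac()] (non-negative).
#' @return List with `C_EES` and `C_EIS` [tac()] objects on `cp`'s grid.
#' @examples
#' tt <- default_time_grid()
#' cp <- generate_aif(aif_params(), tt)
#' cc <- simulate_compartments(pet_params(0.3, 0.5, 0.15, 0.1), cp)
#' @export
simulate_compartments <- function(params, cp) {
  stopifnot(inherits(params, "pet_params"), is_tac(cp))
  if (any(cp$value < 0)) {
    stop("plasma input must be non-negative", call. = FALSE)
  }
  cv <- pet_curves_raw(params$K1, params$k2, params$k3, params$k4,
                       cp$time, cp$value)
  # roundoff guard: analytic responses to a non-negative input are non-negative
  list(C_EES = tac(cp$time, pmax(cv$ees, 0)),
       C_EIS = tac(cp$time, pmax(cv$eis, 0)))
}

# model curves without validation or clamping; also the fitting kernel,
# where the driving input is a separated (noisy, possibly negative) curve
pet_curves_raw <- function(K1, k2, k3, k4, time, x) {
  s <- k2 + k3 + k4
  a2 <- (s + sqrt(max(s^2 - 4 * k2 * k4, 0))) / 2
  a1 <- k2 * k4 / a2
  if ((a2 - a1) < .degenerate_tol * (a1 + a2)) {
    al <- (a1 + a2) / 2
    w <- conv_exp(x, time, al)
    wt <- conv_texp(x, time, al)
    list(ees = K1 * (w + (k4 - al) * wt),
         eis = K1 * k3 * wt)
  } else {
    w1 <- conv_exp(x, time, a1)
    w2 <- conv_exp(x, time, a2)
    list(ees = K1 / (a2 - a1) * ((k4 - a1) * w1 + (a2 - k4) * w2),
         eis = K1 * k3 / (a2 - a1) * (w1 - w2))
  }
}

#' Whole-tissue mixture curve
#'
#' The measured tissue concentration is the volume-weighted sum of the
#' compartment concentrations,
#' \eqn{C_{tissue}(t) = v_b C_b(t) + v_{EES} C_{EES}(t) + v_{EIS} C_{EIS}(t)}.
#'
#' @param vf A [volume_fractions()] object.
#' @param cb,c_ees,c_eis Compartment [tac()]s on one shared grid.
#' @return Whole-tissue [tac()].
#' @export
whole_tissue <- function(vf, cb, c_ees, c_eis) {
  stopifnot(inherits(vf, "volume_fractions"),
            is_tac(cb), is_tac(c_ees), is_tac(c_eis))
  stopifnot_same_grid(cb, c_ees, c_eis)
  tac(cb$time, vf$vb * cb$value + vf$vEES * c_ees$value + vf$vEIS * c_eis$value)
}

#' Extended Tofts tissue curve
#'
#' The DCE-MRI contrast agent stays extracellular, so its tissue curve is
#' \deqn{C_{tissue}(t) = K^{trans} e^{-K^{trans} t / v_{EES}} \otimes C_p(t) + v_p C_p(t).}
#' With `vp = 0` this is the standard (non-extended) Tofts model; the two
#' coincide exactly in that case.
#'
#' @param params A [dce_params()] object.
#' @param cp Plasma input [tac()].
#' @return Tissue [tac()] on `cp`'s grid.
#' @export
dce_tissue <- function(params, cp) {
  stopifnot(inherits(params, "dce_params"), is_tac(cp))
  if (params$Ktrans == 0) {
    return(tac(cp$time, params$vp * cp$value))
  }
  if (params$vEES <= 0) {
    stop("vEES must be positive when Ktrans > 0", call. = FALSE)
  }
  conv <- conv_exp(cp$value, cp$time, params$Ktrans / params$vEES)
  tac(cp$time, params$Ktrans * conv + params$vp * cp$value)
}

#' Convert between whole-blood and plasma concentration curves
#'
#' The model tracks the tracer in plasma; the separation recovers the
#' whole-blood curve. Under the convention adopted here -- tracer confined
#' to plasma with no red-cell uptake -- the two are proportional:
#' \eqn{C_b = (1 - Hct) C_p}, so that \eqn{v_b C_b = v_p C_p} holds
#' identically. Erythrocyte tracer uptake is not modelled.
#'
#' @param cp,cb Plasma / whole-blood [tac()].
#' @param hematocrit Haematocrit in \[0, 1).
#' @return The converted [tac()].
#' @export
blood_from_plasma <- function(cp, hematocrit = 0.45) {
  stopifnot(is_tac(cp))
  check_hct(hematocrit)
  tac(cp$time, (1 - hematocrit) * cp$value)
}

#' @rdname blood_from_plasma
#' @export
plasma_from_blood <- function(cb, hematocrit = 0.45) {
  stopifnot(is_tac(cb))
  check_hct(hematocrit)
  tac(cb$time, cb$value / (1 - hematocrit))
}

check_hct <- function(hematocrit) {
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("hematocrit must lie in [0, 1)", call. = FALSE)
  }
  invisible(hematocrit)
}
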