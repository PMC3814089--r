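#' PET kinetic rate constants
#'
#' The four first-order rate constants of the three-physical-compartment
#' tracer model: `K1` (plasma -> EES delivery, mL/min/g; treated numerically
#' as 1/min under a 1 g/mL tissue-density convention), `k2` (EES -> plasma),
#' `k3` (EES -> EIS) and `k4` (EIS -> EES), all in 1/min. All four must be
#' strictly positive.
#'
#' @param K1,k2,k3,k4 Positive scalars.
#' @return Object of class `"pet_params"`.
#' @seealso [alpha_constants()] for the derived eigen-rates.
#' @examples
#' pet_params(K1 = 0.3, k2 = 0.5, k3 = 0.15, k4 = 0.1)
#' @export
pet_params <- function(K1, k2, k3, k4) {
  p <- c(K1 = as.numeric(K1), k2 = as.numeric(k2),
         k3 = as.numeric(k3), k4 = as.numeric(k4))
  if (!all(is.finite(p)) || any(p <= 0)) {
    stop("all rate constants (K1, k2, k3, k4) must be finite and strictly positive",
         call. = FALSE)
  }
  # discriminant (k2+k3+k4)^2 - 4 k2 k4 = (k2+k3-k4)^2 + 4 k3 k4 > 0 for
  # positive rates; assert numerically anyway
  s <- p[["k2"]] + p[["k3"]] + p[["k4"]]
  disc <- s^2 - 4 * p[["k2"]] * p[["k4"]]
  if (disc < -1e-12 * s^2) {
    stop("negative eigen-rate discriminant; rate constants are not physical",
         call. = FALSE)
  }
  structure(as.list(p), class = "pet_params")
}

#' @rdname pet_params
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.pet_params <- function(x, ...) {
  a <- alpha_constants(x)
  cat(sprintf("<pet_params> K1=%.4g mL/min/g, k2=%.4g, k3=%.4g, k4=%.4g 1/min (alpha1=%.4g, alpha2=%.4g)\n",
              x$K1, x$k2, x$k3, x$k4, a[["alpha1"]], a[["alpha2"]]))
  invisible(x)
}

#' Per-voxel tissue volume fractions
#'
#' The blood (`vb`), extravascular-extracellular (`vEES`) and
#' extravascular-intracellular (`vEIS`) volume fractions of a voxel. The
#' three fractions partition the voxel: they must lie in \[0, 1\] and sum to
#' one. The plasma fraction follows as `vp = vb * (1 - hematocrit)`.
#'
#' @param vb,vEES,vEIS Fractions in \[0, 1\] summing to 1 (within 1e-9).
#' @param hematocrit Haematocrit in \[0, 1); default 0.45, a typical
#'   large-vessel value.
#' @return Object of class `"volume_fractions"` with an additional derived
#'   field `vp`.
#' @examples
#' volume_fractions(vb = 0.08, vEES = 0.35, vEIS = 0.57)
#' @export
volume_fractions <- function(vb, vEES, vEIS = 1 - vb - vEES,
                             hematocrit = 0.45) {
  v <- c(vb, vEES, vEIS)
  if (!all(is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("volume fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(v) - 1) > 1e-9) {
    stop("volume fractions must sum to 1 (got ", format(sum(v)), ")",
         call. = FALSE)
  }
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("hematocrit must lie in [0, 1)", call. = FALSE)
  }
  structure(list(vb = vb, vEES = vEES, vEIS = vEIS,
                 hematocrit = hematocrit,
                 vp = vb * (1 - hematocrit)),
            class = "volume_fractions")
}

#' @rdname volume_fractions
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.volume_fractions <- function(x, ...) {
  cat(sprintf("<volume_fractions> vb=%.4g, vEES=%.4g, vEIS=%.4g (Hct=%.2f, vp=%.4g)\n",
              x$vb, x$vEES, x$vEIS, x$hematocrit, x$vp))
  invisible(x)
}

#' Extended Tofts model parameters
#'
#' Parameters of the extended Tofts DCE-MRI model: the volume transfer
#' constant `Ktrans` (mL blood / mL tissue / min), the EES fraction `vEES`
#' and the plasma fraction `vp`.
#'
#' @param Ktrans Non-negative transfer constant.
#' @param vEES,vp Fractions in \[0, 1\] with `vEES + vp <= 1`.
#' @return Object of class `"dce_params"`.
#' @examples
#' dce_params(Ktrans = 0.25, vEES = 0.35, vp = 0.05)
#' @export
dce_params <- function(Ktrans, vEES, vp = 0) {
  if (!is.finite(Ktrans) || Ktrans < 0) {
    stop("Ktrans must be finite and >= 0", call. = FALSE)
  }
  if (!all(is.finite(c(vEES, vp))) || vEES < 0 || vEES > 1 || vp < 0 || vp > 1) {
    stop("vEES and vp must lie in [0, 1]", call. = FALSE)
  }
  if (vEES + vp > 1 + 1e-12) {
    stop("vEES + vp must not exceed 1", call. = FALSE)
  }
  structure(list(Ktrans = Ktrans, vEES = vEES, vp = vp),
            class = "dce_params")
}

#' Map extended Tofts estimates onto PET-model volume fractions
#'
#' DCE-MRI fitting returns `(Ktrans, vEES, vp)`; the PET separation needs
#' `(vb, vEES, vEIS)`. The blood fraction is recovered from the plasma
#' fraction via the haematocrit, `vb = vp / (1 - Hct)`, and the
#' intracellular fraction closes the partition, `vEIS = 1 - vb - vEES`.
#'
#' @param params A [dce_params()] object.
#' @param hematocrit Haematocrit in \[0, 1).
#' @return A [volume_fractions()] object.
#' @export
dce_to_volume_fractions <- function(params, hematocrit = 0.45) {
  stopifnot(inherits(params, "dce_params"))
  vb <- params$vp / (1 - hematocrit)
  volume_fractions(vb = vb, vEES = params$vEES, vEIS = 1 - vb - params$vEES,
                   hematocrit = hematocrit)
}
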