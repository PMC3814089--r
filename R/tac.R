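#' Time-activity curve (TAC)
#'
#' The basic data object of the package: a tracer-concentration time course
#' sampled on a strictly increasing time grid. Times are in minutes; values
#' are concentrations in whatever activity unit the acquisition uses
#' (e.g. kBq/mL for PET, mM for DCE-MRI). Noise-free model output is
#' non-negative; noisy measurements may dip below zero and are kept as-is.
#'
#' @param time Numeric vector of sample times in minutes; strictly
#'   increasing, finite, first element >= 0, length >= 2.
#' @param value Numeric vector of concentrations, same length as `time`.
#' @return An object of class `"tac"`: a list with elements `time` and
#'   `value`.
#' @examples
#' tt <- seq(0, 60, by = 1 / 6)
#' curve <- tac(tt, exp(-0.1 * tt))
#' @export
tac <- function(time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  validate_time_grid(time)
  if (length(value) != length(time)) {
    stop("`value` must have the same length as `time` (",
         length(value), " vs ", length(time), ")", call. = FALSE)
  }
  if (!all(is.finite(value))) {
    stop("TAC values must all be finite", call. = FALSE)
  }
  structure(list(time = time, value = value), class = "tac")
}

#' @rdname tac
#' @param x Object to test or print.
#' @export
is_tac <- function(x) inherits(x, "tac")

validate_time_grid <- function(time) {
  if (length(time) < 2) {
    stop("time grid needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(time))) {
    stop("time grid must be finite", call. = FALSE)
  }
  if (time[1] < 0) {
    stop("time grid must start at t >= 0", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  invisible(time)
}

#' @rdname tac
#' @param ... Ignored.
#' @export
print.tac <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<tac> %d samples, t = [%.4g, %.4g] min, value range [%.4g, %.4g]\n",
              n, x$time[1], x$time[n], min(x$value), max(x$value)))
  invisible(x)
}

#' @rdname tac
#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(time_min = x$time, value = x$value)
}

#' @rdname tac
#' @param y Ignored (plot method).
#' @export
plot.tac <- function(x, y, ...) {
  graphics::plot(x$time, x$value, type = "l", xlab = "time (min)",
                 ylab = "concentration", ...)
}

# internal: check two tacs share one grid
stopifnot_same_grid <- function(...) {
  tacs <- list(...)
  ref <- tacs[[1]]$time
  for (tc in tacs[-1]) {
    if (length(tc$time) != length(ref) ||
        any(abs(tc$time - ref) > 1e-12 * pmax(1, abs(ref)))) {
      stop("TACs must share the same time grid", call. = FALSE)
    }
  }
  invisible(ref)
}

#' Default simulation time grid
#'
#' Uniform sampling from 0 to 60 minutes at 10-second spacing (361 samples),
#' the grid used by all built-in simulations. Dynamic small-animal PET
#' protocols of roughly this duration and framing are typical for
#' thymidine/deoxyglucose tracers.
#'
#' @param t_end End of scan in minutes.
#' @param dt Sample spacing in minutes.
#' @return Numeric vector of times.
#' @export
default_time_grid <- function(t_end = 60, dt = 1 / 6) {
  seq(0, t_end, by = dt)
}
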