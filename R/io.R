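# Plain-text readers and writers. All numeric output is written with 17
# significant digits so every round trip is lossless at double precision.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write TAC CSV files
#'
#' Format: header `time_min,value`, one row per sample, '.' decimal
#' separator, UTF-8. Round trips are lossless to double precision.
#'
#' @param x A [tac()] to write.
#' @param path File path.
#' @return `read_tac_csv()` returns a [tac()]; `write_tac_csv()` returns
#'   `path` invisibly.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(is_tac(x))
  writeLines(c("time_min,value",
               paste(fmt_num(x$time), fmt_num(x$value), sep = ",")),
             con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "value") %in% names(d))) {
    stop("expected columns time_min,value in ", path, call. = FALSE)
  }
  tac(d$time_min, d$value)
}

#' Read and write design-matrix CSV files
#'
#' Format: header `vb,vEES,vEIS`, one row per window voxel.
#'
#' @param A Design matrix (any input accepted by [build_design_matrix()]).
#' @param path File path.
#' @return `read_design_matrix_csv()` returns a `"design_matrix"`.
#' @export
write_design_matrix_csv <- function(A, path) {
  if (!inherits(A, "design_matrix")) A <- build_design_matrix(A)
  m <- unclass(A)
  writeLines(c("vb,vEES,vEIS",
               paste(fmt_num(m[, 1]), fmt_num(m[, 2]), fmt_num(m[, 3]),
                     sep = ",")),
             con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_design_matrix_csv
#' @export
read_design_matrix_csv <- function(path) {
  build_design_matrix(utils::read.csv(path))
}

#' Read and write window-observation CSV files
#'
#' Wide format: header `time_min,voxel_01,...,voxel_N`, one row per time
#' sample.
#'
#' @param obs A [window_observation()] to write.
#' @param path File path.
#' @return `read_window_csv()` returns a [window_observation()].
#' @export
write_window_csv <- function(obs, path) {
  stopifnot(inherits(obs, "window_observation"))
  n <- ncol(obs$values)
  header <- paste(c("time_min", sprintf("voxel_%02d", seq_len(n))),
                  collapse = ",")
  body <- apply(cbind(obs$time, obs$values), 1,
                function(r) paste(fmt_num(r), collapse = ","))
  writeLines(c(header, body), con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_window_csv
#' @export
read_window_csv <- function(path) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "time_min") {
    stop("expected first column time_min in ", path, call. = FALSE)
  }
  window_observation(d[[1]], as.matrix(d[, -1, drop = FALSE]))
}

#' Serialize model parameters to JSON
#'
#' Writes whichever of the canonical fields the object carries, with the
#' exact names `K1, k2, k3, k4, vb, vEES, vEIS, hematocrit, Ktrans, vp`.
#' `read_params_json()` reconstructs the matching class from the fields
#' present.
#'
#' @param x A [pet_params()], [volume_fractions()] or [dce_params()].
#' @param path File path.
#' @return `read_params_json()` returns the reconstructed object.
#' @export
write_params_json <- function(x, path) {
  fields <- c("K1", "k2", "k3", "k4", "vb", "vEES", "vEIS", "hematocrit",
              "Ktrans", "vp")
  out <- unclass(x)[intersect(fields, names(unclass(x)))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("K1", "k2", "k3", "k4") %in% names(d))) {
    return(pet_params(d$K1, d$k2, d$k3, d$k4))
  }
  if ("Ktrans" %in% names(d)) {
    return(dce_params(d$Ktrans, d$vEES, if (is.null(d$vp)) 0 else d$vp))
  }
  if (all(c("vb", "vEES", "vEIS") %in% names(d))) {
    hct <- if (is.null(d$hematocrit)) 0.45 else d$hematocrit
    return(volume_fractions(d$vb, d$vEES, d$vEIS, hematocrit = hct))
  }
  stop("unrecognised parameter JSON: ", path, call. = FALSE)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `"fit_result"` from [fit_pet_kinetics()] or
#'   [fit_dce_tofts()].
#' @param path File path.
#' @return `read_fit_json()` returns the reconstructed `"fit_result"`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(params = unclass(fit$params),
              param_class = class(fit$params),
              residual_norm = fit$residual_norm,
              converged = fit$converged,
              n_iterations = fit$n_iterations,
              start_used = fit$start_used)
  if (!is.null(fit$per_parameter_relative_error)) {
    out$per_parameter_relative_error <-
      as.list(fit$per_parameter_relative_error)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- d$params
  params <- if (d$param_class == "pet_params") {
    pet_params(p$K1, p$k2, p$k3, p$k4)
  } else {
    dce_params(p$Ktrans, p$vEES, p$vp)
  }
  res <- list(params = params, residual_norm = d$residual_norm,
              converged = d$converged, n_iterations = d$n_iterations,
              start_used = d$start_used)
  if (!is.null(d$per_parameter_relative_error)) {
    res$per_parameter_relative_error <- unlist(d$per_parameter_relative_error)
  }
  structure(res, class = "fit_result")
}

#' Read and write study configurations as flat YAML
#'
#' Every [study_config()] field maps to one key; AIF parameters are
#' flattened with an `aif_` prefix and an optional fixed parameter set with
#' a `kin_` prefix.
#'
#' @param config A [study_config()] to write.
#' @param path File path.
#' @return `read_study_config()` returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  flat <- unclass(config)
  flat$aif <- NULL
  flat$kinetic_params <- NULL
  names(flat) <- names(flat)
  aif <- unclass(config$aif)
  names(aif) <- paste0("aif_", names(aif))
  flat <- c(flat, aif)
  if (!is.null(config$kinetic_params)) {
    kin <- unclass(config$kinetic_params)
    names(kin) <- paste0("kin_", names(kin))
    flat <- c(flat, kin)
  }
  yaml::write_yaml(flat, path, precision = 17)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  d <- yaml::read_yaml(path)
  aif_keys <- grep("^aif_", names(d), value = TRUE)
  aif <- do.call(aif_params, stats::setNames(d[aif_keys],
                                             sub("^aif_", "", aif_keys)))
  kin_keys <- grep("^kin_", names(d), value = TRUE)
  kin <- if (length(kin_keys) == 4) {
    do.call(pet_params, stats::setNames(d[kin_keys], sub("^kin_", "", kin_keys)))
  } else {
    NULL
  }
  rest <- d[setdiff(names(d), c(aif_keys, kin_keys))]
  rest <- lapply(rest, function(x) if (is.list(x)) unlist(x) else x)
  do.call(study_config, c(rest, list(aif = aif, kinetic_params = kin)))
}

#' Read and write study-result tables as CSV
#'
#' @param results A `"study_result"` data frame.
#' @param path File path.
#' @return `read_results_csv()` returns a data frame.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path)
}
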